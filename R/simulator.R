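## Hybrid dynamical simulation of a gene circuit: continuous interphase
## dynamics (sigmoid synthesis + diffusion + decay), synthesis shut-off
## during mitosis, an instantaneous nuclear division that copies mother
## concentrations to both daughters and rescales diffusion for the halved
## nucleus spacing, and no-flux boundaries at the trunk edges.
##
## The right-hand side is compiled C (src/circuit_rhs.c) driven through
## deSolve; mitosis and division are integration breakpoints, never stepped
## over.  External inputs are sampled onto a fine time grid per segment and
## linearly interpolated inside the C code.

.PARMS_LEN <- 32768L

#' Simulated circuit trajectory
#'
#' Concentration snapshots of all gap genes over the nucleus lattice at the
#' requested times, together with the division event record.
#'
#' @slot spec the [GeneNetworkSpec-class] simulated.
#' @slot times named numeric snapshot times (min).
#' @slot states list of gene x nucleus concentration matrices, one per time.
#' @slot latticePre,latticePost lattices before and after division
#'   (\code{latticePost} equals \code{latticePre} when no division occurs).
#' @slot divisionTime numeric(1) or numeric(0).
#' @slot divisionRecord list with \code{pre} and \code{post} state matrices
#'   at the division instant (empty when no division).
#' @export
setClass("Trajectory",
  representation(spec = "GeneNetworkSpec", times = "numeric",
                 states = "list", latticePre = "NucleusLattice",
                 latticePost = "NucleusLattice", divisionTime = "numeric",
                 divisionRecord = "list"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != length(object@states))
    msg <- c(msg, "one state per snapshot time is required")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "snapshot times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "snapshots,",
      length(gapGenes(object@spec)), "genes,",
      nNuclei(object@latticePre), "->", nNuclei(object@latticePost),
      "nuclei\n  times:", paste(names(object@times), collapse = ", "), "\n")
})

#' @describeIn simulateCircuit Snapshot state matrix at a given time class.
#' @param trajectory a [Trajectory-class].
#' @param label snapshot name (e.g. "T3").
#' @export
trajectoryState <- function(trajectory, label) {
  k <- match(label, names(trajectory@times))
  if (is.na(k)) stop("unknown snapshot '", label, "'")
  trajectory@states[[k]]
}

#' Solver options for circuit integration
#'
#' Defaults follow stiff-capable adaptive integration: \code{lsoda} with
#' relative tolerance 1e-6 and absolute tolerance 1e-8.
#' \code{inputGridStep} is the sampling step (min) of the external-input
#' time grid handed to the compiled right-hand side.
#'
#' @param rtol,atol integration tolerances.
#' @param method a deSolve method name.
#' @param inputGridStep external input sampling step (min).
#' @param maxsteps maximal internal steps per output interval.
#' @return list of options.
#' @export
solverOptions <- function(rtol = 1e-6, atol = 1e-8, method = "lsoda",
                          inputGridStep = 1, maxsteps = 50000)
  list(rtol = rtol, atol = atol, method = method,
       inputGridStep = inputGridStep, maxsteps = maxsteps)

## --- parameter packing -----------------------------------------------------

.packHeaderLen <- function(G, M) 5L + 4L * G + G * G + G * M

## template: everything except the parameter block (sizes + input grid)
.parmsTemplate <- function(G, N, M, tgrid, V) {
  hdr <- .packHeaderLen(G, M)
  need <- hdr + 1L + length(tgrid) + length(V)
  if (need > .PARMS_LEN)
    stop("circuit too large for the compiled parameter buffer (need ",
         need, " > ", .PARMS_LEN, " doubles); reduce the input grid")
  p <- numeric(.PARMS_LEN)
  p[1] <- G; p[2] <- N; p[3] <- M
  p[hdr + 1L] <- length(tgrid)
  if (length(tgrid)) p[(hdr + 2L):(hdr + 1L + length(tgrid))] <- tgrid
  if (length(V)) p[(hdr + 1L + length(tgrid) + 1L):(need)] <- V
  p
}

.fillParms <- function(template, params, syn, Ds) {
  G <- length(params@R); M <- ncol(params@E)
  template[4] <- syn; template[5] <- Ds
  template[6:(5L + 4L * G + G * G + G * M)] <-
    c(params@R, params@D, params@lambda, params@h,
      as.numeric(params@W), as.numeric(params@E))
  template
}

## --- segment machinery -----------------------------------------------------

## Build the integration plan: breakpoints at mitosis start/end and at the
## division instant; each segment carries its lattice, synthesis flag,
## diffusion scale and a parameter template with the external inputs
## pre-sampled on a time grid.
.makeSegments <- function(spec, schedule, inputs, latticePre, latticePost,
                          solver) {
  brk <- c(schedule@tStart, schedule@mitosis, schedule@tDivision,
           schedule@tEnd)
  brk <- sort(unique(brk))
  tDiv <- if (length(schedule@tDivision)) schedule@tDivision else Inf
  mit <- schedule@mitosis
  G <- length(gapGenes(spec)); M <- length(externalInputs(spec))
  segs <- list()
  prevPost <- FALSE
  for (k in seq_len(length(brk) - 1L)) {
    t0 <- brk[k]; t1 <- brk[k + 1L]
    mid <- (t0 + t1) / 2
    post <- mid >= tDiv
    lat <- if (post) latticePost else latticePre
    syn <- if (length(mit) == 2L && mid > mit[1] && mid < mit[2]) 0 else 1
    Ds <- if (post) 4 else 1
    tg <- unique(c(seq(t0, t1, by = solver$inputGridStep), t1))
    if (length(tg) < 2L) tg <- c(t0, t1)
    ## flatten as V[k*M*N + m*N + i]: nucleus fastest, then input, then time
    V <- if (M > 0)
      as.numeric(vapply(tg, function(tt)
        t(evaluateInputs(inputs, nucleusPositions(lat), tt)),
        numeric(M * nNuclei(lat))))
    else numeric(0)
    segs[[k]] <- list(t0 = t0, t1 = t1, lattice = lat, syn = syn, Ds = Ds,
                      divideBefore = post && !prevPost,
                      template = .parmsTemplate(G, nNuclei(lat), M, tg, V))
    prevPost <- post
  }
  segs
}

## state matrix (G x N) <-> compiled layout (gene-major vector)
.stateToVec <- function(v) as.numeric(t(v))
.vecToState <- function(y, G, N, genes) {
  m <- t(matrix(y, nrow = N, ncol = G))
  rownames(m) <- genes
  m
}

.odeSegment <- function(y, times, parms, solver) {
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = y, times = times, func = "circuit_derivs", parms = parms,
      dllname = "gapCircuits", initfunc = "circuit_init",
      method = solver$method, rtol = solver$rtol, atol = solver$atol,
      maxsteps = solver$maxsteps)),
    error = function(e) e)
  if (inherits(out, "error"))
    return(list(ok = FALSE, msg = conditionMessage(out)))
  if (nrow(out) < length(times) || any(!is.finite(out)))
    return(list(ok = FALSE,
                msg = sprintf("integrator failed near t = %.3f min, |state| = %.3g",
                              out[nrow(out), 1],
                              sqrt(sum(out[nrow(out), -1]^2, na.rm = TRUE)))))
  list(ok = TRUE, out = out)
}

## Core integration over prepared segments.  Returns snapshots at the
## requested times plus the division record, or a failure flag (used as a
## sentinel by the fitting cost).
.runCircuit <- function(spec, params, segs, schedule, v0, solver) {
  genes <- gapGenes(spec)
  G <- length(genes)
  wanted <- dataTimes(schedule)
  snaps <- vector("list", length(wanted))
  names(snaps) <- names(wanted)
  divRecord <- list()
  state <- v0
  if (abs(schedule@tStart - min(segs[[1]]$t0)) > 1e-9)
    stop("segments must start at tStart")
  for (seg in segs) {
    if (seg$divideBefore) {
      pre <- state
      div <- divideState(state, segs[[1]]$lattice, seg$lattice)
      state <- div$values
      divRecord <- list(pre = pre, post = state)
    }
    N <- nNuclei(seg$lattice)
    hit <- wanted[wanted > seg$t0 + 1e-12 & wanted <= seg$t1 + 1e-12]
    times <- sort(unique(c(seg$t0, hit, seg$t1)))
    parms <- .fillParms(seg$template, params, seg$syn, seg$Ds)
    res <- .odeSegment(.stateToVec(state), times, parms, solver)
    if (!res$ok) return(list(ok = FALSE, msg = res$msg))
    for (nm in names(hit)) {
      r <- which(abs(res$out[, 1] - wanted[[nm]]) < 1e-9)[1]
      snaps[[nm]] <- .vecToState(res$out[r, -1], G, N, genes)
    }
    state <- .vecToState(res$out[nrow(res$out), -1], G, N, genes)
  }
  ## a data time exactly at tStart refers to the initial state
  for (nm in names(wanted))
    if (is.null(snaps[[nm]]) && abs(wanted[[nm]] - schedule@tStart) < 1e-9)
      snaps[[nm]] <- v0
  list(ok = TRUE, snaps = snaps, divRecord = divRecord, final = state)
}

#' Simulate a gene circuit
#'
#' Integrates the hybrid dynamical system dv/dt = R g(u) + D(n) Laplacian -
#' lambda v over the schedule: synthesis is shut off during mitosis (decay,
#' diffusion and the external inputs stay active), the division event copies
#' every mother concentration to both daughters and quadruples the effective
#' diffusion rate (Fickian scaling for halved spacing), and the trunk edges
#' are no-flux.  Snapshots are returned at the schedule's data times.
#'
#' @param params a [CircuitParameters-class].
#' @param inputs an [ExternalInputSet-class] (may have zero inputs).
#' @param schedule a [DivisionSchedule-class].
#' @param v0 initial gene x nucleus state matrix on the pre-division
#'   lattice; defaults to zeros.
#' @param lattice pre-division lattice; defaults to the C13 trunk lattice of
#'   the spec when the schedule divides, otherwise required.
#' @param latticePost post-division lattice; defaults to the C14A trunk
#'   lattice.
#' @param solver see [solverOptions()].
#' @return A [Trajectory-class].
#' @export
simulateCircuit <- function(params, inputs, schedule = divisionSchedule(),
                            v0 = NULL, lattice = NULL, latticePost = NULL,
                            solver = solverOptions()) {
  spec <- params@spec
  divides <- length(schedule@tDivision) > 0L
  if (is.null(lattice)) {
    if (!divides)
      stop("a lattice must be given for schedules without division")
    lattice <- buildLattice("C13", apRange(spec))
  }
  if (divides && is.null(latticePost))
    latticePost <- buildLattice("C14A", apRange(spec))
  if (!divides) latticePost <- lattice
  genes <- gapGenes(spec)
  if (is.null(v0)) {
    v0 <- matrix(0, length(genes), nNuclei(lattice))
    rownames(v0) <- genes
  }
  if (any(v0 < 0)) stop("initial state must be non-negative")
  segs <- .makeSegments(spec, schedule, inputs, lattice, latticePost, solver)
  res <- .runCircuit(spec, params, segs, schedule, v0, solver)
  if (!res$ok) stop("simulation failed: ", res$msg)
  keep <- !vapply(res$snaps, is.null, logical(1))
  new("Trajectory", spec = spec, times = dataTimes(schedule)[keep],
      states = res$snaps[keep], latticePre = lattice,
      latticePost = latticePost,
      divisionTime = schedule@tDivision, divisionRecord = res$divRecord)
}

#' Nuclear division of a state matrix
#'
#' Copies each mother nucleus concentration to both daughters (2i and 2i+1
#' of mother i in axis indices), doubling total mass.  When a target
#' post-division lattice is supplied, daughters whose span no longer
#' intersects the trunk are dropped (27 C13 mothers give 54 daughters, of
#' which the 53-nucleus C14A trunk retains 53).  Dividing a C14A state is an
#' error: the model contains exactly one division.
#'
#' @param values gene x nucleus state matrix on \code{lattice}.
#' @param lattice pre-division [NucleusLattice-class].
#' @param latticePost optional target lattice; defaults to keeping all
#'   daughters.
#' @return list with \code{values} and \code{lattice} after division.
#' @export
divideState <- function(values, lattice, latticePost = NULL) {
  if (lattice@stage == "C14A")
    stop("state is already on a C14A lattice; only one division is modelled")
  if (ncol(values) != nNuclei(lattice))
    stop("state has ", ncol(values), " columns but lattice has ",
         nNuclei(lattice), " nuclei")
  daughters <- sort(c(2L * lattice@indices, 2L * lattice@indices + 1L))
  if (is.null(latticePost)) {
    nAxis <- 2L * lattice@nAxis
    if (lattice@stage == "C13") {
      latticePost <- new("NucleusLattice", stage = "C14A", nAxis = nAxis,
                         indices = daughters,
                         positions = (daughters + 0.5) * (100 / nAxis))
    } else {
      ## custom lattice: halve the bin width, keep the covered interval
      w <- if (nNuclei(lattice) > 1L) diff(lattice@positions[1:2]) else
        100 / lattice@nAxis
      lo <- lattice@positions[1] - w / 2
      latticePost <- new("NucleusLattice", stage = "custom", nAxis = nAxis,
                         indices = daughters,
                         positions = lo + (w / 2) *
                           (seq_along(daughters) - 0.5))
    }
  }
  keep <- latticePost@indices
  mothers <- keep %/% 2L
  col <- match(mothers, lattice@indices)
  if (any(is.na(col)))
    stop("post-division lattice contains daughters without a mother")
  out <- values[, col, drop = FALSE]
  list(values = out, lattice = latticePost)
}

#' Initial conditions by temporal interpolation
#'
#' Gap gene initial conditions at the start of C13 are obtained by linear
#' interpolation in time between an early anchor (cycle 12, t = -6.2 min,
#' zeros by default since mRNA levels are low at the start of C13) and the
#' dataset's C13 time class, evaluated at \code{t0}.  Values inherit the
#' dataset's temporal scaling through the C13 anchor.
#'
#' @param dataset an [ExpressionDataset-class] whose first time class is on
#'   the C13 lattice.
#' @param t0 evaluation time (default 0, start of C13).
#' @param tC12 early anchor time (min).
#' @param vC12 early anchor matrix; zeros by default.
#' @return gene x nucleus state matrix on the C13 lattice.
#' @export
initialConditions <- function(dataset, t0 = 0, tC12 = -6.2, vC12 = NULL) {
  cd <- SummarizedExperiment::colData(dataset)
  lab <- cd$time_class[1]
  cols <- which(cd$time_class == lab)
  v13 <- datasetValues(dataset)[, cols, drop = FALSE]
  t13 <- cd$time_min[cols[1]]
  if (is.null(vC12)) vC12 <- v13 * 0
  if (t0 < tC12 || t0 > t13)
    stop("t0 must lie within the anchor interval [", tC12, ", ", t13, "]")
  vC12 + (v13 - vC12) * (t0 - tC12) / (t13 - tC12)
}

#' Sample a trajectory in dataset layout
#'
#' Extracts the snapshots at the requested times and binds them into a gene
#' x (time, nucleus) matrix ordered exactly like an
#' [ExpressionDataset-class] with the same time classes, so model output and
#' data can be compared element-wise.
#'
#' @param trajectory a [Trajectory-class].
#' @param times snapshot labels (default: all snapshots).
#' @return gene x column matrix (possibly with zero columns).
#' @export
sampleAt <- function(trajectory, times = names(trajectory@times)) {
  if (length(times) == 0L)
    return(matrix(numeric(0), length(gapGenes(trajectory@spec)), 0))
  bad <- setdiff(times, names(trajectory@times))
  if (length(bad))
    stop("unknown snapshot time(s): ", paste(bad, collapse = ", "))
  do.call(cbind, lapply(times, function(nm) {
    m <- trajectory@states[[match(nm, names(trajectory@times))]]
    colnames(m) <- paste(nm, seq_len(ncol(m)) - 1L, sep = ".")
    m
  }))
}
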