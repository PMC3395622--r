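## Circuit structure: lattices, parameters, masks, the regulation-expression
## function, and parameter (de)serialisation.

#' Build a nucleus lattice for a cleavage-cycle stage
#'
#' Discretises the A--P axis into 50 ("C13") or 100 ("C14A") equally wide
#' nucleus bins and retains the contiguous run of nuclei whose spatial span
#' intersects the closed trunk interval \code{apRange}.  Nucleus j (0-based)
#' spans the half-open interval [100j/nAxis, 100(j+1)/nAxis) \% A--P.  With
#' the defaults this reproduces the published lattice sizes: 27 nuclei at C13
#' and 53 at C14A for the 35--87\% trunk, and 58 at C14A for 35--92\%.
#'
#' @param stage "C13" or "C14A".
#' @param apRange closed trunk interval in \% A--P.
#' @return A [NucleusLattice-class].
#' @examples
#' nNuclei(buildLattice("C14A", c(35, 87)))  # 53
#' @export
buildLattice <- function(stage = c("C14A", "C13"), apRange = c(35, 87)) {
  stage <- match.arg(stage)
  nAxis <- if (stage == "C13") 50L else 100L
  apRange <- as.numeric(apRange)
  if (length(apRange) != 2L || apRange[1] < 0 || apRange[2] > 100 ||
      apRange[1] >= apRange[2])
    stop("apRange must satisfy 0 <= lo < hi <= 100")
  w <- 100 / nAxis
  if (diff(apRange) < w)
    stop(sprintf("A-P range [%g, %g] is narrower than one nucleus at %s",
                 apRange[1], apRange[2], stage))
  j <- 0:(nAxis - 1L)
  ## span [j*w, (j+1)*w) intersects closed [lo, hi]
  keep <- (j * w <= apRange[2]) & ((j + 1L) * w > apRange[1])
  if (!any(keep))
    stop(sprintf("A-P range [%g, %g] is narrower than one nucleus at %s",
                 apRange[1], apRange[2], stage))
  idx <- j[keep]
  new("NucleusLattice", stage = stage, nAxis = nAxis,
      indices = as.integer(idx), positions = (idx + 0.5) * w)
}

#' Build a custom lattice over an arbitrary interval
#'
#' Used for reduced synthetic scenarios that do not model the full embryo
#' axis: \code{n} equally wide bins spanning \code{apRange}.
#'
#' @param n number of nuclei.
#' @param apRange interval covered (\% A--P).
#' @return A [NucleusLattice-class] with stage "custom".
#' @export
customLattice <- function(n, apRange = c(35, 87)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  w <- diff(apRange) / n
  new("NucleusLattice", stage = "custom", nAxis = n,
      indices = 0:(n - 1L), positions = apRange[1] + w * (0:(n - 1L) + 0.5))
}

#' Number of state variables of a circuit
#'
#' One ODE per gap gene and trunk nucleus: G x N.  The default trunk circuits
#' have 4 x 27 = 108 state variables at C13 and 4 x 53 = 212 at C14A.
#'
#' @param spec a [GeneNetworkSpec-class].
#' @param lattice a [NucleusLattice-class].
#' @return integer.
#' @export
countStateVariables <- function(spec, lattice)
  length(gapGenes(spec)) * nNuclei(lattice)

#' Sigmoid regulation-expression function
#'
#' g(u) = (u / sqrt(u^2 + 1) + 1) / 2, the saturating response mapping total
#' regulatory input u to a synthesis activation level in (0, 1).  It is
#' strictly increasing, satisfies g(0) = 1/2 and g(u) + g(-u) = 1, and tends
#' to 0 and 1 in the limits.
#'
#' @param u total regulatory input (finite numeric, vectorised).
#' @return activation level(s) in (0, 1).
#' @examples
#' regulationFunction(0)   # 0.5
#' regulationFunction(1)   # (1/sqrt(2) + 1)/2
#' @export
regulationFunction <- function(u) {
  if (any(!is.finite(u))) stop("u must be finite")
  0.5 * (u / sqrt(u * u + 1) + 1)
}

#' Total regulatory input on one gene
#'
#' u^a = sum_b w^{ba} v^b + sum_m e^{ma} v^m + h^a for target gene \code{gene}
#' in a single nucleus.
#'
#' @param gapConcentrations concentrations of the gap genes, in spec order.
#' @param externalConcentrations concentrations of the external inputs, in
#'   spec order.
#' @param params a [CircuitParameters-class].
#' @param gene target gene identifier.
#' @return numeric scalar u.
#' @export
totalInput <- function(gapConcentrations, externalConcentrations, params,
                       gene) {
  g <- gapGenes(params@spec); m <- externalInputs(params@spec)
  if (length(gapConcentrations) != length(g))
    stop("gapConcentrations must match the number of gap genes")
  if (length(externalConcentrations) != length(m))
    stop("externalConcentrations must match the number of external inputs")
  a <- match(gene, g)
  if (is.na(a)) stop(sprintf("unknown gap gene '%s'", gene))
  unname(sum(params@W[a, ] * gapConcentrations) +
         (if (length(m)) sum(params@E[a, ] * externalConcentrations) else 0) +
         params@h[a])
}

#' Default free/fixed mask for circuit parameters
#'
#' All parameters free except the thresholds \code{h} (fixed, by default at
#' -2.5 for every gap gene) and -- in the standard four-gene network -- the
#' regulatory weights of Hkb on every gap gene except \emph{hb}, which are
#' fixed at 0.  \code{TRUE} marks a free parameter.  Individual entries can
#' be overridden after construction to configure any fixing variant.
#'
#' @param spec a [GeneNetworkSpec-class].
#' @return named list of logical structures (W, E, R, D, lambda, h).
#' @export
defaultMask <- function(spec) {
  g <- gapGenes(spec); m <- externalInputs(spec)
  G <- length(g); M <- length(m)
  mask <- list(
    W = matrix(TRUE, G, G, dimnames = list(g, g)),
    E = matrix(TRUE, G, M, dimnames = list(g, m)),
    R = setNames(rep(TRUE, G), g),
    D = setNames(rep(TRUE, G), g),
    lambda = setNames(rep(TRUE, G), g),
    h = setNames(rep(FALSE, G), g))
  if ("hkb" %in% m) {
    others <- setdiff(g, "hb")
    mask$E[others, "hkb"] <- FALSE
  }
  mask
}

#' Create a circuit parameter object
#'
#' Builds a [CircuitParameters-class] with named, dimension-checked slots.
#' Masked (fixed) entries default to the biologically standard values:
#' h = -2.5 everywhere and Hkb weights 0 on all targets but \emph{hb}.
#'
#' @param spec a [GeneNetworkSpec-class].
#' @param W G x G weight matrix, targets in rows, regulators in columns.
#' @param E G x M external input weight matrix, inputs in columns.
#' @param R,D,lambda,h per-gene rates/thresholds (recycled if scalar).
#' @param mask free/fixed mask, see [defaultMask()].
#' @return A [CircuitParameters-class].
#' @export
circuitParameters <- function(spec = geneNetworkSpec(),
                              W = NULL, E = NULL, R = 15, D = 0.05,
                              lambda = 0.08, h = -2.5,
                              mask = defaultMask(spec)) {
  g <- gapGenes(spec); m <- externalInputs(spec)
  G <- length(g); M <- length(m)
  if (is.null(W)) W <- matrix(0, G, G)
  if (is.null(E)) E <- matrix(0, G, M)
  dimnames(W) <- list(g, g)
  if (M) dimnames(E) <- list(g, m) else dimnames(E) <- list(g, NULL)
  vec <- function(x) setNames(rep_len(as.numeric(x), G), g)
  p <- new("CircuitParameters", spec = spec, W = W, E = E,
           R = vec(R), D = vec(D), lambda = vec(lambda), h = vec(h),
           mask = mask)
  ## enforce canonical fixed values for the default-masked Hkb column
  if ("hkb" %in% m) {
    fixedE <- !p@mask$E[, "hkb", drop = TRUE]
    p@E[fixedE, "hkb"] <- 0
  }
  p
}

## --- free parameter vector plumbing ---------------------------------------

.paramSlots <- c("W", "E", "R", "D", "lambda", "h")

.freeNames <- function(params) {
  out <- character()
  for (nm in .paramSlots) {
    x <- slot(params, nm); msk <- params@mask[[nm]]
    if (is.matrix(x)) {
      lbl <- outer(rownames(x), colnames(x),
                   function(a, b) paste0(nm, ".", a, ".", b))
    } else lbl <- paste0(nm, ".", names(x))
    out <- c(out, lbl[as.logical(msk)])
  }
  out
}

#' Extract the free-parameter vector
#'
#' Flattens the free (unmasked) entries of a [CircuitParameters-class] into a
#' named numeric vector; matrix entries are named
#' \code{W.<target>.<regulator>} and \code{E.<target>.<input>}.
#'
#' @param params a [CircuitParameters-class].
#' @return named numeric vector.
#' @export
freeParams <- function(params) {
  out <- numeric()
  for (nm in .paramSlots) {
    x <- slot(params, nm); msk <- as.logical(params@mask[[nm]])
    out <- c(out, as.numeric(x)[msk])
  }
  setNames(out, .freeNames(params))
}

#' Update the free parameters of a circuit
#'
#' Writes a free-parameter vector (as produced by [freeParams()]) back into a
#' [CircuitParameters-class]; masked entries are left untouched, so fixed
#' parameters can never change through the fitting interface.
#'
#' @param params a [CircuitParameters-class].
#' @param theta numeric vector, same length and order as [freeParams()].
#' @return the updated [CircuitParameters-class].
#' @export
updateFreeParams <- function(params, theta) {
  k <- 0L
  for (nm in .paramSlots) {
    x <- slot(params, nm); msk <- as.logical(params@mask[[nm]])
    n <- sum(msk)
    if (n) {
      x[msk] <- theta[(k + 1L):(k + n)]
      slot(params, nm) <- x
      k <- k + n
    }
  }
  if (k != length(theta))
    stop("theta has the wrong length for the free parameters of this circuit")
  validObject(params)
  params
}

## --- JSON serialisation ----------------------------------------------------

#' Write / read circuit parameters as labelled JSON
#'
#' Parameters are serialised with explicit gene and input labels (never
#' positionally), so files remain readable when gene ordering conventions
#' change.
#'
#' @param params a [CircuitParameters-class].
#' @param path file path.
#' @return \code{readCircuitParameters} returns a [CircuitParameters-class];
#'   \code{writeCircuitParameters} returns \code{path} invisibly.
#' @export
writeCircuitParameters <- function(params, path) {
  s <- params@spec
  obj <- list(
    gap_genes = gapGenes(s), external_inputs = externalInputs(s),
    ap_range = apRange(s),
    W = params@W, E = params@E, R = params@R, D = params@D,
    lambda = params@lambda, h = params@h,
    mask = lapply(params@mask, function(x) x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname writeCircuitParameters
#' @export
readCircuitParameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- geneNetworkSpec(obj$gap_genes, obj$external_inputs, obj$ap_range)
  g <- obj$gap_genes
  asmat <- function(x, cn) {
    x <- as.matrix(x); dimnames(x) <- list(g, cn); x
  }
  mask <- list(W = asmat(matrix(as.logical(obj$mask$W), nrow = length(g)), g),
               E = asmat(matrix(as.logical(obj$mask$E), nrow = length(g)),
                         obj$external_inputs),
               R = setNames(as.logical(obj$mask$R), g),
               D = setNames(as.logical(obj$mask$D), g),
               lambda = setNames(as.logical(obj$mask$lambda), g),
               h = setNames(as.logical(obj$mask$h), g))
  new("CircuitParameters", spec = spec,
      W = asmat(obj$W, g), E = asmat(obj$E, obj$external_inputs),
      R = setNames(as.numeric(obj$R), g), D = setNames(as.numeric(obj$D), g),
      lambda = setNames(as.numeric(obj$lambda), g),
      h = setNames(as.numeric(obj$h), g), mask = mask)
}
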