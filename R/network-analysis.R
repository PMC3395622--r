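## From parameter ensembles to regulatory biology: interaction
## classification, interconnectivity summaries, net effects between
## overlapping expression domains, mechanism detection, and the
## reduced-data experiment harness.

#' Classify a regulatory weight
#'
#' repressing if w < -cutoff, activating if w > cutoff, otherwise "none";
#' values exactly at the cutoff count as no interaction.  Antisymmetric
#' under negation of the weight.
#'
#' @param weight finite numeric (vectorised).
#' @param cutoff category cutoff (default 0.005).
#' @return character vector in \{"repressing", "none", "activating"\}.
#' @examples
#' classifyInteraction(c(-0.2, 0.004, 0.005, 0.2))
#' @export
classifyInteraction <- function(weight, cutoff = 0.005) {
  if (any(!is.finite(weight))) stop("weights must be finite")
  ifelse(weight < -cutoff, "repressing",
         ifelse(weight > cutoff, "activating", "none"))
}

#' Interconnectivity summary over an ensemble
#'
#' Counts, for every (regulator, target) pair, how many circuits of an
#' ensemble classify the interaction as repressing / none / activating,
#' and reports the consensus category (strict majority; ties are
#' "ambiguous").
#'
#' @param ensemble list of [CircuitParameters-class] or
#'   [FitResult-class] objects.
#' @param cutoff see [classifyInteraction()].
#' @return data frame: regulator, target, n_repressing, n_none,
#'   n_activating, consensus.
#' @export
interactionSummary <- function(ensemble, cutoff = 0.005) {
  pars <- lapply(ensemble, function(e)
    if (is(e, "FitResult")) e@params else e)
  spec <- pars[[1]]@spec
  g <- gapGenes(spec); m <- externalInputs(spec)
  pairs <- rbind(expand.grid(regulator = g, target = g,
                             stringsAsFactors = FALSE),
                 expand.grid(regulator = m, target = g,
                             stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    reg <- pairs$regulator[k]; tgt <- pairs$target[k]
    w <- vapply(pars, function(p)
      if (reg %in% g) p@W[tgt, reg] else p@E[tgt, reg], numeric(1))
    cl <- classifyInteraction(w, cutoff)
    n <- c(sum(cl == "repressing"), sum(cl == "none"),
           sum(cl == "activating"))
    cons <- if (max(n) > sum(n) / 2)
      c("repressing", "none", "activating")[which.max(n)] else "ambiguous"
    data.frame(regulator = reg, target = tgt, n_repressing = n[1],
               n_none = n[2], n_activating = n[3], consensus = cons)
  })
  do.call(rbind, rows)
}

#' Region of overlapping expression of two genes
#'
#' Nuclei at which both genes exceed \code{threshold} times their own
#' slice maximum at the given time.  For genes with multiple expression
#' domains, the posterior-most contiguous run of the overlap is returned,
#' as used in the domain-shift analysis.
#'
#' @param trajectory a [Trajectory-class].
#' @param geneA,geneB gene identifiers.
#' @param time snapshot label.
#' @param threshold fraction of the per-gene slice maximum (default 0.1).
#' @return integer vector of nucleus column indices (possibly empty).
#' @export
overlapRegion <- function(trajectory, geneA, geneB, time, threshold = 0.1) {
  st <- trajectoryState(trajectory, time)
  on <- function(g) {
    v <- st[g, ]
    mx <- max(v)
    if (mx <= 0) rep(FALSE, length(v)) else v > threshold * mx
  }
  both <- on(geneA) & on(geneB)
  if (!any(both)) return(integer(0))
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  k <- runs[length(runs)]            # posterior-most contiguous run
  seq.int(starts[k], ends[k])
}

#' Net effect of a regulatory interaction over a region
#'
#' The regulatory weight of \code{regulator} on \code{target} multiplied by
#' the regulator's concentration, summed over the given nuclei and snapshot
#' times and (by default) normalised per nucleus-time so regions of
#' different sizes compare fairly.  Negative values are net repression.
#'
#' @param trajectory a [Trajectory-class].
#' @param params the circuit's [CircuitParameters-class].
#' @param regulator,target gap gene identifiers.
#' @param region integer nucleus columns (e.g. from [overlapRegion()]), or
#'   a function(time label) returning them per time.
#' @param times snapshot labels to integrate over.
#' @param normalize divide by the number of (nucleus, time) terms?
#' @return signed numeric scalar.
#' @export
netEffect <- function(trajectory, params, regulator, target, region,
                      times, normalize = TRUE) {
  w <- params@W[target, regulator]
  tot <- 0; n <- 0L
  for (tm in times) {
    reg <- if (is.function(region)) region(tm) else region
    if (length(reg) == 0L) next
    st <- trajectoryState(trajectory, tm)
    tot <- tot + sum(w * st[regulator, reg])
    n <- n + length(reg)
  }
  if (n == 0L) stop("empty overlap region for ", regulator, " -> ", target)
  if (normalize) tot / n else tot
}

## ---------------------------------------------------------------------------
## mechanism report
## ---------------------------------------------------------------------------

#' Mechanism report over a gene-circuit ensemble
#'
#' Fractions of circuits exhibiting the canonical gap-gene regulatory
#' mechanisms, computed with [classifyInteraction()] (weight sign with
#' cutoff) and [netEffect()] (domain-shift asymmetries over the posterior
#' overlap regions at the C14A time classes):
#' \itemize{
#'   \item alternating cushions: mutual repression between both pairs of
#'     non-overlapping gap genes (hb/kni and Kr/gt);
#'   \item auto-activation: each gene's self-weight activating;
#'   \item shifting domains: net repression of \emph{gt} by posterior Hb,
#'     of \emph{kni} by Gt and of \emph{Kr} by Kni stronger than the
#'     reciprocal effect (posterior dominance);
#'   \item hb/Kr net repression: whether Hb net-represses \emph{Kr} more
#'     than Kr net-represses \emph{hb} over their overlap;
#'   \item Bcd and Cad activation: Bcd activates all four gap genes and
#'     Cad activates \emph{gt} and \emph{kni};
#'   \item Tll and Hkb inhibition: Hkb represses \emph{hb} while Tll
#'     represses the other three gap genes.
#' }
#'
#' @slot fractions named numeric in [0, 1].
#' @slot nCircuits ensemble size.
#' @slot perCircuit logical matrix (circuit x mechanism).
#' @export
setClass("MechanismReport",
  representation(fractions = "numeric", nCircuits = "integer",
                 perCircuit = "matrix"))

setValidity("MechanismReport", function(object) {
  ## NA marks mechanisms that could not be evaluated (e.g. no trajectories)
  if (any(object@fractions < 0 | object@fractions > 1, na.rm = TRUE))
    "fractions must lie in [0, 1]" else TRUE
})

setMethod("show", "MechanismReport", function(object) {
  cat("MechanismReport over", object@nCircuits, "circuits:\n")
  for (nm in names(object@fractions))
    cat(sprintf("  %-28s %.2f\n", nm, object@fractions[[nm]]))
})

#' @rdname MechanismReport-class
#' @param ensemble list of [CircuitParameters-class] or
#'   [FitResult-class] objects (QC-passed circuits).
#' @param trajectories list of [Trajectory-class] objects matching the
#'   ensemble (required for the net-effect mechanisms; if NULL those
#'   fractions are NA).
#' @param cutoff interaction cutoff.
#' @param times snapshot labels for net-effect integration; defaults to
#'   all C14A time classes of the first trajectory.
#' @param threshold overlap threshold, see [overlapRegion()].
#' @return A [MechanismReport-class].
#' @export
mechanismReport <- function(ensemble, trajectories = NULL, cutoff = 0.005,
                            times = NULL, threshold = 0.1) {
  if (length(ensemble) == 0L) stop("ensemble must be non-empty")
  pars <- lapply(ensemble, function(e)
    if (is(e, "FitResult")) e@params else e)
  spec <- pars[[1]]@spec
  g <- gapGenes(spec); m <- externalInputs(spec)
  need <- c("hb", "Kr", "gt", "kni")
  if (!all(need %in% g))
    stop("mechanism definitions require the gap genes ",
         paste(need, collapse = ", "))
  act <- function(p, tgt, reg) p@W[tgt, reg] > cutoff
  rep_ <- function(p, tgt, reg) p@W[tgt, reg] < -cutoff
  eAct <- function(p, tgt, reg) p@E[tgt, reg] > cutoff
  eRep <- function(p, tgt, reg) p@E[tgt, reg] < -cutoff
  shiftPairs <- list(c(target = "gt", regulator = "hb"),
                     c(target = "kni", regulator = "gt"),
                     c(target = "Kr", regulator = "kni"))
  mech <- c("alternating_cushions",
            paste0("auto_activation_", need),
            "shift_gt_by_hb", "shift_kni_by_gt", "shift_Kr_by_kni",
            "hb_Kr_net_repression_by_hb",
            "bcd_cad_activation", "tll_hkb_inhibition")
  perC <- matrix(NA, length(pars), length(mech),
                 dimnames = list(NULL, mech))
  for (i in seq_along(pars)) {
    p <- pars[[i]]
    perC[i, "alternating_cushions"] <-
      rep_(p, "hb", "kni") && rep_(p, "kni", "hb") &&
      rep_(p, "Kr", "gt") && rep_(p, "gt", "Kr")
    for (gn in need)
      perC[i, paste0("auto_activation_", gn)] <- act(p, gn, gn)
    if (all(c("bcd", "cad") %in% m))
      perC[i, "bcd_cad_activation"] <-
        all(vapply(need, function(gn) eAct(p, gn, "bcd"), logical(1))) &&
        eAct(p, "gt", "cad") && eAct(p, "kni", "cad")
    if (all(c("tll", "hkb") %in% m))
      perC[i, "tll_hkb_inhibition"] <-
        eRep(p, "hb", "hkb") && eRep(p, "Kr", "tll") &&
        eRep(p, "gt", "tll") && eRep(p, "kni", "tll")
    if (!is.null(trajectories)) {
      tr <- trajectories[[i]]
      if (is.null(times)) {
        tms <- names(tr@times)
        if (length(tr@divisionTime))
          tms <- tms[tr@times > tr@divisionTime]
      } else tms <- times
      netPair <- function(target, regulator) {
        fwd <- bwd <- 0; n <- 0L
        for (tm in tms) {
          rg <- overlapRegion(tr, target, regulator, tm, threshold)
          if (!length(rg)) next
          st <- trajectoryState(tr, tm)
          fwd <- fwd + sum(p@W[target, regulator] * st[regulator, rg])
          bwd <- bwd + sum(p@W[regulator, target] * st[target, rg])
          n <- n + length(rg)
        }
        if (n == 0L) return(NA)
        (fwd / n) < (bwd / n)   # regulator dominates (more repressive)
      }
      for (sp in shiftPairs)
        perC[i, paste0("shift_", sp[["target"]], "_by_", sp[["regulator"]])] <-
          netPair(sp[["target"]], sp[["regulator"]])
      perC[i, "hb_Kr_net_repression_by_hb"] <- netPair("Kr", "hb")
    }
  }
  fr <- colMeans(perC)
  new("MechanismReport", fractions = fr,
      nCircuits = length(pars), perCircuit = perC)
}

## ---------------------------------------------------------------------------
## reduced-data harness
## ---------------------------------------------------------------------------

## round half away from zero
.roundHalfAway <- function(x) floor(x + 0.5)

#' Randomly reduce the number of boundary observations
#'
#' Emulates reduced-coverage datasets: within every (gene, time class,
#' boundary id) group of individual-embryo annotations, a random subset of
#' max(1, round(fraction * n)) rows is retained, so every observed boundary
#' keeps at least one data point (avoiding artefactual fusion or ectopic
#' extension of domains).  Deterministic per seed.
#'
#' @param annotations individual-embryo annotation data frame.
#' @param fraction fraction retained, in (0, 1].
#' @param seed integer seed.
#' @return reduced annotation data frame.
#' @export
reduceBoundaries <- function(annotations, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  set.seed(seed)
  key <- interaction(annotations$gene, annotations$time_class,
                     annotations$boundary_id, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(annotations)), key),
                        function(idx) {
    k <- max(1L, .roundHalfAway(fraction * length(idx)))
    if (k >= length(idx)) idx else sort(sample(idx, k))
  }), use.names = FALSE)
  out <- annotations[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly reduce the number of time classes
#'
#' Keeps only \code{k} of the nine standard time classes: the initial
#' (C13) and final (T8) classes are never removed, the remaining 9 - k are
#' drawn uniformly from T1--T7.  Deterministic per seed.
#'
#' @param annotations annotation data frame.
#' @param k number of time classes retained, 3 <= k <= 9.
#' @param seed integer seed.
#' @return reduced annotation data frame.
#' @export
reduceTimeclasses <- function(annotations, k, seed = 1L) {
  if (k < 3 || k > 9) stop("k must lie in [3, 9]")
  set.seed(seed)
  all9 <- c("C13", paste0("T", 1:8))
  middle <- paste0("T", 1:7)
  drop <- sample(middle, 9L - k)
  keepClasses <- setdiff(all9, drop)
  out <- annotations[annotations$time_class %in% keepClasses, ,
                     drop = FALSE]
  rownames(out) <- NULL
  attr(out, "time_classes") <- keepClasses
  out
}
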