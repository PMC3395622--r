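## Practical parameter determinability: Jacobian of the weighted residual
## vector, confidence ellipsoid, dependent (conditional) and independent
## (bounding-box) per-parameter confidence intervals, and classification of
## regulatory weights into determinability categories.

#' Per-parameter confidence intervals of a circuit fit
#'
#' Around the least-squares estimate theta-hat the (1 - alpha) confidence
#' region is the ellipsoid (theta - theta-hat)' J'J (theta - theta-hat) <=
#' Delta with Delta = p s^2 F_alpha(p, N_d - p) and s^2 = S/(N_d - p).
#' Dependent intervals are the widths of the ellipsoid's axis-parallel
#' slices through the estimate (they underestimate the region under
#' parameter correlation); independent intervals are the ellipsoid's
#' bounding box obtained from the SVD J = U Sigma V' (they overestimate
#' it), so every dependent interval is contained in its independent
#' counterpart.
#'
#' @slot table data frame: parameter, estimate, dep_lo, dep_hi, indep_lo,
#'   indep_hi.
#' @slot delta,s2 ellipsoid radius and residual variance estimate.
#' @slot p,Nd free-parameter and data-point counts.
#' @slot alpha significance level.
#' @export
setClass("ConfidenceIntervals",
  representation(table = "data.frame", delta = "numeric", s2 = "numeric",
                 p = "integer", Nd = "integer", alpha = "numeric"))

setValidity("ConfidenceIntervals", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("parameter", "estimate", "dep_lo", "dep_hi", "indep_lo",
            "indep_hi")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  tol <- 1e-9
  if (any(tb$dep_lo > tb$estimate + tol | tb$dep_hi < tb$estimate - tol))
    msg <- c(msg, "dependent intervals must contain the estimate")
  if (any(tb$indep_lo > tb$dep_lo + tol | tb$indep_hi < tb$dep_hi - tol))
    msg <- c(msg, "dependent intervals must lie inside independent ones")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConfidenceIntervals", function(object) {
  cat("ConfidenceIntervals: p =", object@p, "free parameters, N_d =",
      object@Nd, ", alpha =", object@alpha, "\n")
  print(utils::head(object@table, 10))
  if (nrow(object@table) > 10) cat("  ...\n")
})

#' @describeIn confidenceIntervals Interval table of a
#'   [ConfidenceIntervals-class].
#' @param ci a \code{ConfidenceIntervals} object.
#' @export
ciTable <- function(ci) ci@table

#' Jacobian of the weighted residual vector
#'
#' J[k, j] = d(sqrt(v_k) (model_k - data_k)) / d theta_j for every data
#' point k and free parameter j, by central finite differences with a
#' relative step of \code{relStep} per parameter (absolute floor
#' \code{absStep}).  Columns of masked parameters are omitted.
#'
#' @param params a [CircuitParameters-class] at the estimate.
#' @param dataset,inputs,schedule,v0,lattice,latticePost,solver simulation
#'   context, as in [circuitCost()].
#' @param mode "WLS" (weights from the dataset) or "OLS" (unit weights).
#' @param relStep,absStep finite-difference step controls.
#' @return N_d x p matrix with free-parameter column names.
#' @export
residualJacobian <- function(params, dataset, inputs,
                             schedule = divisionSchedule(), mode = "WLS",
                             v0 = NULL, lattice = NULL, latticePost = NULL,
                             solver = solverOptions(), relStep = 1e-4,
                             absStep = 1e-6) {
  spec <- params@spec
  if (is.null(v0) && length(schedule@tDivision) > 0L)
    v0 <- initialConditions(dataset)
  ev <- .makeEvaluator(spec, dataset, inputs, schedule, v0, lattice,
                       latticePost, solver, mode)
  w <- if (mode == "OLS") array(1, dim(datasetValues(dataset))) else
    datasetWeights(dataset)
  sw <- sqrt(as.numeric(w))
  y <- as.numeric(datasetValues(dataset))
  resid <- function(p) {
    r <- ev(p)
    if (!r$ok) stop("simulation failed while differentiating: ", r$msg)
    sw * (as.numeric(r$model) - y)
  }
  theta <- freeParams(params)
  J <- matrix(NA_real_, length(y), length(theta),
              dimnames = list(NULL, names(theta)))
  for (j in seq_along(theta)) {
    hstep <- max(relStep * abs(theta[j]), absStep)
    up <- theta; up[j] <- up[j] + hstep
    dn <- theta; dn[j] <- dn[j] - hstep
    J[, j] <- (resid(updateFreeParams(params, up)) -
                 resid(updateFreeParams(params, dn))) / (2 * hstep)
    if (any(!is.finite(J[, j])))
      stop("non-finite Jacobian column for parameter ", names(theta)[j])
  }
  J
}

#' Dependent and independent confidence intervals
#'
#' @param J residual Jacobian (N_d x p), see [residualJacobian()].
#' @param S cost at the estimate (same weighting as J).
#' @param estimates named free-parameter vector at the estimate.
#' @param alpha significance level (default 0.05 for 95\% intervals).
#' @param rankTol singular values below \code{rankTol} times the largest
#'   are treated as zero; the affected parameters receive infinite
#'   independent intervals (non-determinable) instead of an error.
#' @return A [ConfidenceIntervals-class].
#' @export
confidenceIntervals <- function(J, S, estimates, alpha = 0.05,
                                rankTol = 1e-10) {
  Nd <- nrow(J); p <- ncol(J)
  if (Nd <= p) stop("need more data points than free parameters")
  s2 <- S / (Nd - p)
  delta <- p * s2 * qf(1 - alpha, p, Nd - p)
  sv <- svd(J)
  sig <- sv$d
  keep <- sig > rankTol * max(sig)
  ## dependent: slice width from the (J'J) diagonal
  jtjDiag <- colSums(J^2)
  depHW <- ifelse(jtjDiag > 0, sqrt(delta / jtjDiag), Inf)
  ## independent: bounding box of the ellipsoid via the SVD
  V2 <- sv$v^2
  indepHW <- vapply(seq_len(p), function(j) {
    if (any(!keep & V2[j, ] > 1e-16)) return(Inf)
    sqrt(delta * sum(V2[j, keep] / sig[keep]^2))
  }, numeric(1))
  indepHW <- pmax(indepHW, depHW)   # numerical guard for exact-rank cases
  tb <- data.frame(parameter = colnames(J), estimate = as.numeric(estimates),
                   dep_lo = estimates - depHW, dep_hi = estimates + depHW,
                   indep_lo = estimates - indepHW,
                   indep_hi = estimates + indepHW, row.names = NULL)
  new("ConfidenceIntervals", table = tb, delta = delta, s2 = s2,
      p = as.integer(p), Nd = as.integer(Nd), alpha = alpha)
}

#' Classify determinability of regulatory weights
#'
#' A regulatory weight falls into one of three categories: repressing
#' (value < -cutoff), no interaction (within [-cutoff, cutoff]) or
#' activating (> cutoff).  A parameter is determinable if its independent
#' confidence interval lies entirely within one category, weakly
#' determinable if the interval excludes exactly one category ("not
#' repressing" / "not activating"), and non-determinable otherwise.  Only
#' W and E entries are classified.
#'
#' @param ci a [ConfidenceIntervals-class].
#' @param cutoff regulatory category cutoff (default 0.005).
#' @return list (class \code{determinabilityReport}) with \code{table}
#'   (parameter, interval, category, class) and \code{counts} =
#'   c(determinable, weakly, non) over the regulatory weights.
#' @export
classifyDeterminability <- function(ci, cutoff = 0.005) {
  tb <- ciTable(ci)
  reg <- grepl("^(W|E)\\.", tb$parameter)
  tb <- tb[reg, , drop = FALSE]
  classify1 <- function(lo, hi) {
    inRep <- lo < -cutoff                 # interval touches repression
    inAct <- hi > cutoff                  # touches activation
    inNone <- lo <= cutoff & hi >= -cutoff  # touches the none band
    touched <- inRep + inNone + inAct
    if (touched == 1L) "determinable"
    else if (touched == 2L) "weakly determinable"
    else "non-determinable"
  }
  category1 <- function(lo, hi) {
    if (hi < -cutoff) "repressing"
    else if (lo > cutoff) "activating"
    else if (lo >= -cutoff && hi <= cutoff) "none"
    else NA_character_
  }
  cls <- mapply(classify1, tb$indep_lo, tb$indep_hi)
  cat3 <- mapply(category1, tb$indep_lo, tb$indep_hi)
  counts <- c(determinable = sum(cls == "determinable"),
              weakly = sum(cls == "weakly determinable"),
              non = sum(cls == "non-determinable"))
  out <- list(table = data.frame(parameter = tb$parameter,
                                 indep_lo = tb$indep_lo,
                                 indep_hi = tb$indep_hi,
                                 category = cat3, class = cls,
                                 row.names = NULL),
              counts = counts, cutoff = cutoff)
  class(out) <- "determinabilityReport"
  out
}

#' @export
print.determinabilityReport <- function(x, ...) {
  cat("Determinability (cutoff ", x$cutoff, "): ",
      x$counts[1], " determinable / ", x$counts[2],
      " weakly / ", x$counts[3], " non-determinable\n", sep = "")
  invisible(x)
}
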