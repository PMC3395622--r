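## External regulator concentration profiles: maternal gradients (Bcd, Cad)
## and terminal gap genes (Tll, Hkb), either measured (tabulated) or
## generated artificially.  All profiles share one evaluation contract,
## f(x, t) -> concentration, and downstream code never branches on
## provenance.

#' Set of external input profiles
#'
#' Named collection of evaluable concentration surfaces f(x \% A--P, t min)
#' for the external input genes of a circuit, each tagged with its
#' provenance ("measured" or "artificial").  Profiles must be non-negative
#' over the trunk and the simulated time span.
#'
#' @slot funs named list of functions f(x, t).
#' @slot provenance named character, "measured" or "artificial".
#' @export
setClass("ExternalInputSet",
  representation(funs = "list", provenance = "character"))

setValidity("ExternalInputSet", function(object) {
  msg <- character()
  if (length(object@funs) &&
      (is.null(names(object@funs)) || any(names(object@funs) == "")))
    msg <- c(msg, "profiles must be named by input gene")
  if (!all(vapply(object@funs, is.function, logical(1))))
    msg <- c(msg, "profiles must be functions f(x, t)")
  if (length(object@provenance) != length(object@funs))
    msg <- c(msg, "one provenance tag per profile is required")
  if (length(msg)) msg else TRUE
})

#' Create an external input set
#'
#' @param funs named list of profile functions f(x, t).
#' @param provenance character vector ("measured"/"artificial"), recycled.
#' @return An [ExternalInputSet-class].
#' @export
externalInputSet <- function(funs = list(), provenance = "artificial") {
  new("ExternalInputSet", funs = funs,
      provenance = setNames(rep_len(provenance, length(funs)), names(funs)))
}

setMethod("show", "ExternalInputSet", function(object) {
  cat("ExternalInputSet:", length(object@funs), "inputs\n")
  for (nm in names(object@funs))
    cat("  ", nm, " (", object@provenance[[nm]], ")\n", sep = "")
})

#' Evaluate all input profiles on a set of positions
#'
#' @param inputs an [ExternalInputSet-class].
#' @param x nucleus positions (\% A--P).
#' @param t time (min).
#' @return input x position concentration matrix (inputs in declared order).
#' @export
evaluateInputs <- function(inputs, x, t) {
  M <- length(inputs@funs)
  out <- matrix(0, M, length(x),
                dimnames = list(names(inputs@funs), NULL))
  for (m in seq_len(M)) {
    v <- inputs@funs[[m]](x, t)
    if (any(!is.finite(v)) || any(v < 0))
      stop("input profile '", names(inputs@funs)[m],
           "' returned negative or non-finite values")
    out[m, ] <- v
  }
  out
}

## ---------------------------------------------------------------------------
## artificial generators
## ---------------------------------------------------------------------------

#' Fit a time-independent exponential anterior gradient
#'
#' Pools all samples across time and space and fits f(x) = A exp(-x/L) by
#' least squares in linear space (positive samples only; a log-linear fit
#' provides starting values, and is returned directly with
#' \code{logSpace = TRUE}).  The resulting profile is constant in time, as
#' appropriate for the Bcd gradient over the modelled interval.
#'
#' @param samples data frame with columns \code{x} (\% A--P) and
#'   \code{conc}; a \code{t} column may be present and is ignored (pooled).
#' @param logSpace fit in log space instead.
#' @return a profile function f(x, t) with attribute \code{coef} = c(A, L).
#' @export
fitBcdExponential <- function(samples, logSpace = FALSE) {
  s <- samples[is.finite(samples$conc) & samples$conc > 0, , drop = FALSE]
  if (nrow(s) < 3L || length(unique(s$x)) < 2L)
    stop("need at least 3 positive samples spanning 2 distinct positions")
  start <- lm(log(conc) ~ x, data = s)
  A0 <- unname(exp(coef(start)[1])); L0 <- unname(-1 / coef(start)[2])
  if (!is.finite(L0) || L0 <= 0)
    stop("samples do not decay with x; cannot fit an anterior gradient")
  if (logSpace) {
    A <- A0; L <- L0
  } else {
    fit <- minpack.lm::nlsLM(conc ~ A * exp(-x / L), data = s,
                             start = list(A = A0, L = L0))
    cf <- coef(fit)
    A <- cf[["A"]]; L <- cf[["L"]]
  }
  if (A <= 0) stop("fitted amplitude is not positive")
  f <- function(x, t) A * exp(-x / L)
  attr(f, "coef") <- c(A = A, L = L)
  f
}

#' Artificial posterior Cad gradient
#'
#' Smooth concentration surface over (x, t) built from the three salient
#' features of the Caudal protein pattern: (1) a posterior gradient
#' complementary (anti-correlated) to the anterior Bcd gradient, (2)
#' expression in the abdominal region (~50--80\% A--P) decaying as
#' development progresses, and (3) a posterior stripe around 80\% A--P
#' appearing from time class T6 onwards.  The surface is a mirrored
#' exponential gradient times a smooth abdominal decay window, plus a
#' Gaussian stripe ramped in at the onset time.
#'
#' @param features named list overriding any of: \code{amplitude} (200),
#'   \code{L} (decay length, 20\% A--P), \code{decayMax} (0.5),
#'   \code{decayWindow} (c(50, 80)), \code{stripeCenter} (80),
#'   \code{stripeWidth} (2.5), \code{stripeAmp} (100), \code{stripeOnset}
#'   (55.475 min, T6), \code{tEnd} (71.1).
#' @param schedule optional [DivisionSchedule-class]; if given, the stripe
#'   onset must lie within its data-time span.
#' @return a profile function f(x, t).
#' @export
buildCadProfile <- function(features = list(), schedule = NULL) {
  f <- utils::modifyList(list(
    amplitude = 200, L = 20, decayMax = 0.5, decayWindow = c(50, 80),
    stripeCenter = 80, stripeWidth = 2.5, stripeAmp = 100,
    stripeOnset = 55.475, tEnd = 71.1), features)
  if (!is.null(schedule)) {
    dt <- dataTimes(schedule)
    if (f$stripeOnset < min(dt) || f$stripeOnset > max(dt))
      stop("stripe onset ", f$stripeOnset,
           " lies outside the data times [", min(dt), ", ", max(dt), "]")
  }
  w <- f$decayWindow
  function(x, t) {
    base <- f$amplitude * exp(-(100 - x) / f$L)
    bump <- ifelse(x >= w[1] & x <= w[2],
                   sin(pi * (x - w[1]) / (w[2] - w[1]))^2, 0)
    decay <- 1 - f$decayMax * pmin(1, t / f$tEnd) * bump
    ramp <- ifelse(t < f$stripeOnset, 0,
                   pmin(1, 0.5 + 0.5 * (t - f$stripeOnset) /
                          max(f$tEnd - f$stripeOnset, 1e-9)))
    stripe <- f$stripeAmp * ramp *
      exp(-(x - f$stripeCenter)^2 / (2 * f$stripeWidth^2))
    base * decay + stripe
  }
}

#' Time-invariant profile from boundaries pooled over time
#'
#' Averages each boundary's anchor positions across all cleavage cycles and
#' time classes (arithmetic mean per boundary id) and assembles the
#' resulting mean boundaries into a single expression profile that is
#' constant in time.  Used for the terminal gap genes \emph{tll} and
#' \emph{hkb}, whose patterns change little over the modelled interval.
#'
#' @param annotations boundary annotation data frame for one gene, possibly
#'   spanning several time classes.
#' @param amplitude concentration scale of the profile (default 200,
#'   matching the x200 gap-gene scale).
#' @return a profile function f(x, t).
#' @export
timeInvariantProfile <- function(annotations, amplitude = 200) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("at least one boundary observation is required")
  avg <- do.call(rbind, lapply(split(annotations, annotations$boundary_id),
                               function(d)
    data.frame(embryo_id = "mean", gene = d$gene[1],
               time_class = "all", boundary_id = d$boundary_id[1],
               polarity = d$polarity[1],
               x0 = mean(d$x0), y0 = mean(d$y0),
               x2 = mean(d$x2), y2 = mean(d$y2))))
  splines <- splinesFromAnnotations(avg)
  function(x, t) amplitude * .profileValue(splines, x)
}

#' Default artificial external input set
#'
#' Bcd as a time-constant anterior exponential, Cad from
#' [buildCadProfile()], and Tll/Hkb as time-invariant posterior profiles
#' with boundary positions typical of the terminal system (tll rising from
#' 74\% A--P, hkb from 88\%).  Amplitudes default to 200, the gap-gene
#' concentration scale.
#'
#' @param spec a [GeneNetworkSpec-class]; profiles are built for its
#'   external inputs.
#' @param config named list overriding \code{bcd.A}, \code{bcd.L},
#'   \code{cad} (feature list), \code{tll.x0}, \code{hkb.x0},
#'   \code{amplitude}, \code{width}.
#' @return An [ExternalInputSet-class].
#' @export
artificialInputs <- function(spec = geneNetworkSpec(), config = list()) {
  cfg <- utils::modifyList(list(
    bcd.A = 200 * exp(35 / 20), bcd.L = 20, cad = list(),
    tll.x0 = 74, hkb.x0 = 88, amplitude = 200, width = 5), config)
  mk <- list(
    bcd = function() {
      A <- cfg$bcd.A; L <- cfg$bcd.L
      function(x, t) A * exp(-x / L)
    },
    cad = function() buildCadProfile(cfg$cad),
    tll = function() {
      b <- data.frame(embryo_id = "mean", gene = "tll", time_class = "all",
                      boundary_id = "tll.posterior.A", polarity = "rising",
                      x0 = cfg$tll.x0, y0 = 0, x2 = cfg$tll.x0 + cfg$width,
                      y2 = 1)
      timeInvariantProfile(b, cfg$amplitude)
    },
    hkb = function() {
      b <- data.frame(embryo_id = "mean", gene = "hkb", time_class = "all",
                      boundary_id = "hkb.posterior.A", polarity = "rising",
                      x0 = cfg$hkb.x0, y0 = 0, x2 = cfg$hkb.x0 + cfg$width,
                      y2 = 1)
      timeInvariantProfile(b, cfg$amplitude)
    })
  wanted <- externalInputs(spec)
  missing <- setdiff(wanted, names(mk))
  if (length(missing))
    stop("no artificial generator for input(s): ",
         paste(missing, collapse = ", "))
  externalInputSet(setNames(lapply(wanted, function(nm) mk[[nm]]()), wanted),
                   provenance = "artificial")
}

#' Read measured input profiles from a TSV table
#'
#' Expects columns \code{input_gene}, \code{time_min}, \code{ap_position},
#' \code{concentration}; each gene's profile is interpolated bilinearly in
#' position and time (constant extrapolation at the edges).
#'
#' @param path TSV file.
#' @return An [ExternalInputSet-class] with provenance "measured".
#' @export
readInputProfiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("input_gene", "time_min", "ap_position", "concentration")
  if (!all(need %in% colnames(df)))
    stop("input profile file must have columns ",
         paste(need, collapse = ", "))
  funs <- lapply(split(df, df$input_gene), function(d) {
    ts <- sort(unique(d$time_min))
    grids <- lapply(ts, function(tt) {
      s <- d[d$time_min == tt, ]
      s <- s[order(s$ap_position), ]
      list(x = s$ap_position, y = s$concentration)
    })
    function(x, t) {
      vals <- vapply(grids, function(g)
        approx(g$x, g$y, xout = x, rule = 2)$y, numeric(length(x)))
      if (length(ts) == 1L) return(as.numeric(vals))
      vals <- matrix(vals, nrow = length(x))
      apply(vals, 1, function(row) approx(ts, row, xout = t, rule = 2)$y)
    }
  })
  externalInputSet(funs, provenance = "measured")
}
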