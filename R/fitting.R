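## Model fitting: OLS/WLS cost, RMS reporting, global optimisation by the
## Lam-Delosme adaptive simulated annealing schedule, and automated quality
## control of solutions (solver sensitivity, brittleness, patterning-defect
## heuristics).

#' Result of a circuit fit
#'
#' @slot params the estimated [CircuitParameters-class] (masked entries at
#'   their fixed values).
#' @slot cost final cost S(theta-hat) under the fitting mode.
#' @slot rms unweighted root-mean-square residual.
#' @slot mode "OLS" or "WLS".
#' @slot seed integer seed of the optimisation run.
#' @slot trace data frame (eval, temperature, cost, best) recorded during
#'   annealing.
#' @slot qc list, populated by [qcScreen()].
#' @slot convergence list with optimiser diagnostics.
#' @export
setClass("FitResult",
  representation(params = "CircuitParameters", cost = "numeric",
                 rms = "numeric", mode = "character", seed = "integer",
                 trace = "data.frame", qc = "list", convergence = "list"))

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@mode, "): cost = ", signif(object@cost, 6),
      ", RMS = ", signif(object@rms, 6), ", seed = ", object@seed, "\n",
      sep = "")
})

#' @describeIn fitCircuit Estimated parameters of a fit.
#' @param fit a [FitResult-class].
#' @export
fittedParams <- function(fit) fit@params

## ---------------------------------------------------------------------------
## cost and RMS
## ---------------------------------------------------------------------------

## Build a fast objective closure around a prepared simulation problem.
## Returns a function(params) -> list(ok, model, S, sse).
.makeEvaluator <- function(spec, dataset, inputs, schedule, v0, lattice,
                           latticePost, solver, mode = c("WLS", "OLS")) {
  mode <- match.arg(mode)
  divides <- length(schedule@tDivision) > 0L
  if (is.null(lattice))
    lattice <- if (divides) buildLattice("C13", apRange(spec)) else
      stop("a lattice is required for schedules without division")
  if (divides && is.null(latticePost))
    latticePost <- buildLattice("C14A", apRange(spec))
  if (!divides) latticePost <- lattice
  segs <- .makeSegments(spec, schedule, inputs, lattice, latticePost, solver)
  y <- datasetValues(dataset)
  w <- if (mode == "OLS") array(1, dim(y)) else datasetWeights(dataset)
  if (is.null(v0)) {
    v0 <- matrix(0, length(gapGenes(spec)), nNuclei(lattice))
    rownames(v0) <- gapGenes(spec)
  }
  Nd <- length(y)
  function(params) {
    res <- .runCircuit(spec, params, segs, schedule, v0, solver)
    if (!res$ok)
      return(list(ok = FALSE, S = NA_real_, sse = NA_real_, msg = res$msg))
    m <- do.call(cbind, res$snaps)
    r <- m - y
    list(ok = TRUE, model = m, S = sum(w * r * r), sse = sum(r * r),
         Nd = Nd)
  }
}

#' Cost of a candidate circuit
#'
#' S(theta) = sum over time classes, nuclei and genes of
#' v (model - data)^2, the energy minimised during annealing.  With
#' \code{mode = "OLS"} all weights are forced to 1 and the cost is the
#' ordinary least-squares sum; with \code{mode = "WLS"} the dataset's
#' weights are used.  A failed simulation yields a large finite sentinel
#' (\code{penalty * N_d}) carrying attribute \code{failed = TRUE}, so
#' annealing can reject the move rather than abort.
#'
#' @param params a [CircuitParameters-class].
#' @param dataset an [ExpressionDataset-class].
#' @param inputs an [ExternalInputSet-class].
#' @param schedule a [DivisionSchedule-class] whose data times match the
#'   dataset's time classes.
#' @param mode "WLS" or "OLS".
#' @param v0 initial state (defaults to zeros).
#' @param lattice,latticePost lattices, as in [simulateCircuit()].
#' @param solver see [solverOptions()].
#' @param penalty sentinel cost multiplier for failed solves.
#' @return numeric cost.
#' @export
circuitCost <- function(params, dataset, inputs,
                        schedule = divisionSchedule(),
                        mode = c("WLS", "OLS"), v0 = NULL, lattice = NULL,
                        latticePost = NULL, solver = solverOptions(),
                        penalty = 1e6) {
  mode <- match.arg(mode)
  if (is.null(v0) && length(schedule@tDivision) > 0L)
    v0 <- initialConditions(dataset)
  ev <- .makeEvaluator(params@spec, dataset, inputs, schedule, v0, lattice,
                       latticePost, solver, mode)
  r <- ev(params)
  if (!r$ok) {
    out <- penalty * nDataPoints(dataset)
    attr(out, "failed") <- TRUE
    return(out)
  }
  r$S
}

#' Root-mean-square residual of a circuit
#'
#' RMS = sqrt(sum (model - data)^2 / N_d), always unweighted, so fits
#' obtained under different weighting schemes (and datasets with different
#' weights) remain comparable.
#'
#' @inheritParams circuitCost
#' @return numeric RMS.
#' @export
circuitRMS <- function(params, dataset, inputs,
                       schedule = divisionSchedule(), v0 = NULL,
                       lattice = NULL, latticePost = NULL,
                       solver = solverOptions()) {
  Nd <- nDataPoints(dataset)
  if (Nd == 0L) stop("dataset has no data points")
  if (is.null(v0) && length(schedule@tDivision) > 0L)
    v0 <- initialConditions(dataset)
  ev <- .makeEvaluator(params@spec, dataset, inputs, schedule, v0, lattice,
                       latticePost, solver, "OLS")
  r <- ev(params)
  if (!r$ok) stop("simulation failed: ", r$msg)
  sqrt(r$sse / Nd)
}

## ---------------------------------------------------------------------------
## bounds and configuration
## ---------------------------------------------------------------------------

#' Fitting configuration
#'
#' Search-space bounds and Lam-annealing controls.  Bounds are scale-free
#' defaults appropriate for the x200 concentration scale: regulatory
#' weights |w|, |e| <= 0.3, synthesis R in (0, 30], decay lambda in
#' [0.005, 0.3] /min (protein/mRNA half-lives of minutes to hours),
#' diffusion D in [0, 0.3] /min.
#'
#' Annealing controls: \code{maxEvals} total energy evaluations,
#' \code{warmup} accept-all moves used to estimate the initial temperature,
#' \code{targetAcceptance} the acceptance ratio the Lam schedule tracks
#' after warm-up, \code{lamRate} the schedule's quality factor,
#' \code{moveScale} the initial per-parameter move size as a fraction of the
#' bound range, \code{refineEvals} a Nelder-Mead polish budget after
#' annealing, \code{penalty} the sentinel cost multiplier for failed
#' solves.
#'
#' @param ... overrides of any default element.
#' @return named list.
#' @export
fitConfig <- function(...) {
  cfg <- list(
    bounds = list(w = 0.3, e = 0.3, R = c(0.5, 30), D = c(0, 0.3),
                  lambda = c(0.005, 0.3), h = c(-5, 5)),
    maxEvals = 4000, warmup = 150, targetAcceptance = 0.44,
    lamRate = 0.05, moveScale = 0.1, scaleAdaptEvery = 50,
    refineEvals = 500, penalty = 1e6)
  utils::modifyList(cfg, list(...))
}

#' Lower/upper bounds for the free parameters of a circuit
#'
#' @param params a [CircuitParameters-class].
#' @param config a [fitConfig()] list.
#' @return list with named numeric vectors \code{lower} and \code{upper}
#'   aligned with [freeParams()].
#' @export
paramBounds <- function(params, config = fitConfig()) {
  nm <- names(freeParams(params))
  b <- config$bounds
  lower <- upper <- setNames(numeric(length(nm)), nm)
  kind <- sub("\\..*$", "", nm)
  lower[kind == "W"] <- -b$w; upper[kind == "W"] <- b$w
  lower[kind == "E"] <- -b$e; upper[kind == "E"] <- b$e
  lower[kind == "R"] <- b$R[1]; upper[kind == "R"] <- b$R[2]
  lower[kind == "D"] <- b$D[1]; upper[kind == "D"] <- b$D[2]
  lower[kind == "lambda"] <- b$lambda[1]; upper[kind == "lambda"] <- b$lambda[2]
  lower[kind == "h"] <- b$h[1]; upper[kind == "h"] <- b$h[2]
  list(lower = lower, upper = upper)
}

## ---------------------------------------------------------------------------
## Lam-Delosme adaptive simulated annealing
## ---------------------------------------------------------------------------

#' Adaptive simulated annealing with the Lam schedule
#'
#' Minimises \code{fn} over a box.  Moves perturb one randomly chosen
#' coordinate by a Gaussian step (reflected into the bounds); per-coordinate
#' move scales adapt towards the target acceptance ratio.  After an
#' accept-all warm-up that estimates the energy scale, the inverse
#' temperature follows the Lam-Delosme update
#' dS = lamRate * 4 rho (1 - rho)^2 / ((2 - rho)^2 S^2 sigma^3),
#' with rho the smoothed acceptance ratio and sigma the smoothed energy
#' standard deviation, which tracks the maximum-entropy-reduction
#' trajectory.  As the temperature falls the dynamics reduce to greedy
#' descent.  Runs are deterministic given \code{seed}.  An optional
#' Nelder-Mead polish refines the best point found.
#'
#' @param fn objective, called with a numeric vector; may return Inf/NA for
#'   infeasible points (treated as rejected).
#' @param x0 start vector (within bounds).
#' @param lower,upper bounds.
#' @param config a [fitConfig()] list (annealing elements used).
#' @param seed integer RNG seed.
#' @return list with \code{par}, \code{value}, \code{evals}, \code{trace}
#'   (data frame), \code{accepted}.
#' @export
lamAnneal <- function(fn, x0, lower, upper, config = fitConfig(), seed = 1L) {
  set.seed(seed)
  n <- length(x0)
  rng <- upper - lower
  x <- pmin(upper, pmax(lower, x0))
  scl <- rep(config$moveScale, n)
  reflect <- function(v, lo, hi) {
    if (hi <= lo) return(lo)
    while (v < lo || v > hi) {
      if (v < lo) v <- 2 * lo - v
      if (v > hi) v <- 2 * hi - v
    }
    v
  }
  safe <- function(z) {
    e <- fn(z)
    if (!is.finite(e)) Inf else e
  }
  E <- safe(x)
  evals <- 1L
  best <- x; bestE <- E           # track the best point from the start
  ## warm-up: accept every feasible move, estimate the energy scale
  warmE <- E
  nAccepted <- 0L
  for (k in seq_len(config$warmup)) {
    j <- sample.int(n, 1L)
    xp <- x; xp[j] <- reflect(x[j] + scl[j] * rng[j] * rnorm(1L),
                              lower[j], upper[j])
    Ep <- safe(xp); evals <- evals + 1L
    if (is.finite(Ep)) {
      x <- xp; E <- Ep
      warmE <- c(warmE, Ep)
      nAccepted <- nAccepted + 1L
      if (E < bestE) { best <- x; bestE <- E }
    }
  }
  if (nAccepted == 0L)
    stop("no move was accepted during warm-up; ",
         "widen or shrink the move scale (config$moveScale)")
  sigma <- max(sd(warmE[is.finite(warmE)]), 1e-12)
  S <- 1 / max(sigma, 1e-12)      # inverse temperature
  rho <- 0.8                      # smoothed acceptance ratio
  muE <- E; varE <- sigma^2       # smoothed energy statistics
  aAcc <- rep(1, n); aTry <- rep(2, n)
  alpha <- 0.02                   # smoothing weight for schedule statistics
  traceEvery <- max(1L, (config$maxEvals %/% 200L))
  tr <- list()
  while (evals < config$maxEvals) {
    j <- sample.int(n, 1L)
    xp <- x; xp[j] <- reflect(x[j] + scl[j] * rng[j] * rnorm(1L),
                              lower[j], upper[j])
    Ep <- safe(xp); evals <- evals + 1L
    dE <- Ep - E
    acc <- is.finite(Ep) && (dE <= 0 || runif(1L) < exp(-dE * S))
    aTry[j] <- aTry[j] + 1
    if (acc) {
      x <- xp; E <- Ep
      aAcc[j] <- aAcc[j] + 1
      if (E < bestE) { best <- x; bestE <- E }
    }
    rho <- (1 - alpha) * rho + alpha * as.numeric(acc)
    if (is.finite(Ep)) {
      muE <- (1 - alpha) * muE + alpha * Ep
      varE <- (1 - alpha) * varE + alpha * (Ep - muE)^2
    }
    sigma <- sqrt(max(varE, 1e-24))
    dS <- config$lamRate * 4 * rho * (1 - rho)^2 /
      ((2 - rho)^2 * S^2 * sigma^3)
    S <- S + min(dS, 0.5 * S)     # cap to keep the schedule stable
    if (evals %% config$scaleAdaptEvery == 0L) {
      rj <- aAcc / aTry
      scl <- pmin(2, pmax(1e-5, scl * exp(rj - config$targetAcceptance)))
      aAcc <- rep(1, n); aTry <- rep(2, n)
    }
    if (evals %% traceEvery == 0L)
      tr[[length(tr) + 1L]] <- c(evals, 1 / S, E, bestE)
  }
  ## greedy polish of the best point (box kept by large-penalty wrapper)
  if (config$refineEvals > 0L) {
    pen <- function(z) {
      if (any(z < lower) || any(z > upper)) return(bestE + 1e8 * (1 +
        sum(pmax(0, lower - z) + pmax(0, z - upper))))
      safe(z)
    }
    opt <- optim(best, pen, method = "Nelder-Mead",
                 control = list(maxit = config$refineEvals,
                                parscale = pmax(rng, 1e-8)))
    evals <- evals + opt$counts[1]
    if (is.finite(opt$value) && opt$value < bestE) {
      best <- pmin(upper, pmax(lower, opt$par)); bestE <- opt$value
    }
  }
  trace <- as.data.frame(do.call(rbind, tr))
  if (nrow(trace)) colnames(trace) <- c("eval", "temperature", "cost", "best")
  list(par = setNames(best, names(x0)), value = bestE, evals = evals,
       trace = trace, accepted = nAccepted)
}

## ---------------------------------------------------------------------------
## fit driver
## ---------------------------------------------------------------------------

#' Fit a gene circuit to an expression dataset
#'
#' Global optimisation of all free circuit parameters by Lam-schedule
#' simulated annealing (see [lamAnneal()]) under the OLS or WLS cost.
#' Masked parameters are held at their fixed values throughout.  Failed
#' simulations receive a large finite penalty cost so the annealer simply
#' rejects them.  Deterministic given \code{seed}.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param inputs an [ExternalInputSet-class].
#' @param spec a [GeneNetworkSpec-class].
#' @param schedule a [DivisionSchedule-class] matching the dataset.
#' @param mode "WLS" or "OLS".
#' @param config a [fitConfig()] list.
#' @param seed integer seed.
#' @param params0 optional start [CircuitParameters-class]; defaults to a
#'   random circuit drawn within the bounds.
#' @param v0 initial state matrix; defaults to
#'   [initialConditions()] of the dataset when the schedule divides, else
#'   zeros.
#' @param lattice,latticePost lattices, as in [simulateCircuit()].
#' @param solver see [solverOptions()].
#' @param optimizer "lam" (default) or a function with the signature of
#'   [lamAnneal()], allowing alternative global optimisers behind the same
#'   contract.
#' @return A [FitResult-class].
#' @export
fitCircuit <- function(dataset, inputs, spec = geneNetworkSpec(),
                       schedule = divisionSchedule(),
                       mode = c("WLS", "OLS"), config = fitConfig(),
                       seed = 1L, params0 = NULL, v0 = NULL, lattice = NULL,
                       latticePost = NULL, solver = solverOptions(),
                       optimizer = "lam") {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  if (is.null(params0))
    params0 <- randomCircuit(spec, config, seed = seed)
  if (is.null(v0) && length(schedule@tDivision) > 0L)
    v0 <- initialConditions(dataset)
  ev <- .makeEvaluator(spec, dataset, inputs, schedule, v0, lattice,
                       latticePost, solver, mode)
  Nd <- nDataPoints(dataset)
  template <- params0
  energy <- function(theta) {
    p <- updateFreeParams(template, theta)
    r <- ev(p)
    if (!r$ok) config$penalty * Nd else r$S
  }
  b <- paramBounds(params0, config)
  theta0 <- pmin(b$upper, pmax(b$lower, freeParams(params0)))
  engine <- if (identical(optimizer, "lam")) lamAnneal else optimizer
  opt <- engine(energy, theta0, b$lower, b$upper, config, seed)
  params <- updateFreeParams(template, opt$par)
  r <- ev(params)
  rms <- if (r$ok) sqrt(r$sse / Nd) else NA_real_
  new("FitResult", params = params, cost = opt$value, rms = rms,
      mode = mode, seed = seed, trace = opt$trace, qc = list(),
      convergence = list(evals = opt$evals))
}

## ---------------------------------------------------------------------------
## quality control
## ---------------------------------------------------------------------------

#' Automated quality control of a fitted circuit
#'
#' Screens a solution for (1) solver sensitivity: the maximum absolute
#' change of any sampled concentration when the integration tolerances are
#' tightened tenfold; (2) brittleness: the maximum RMS change under a
#' +/-0.1\% perturbation of each free parameter; and (3) patterning
#' defects, replacing visual inspection with per-gene, per-time heuristics:
#' a missing domain (model below \code{missingFrac} of the slice data
#' maximum wherever data exceed \code{highFrac} of it), an ectopic domain
#' (model above \code{highFrac} wherever data are below
#' \code{missingFrac}), and a wrong domain order (the A--P ranking of gene
#' expression peaks differs between model and data).
#'
#' @param fit a [FitResult-class] or [CircuitParameters-class].
#' @param dataset,inputs,schedule as in [circuitCost()].
#' @param v0,lattice,latticePost,solver simulation context.
#' @param thresholds list with \code{missingFrac} (0.1), \code{highFrac}
#'   (0.5), \code{sensitivity} (allowed solver sensitivity, 1.0),
#'   \code{brittleness} (allowed RMS change, 1.0).
#' @return list (class \code{qcReport}) with \code{solver_sensitivity},
#'   \code{brittleness}, \code{defects} (data frame), and logical
#'   \code{pass}.
#' @export
qcScreen <- function(fit, dataset, inputs, schedule = divisionSchedule(),
                     v0 = NULL, lattice = NULL, latticePost = NULL,
                     solver = solverOptions(),
                     thresholds = list(missingFrac = 0.1, highFrac = 0.5,
                                       sensitivity = 1.0,
                                       brittleness = 1.0)) {
  params <- if (is(fit, "FitResult")) fit@params else fit
  spec <- params@spec
  if (is.null(v0) && length(schedule@tDivision) > 0L)
    v0 <- initialConditions(dataset)
  ev <- .makeEvaluator(spec, dataset, inputs, schedule, v0, lattice,
                       latticePost, solver, "OLS")
  base <- ev(params)
  if (!base$ok) stop("solution cannot be simulated: ", base$msg)
  Nd <- nDataPoints(dataset)
  rms0 <- sqrt(base$sse / Nd)
  ## solver sensitivity
  tight <- solver; tight$rtol <- solver$rtol / 10; tight$atol <- solver$atol / 10
  evT <- .makeEvaluator(spec, dataset, inputs, schedule, v0, lattice,
                        latticePost, tight, "OLS")
  rT <- evT(params)
  sens <- if (rT$ok) max(abs(rT$model - base$model)) else Inf
  ## brittleness
  theta <- freeParams(params)
  brittle <- 0
  for (j in seq_along(theta)) {
    for (sgn in c(-1, 1)) {
      th <- theta
      th[j] <- th[j] * (1 + sgn * 0.001)
      rp <- ev(updateFreeParams(params, th))
      d <- if (rp$ok) abs(sqrt(rp$sse / Nd) - rms0) else Inf
      brittle <- max(brittle, d)
    }
  }
  ## defect heuristics
  cd <- SummarizedExperiment::colData(dataset)
  y <- datasetValues(dataset)
  genes <- rownames(y)
  rows <- list()
  for (lab in unique(cd$time_class)) {
    cols <- which(cd$time_class == lab)
    for (g in genes) {
      dat <- y[g, cols]; mod <- base$model[g, cols]
      mx <- max(dat)
      if (mx <= 0) next
      missing <- any(dat > thresholds$highFrac * mx &
                       mod < thresholds$missingFrac * mx)
      ectopic <- any(dat < thresholds$missingFrac * mx &
                       mod > thresholds$highFrac * mx)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, time_class = lab, missing = missing,
                   ectopic = ectopic, order_violation = FALSE)
    }
    ## domain order: ranking of peak positions across genes
    expressed <- genes[apply(y[, cols, drop = FALSE], 1, max) > 0]
    if (length(expressed) > 1L) {
      pkD <- vapply(expressed, function(g)
        cd$ap_position[cols][which.max(y[g, cols])], numeric(1))
      pkM <- vapply(expressed, function(g)
        cd$ap_position[cols][which.max(base$model[g, cols])], numeric(1))
      orderOK <- identical(order(pkD), order(pkM))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = "(all)", time_class = lab, missing = FALSE,
                   ectopic = FALSE, order_violation = !orderOK)
    }
  }
  defects <- do.call(rbind, rows)
  anyDefect <- any(defects$missing) || any(defects$ectopic) ||
    any(defects$order_violation)
  out <- list(solver_sensitivity = sens, brittleness = brittle,
              defects = defects,
              pass = sens <= thresholds$sensitivity &&
                brittle <= thresholds$brittleness && !anyDefect)
  class(out) <- "qcReport"
  out
}

#' @export
print.qcReport <- function(x, ...) {
  cat("QC report: solver sensitivity =", signif(x$solver_sensitivity, 4),
      ", brittleness =", signif(x$brittleness, 4),
      ", defects =", sum(x$defects$missing | x$defects$ectopic |
                           x$defects$order_violation),
      "->", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
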