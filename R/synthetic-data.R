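## Ground-truth circuits and noisy pseudo-data with the structure the
## method assumes: simulate a known circuit, add concentration noise,
## extract boundary positions per pseudo-embryo, and run end-to-end
## parameter-recovery experiments -- all without any external data.

#' Synthetic data scenario
#'
#' Bundles everything needed to generate pseudo-data from a known circuit:
#' the network spec, lattice, schedule, external inputs, the ground-truth
#' parameters, and the noise model (additive Gaussian concentration noise
#' with standard deviation \code{sigma} as a fraction of the maximum
#' concentration; boundary-position jitter \code{jitterX} in \% A--P per
#' pseudo-embryo).
#'
#' @slot spec,lattice,schedule,inputs,truth the circuit definition.
#' @slot sigma concentration noise level (fraction of max).
#' @slot jitterX boundary jitter SD (\% A--P).
#' @slot embryos pseudo-embryos per boundary.
#' @slot threshold boundary extraction threshold (fraction of slice max).
#' @slot width boundary spline width emitted in annotations (\% A--P).
#' @export
setClass("SyntheticScenario",
  representation(spec = "GeneNetworkSpec", lattice = "NucleusLattice",
                 schedule = "DivisionSchedule", inputs = "ExternalInputSet",
                 truth = "CircuitParameters", sigma = "numeric",
                 jitterX = "numeric", embryos = "integer",
                 threshold = "numeric", width = "numeric"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
  if (object@jitterX < 0) msg <- c(msg, "jitterX must be non-negative")
  if (object@embryos < 1L) msg <- c(msg, "need at least one pseudo-embryo")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", length(gapGenes(object@spec)), "genes,",
      nNuclei(object@lattice), "nuclei,",
      length(dataTimes(object@schedule)), "time points, sigma =",
      object@sigma, "\n")
})

#' @rdname SyntheticScenario-class
#' @param spec,lattice,schedule,inputs,truth circuit definition components.
#' @param sigma,jitterX,embryos,threshold,width noise model settings.
#' @export
syntheticScenario <- function(spec, lattice, schedule, inputs, truth,
                              sigma = 0.05, jitterX = 1, embryos = 6L,
                              threshold = 0.5, width = 5) {
  new("SyntheticScenario", spec = spec, lattice = lattice,
      schedule = schedule, inputs = inputs, truth = truth, sigma = sigma,
      jitterX = jitterX, embryos = as.integer(embryos),
      threshold = threshold, width = width)
}

#' The standard two-gene recovery benchmark
#'
#' A reduced scenario sized so a full recovery experiment runs in minutes
#' on one CPU: two genes with mutual repression and auto-activation, two
#' complementary exponential external gradients (an anterior "bcd"-like and
#' a posterior "cad"-like input, each activating one gene), 20 nuclei
#' across the 35--87\% trunk, five data time points over 50 minutes, no
#' division.  The ground-truth parameters produce two sharp, mutually
#' exclusive expression domains with a mid-trunk interface.
#'
#' @param sigma concentration noise level (default 0.05).
#' @return A [SyntheticScenario-class].
#' @export
benchScenario <- function(sigma = 0.05) {
  spec <- geneNetworkSpec(gapGenes = c("gA", "gB"),
                          externalInputs = c("bcd", "cad"),
                          apRange = c(35, 87))
  lattice <- customLattice(20, c(35, 87))
  schedule <- divisionSchedule(tStart = 0, tEnd = 50, mitosis = numeric(0),
                               tDivision = numeric(0),
                               dataTimes = c(S1 = 10, S2 = 20, S3 = 30,
                                             S4 = 40, S5 = 50))
  inputs <- externalInputSet(list(
    bcd = function(x, t) 200 * exp(-(x - 35) / 12),
    cad = function(x, t) 200 * exp(-(87 - x) / 12)),
    provenance = "artificial")
  truth <- circuitParameters(
    spec,
    W = matrix(c(0.05, -0.1, -0.1, 0.05), 2, 2),
    E = matrix(c(0.08, 0, 0, 0.08), 2, 2),
    R = c(15, 12), D = c(0.1, 0.1), lambda = c(0.08, 0.09), h = -2.5)
  syntheticScenario(spec, lattice, schedule, inputs, truth, sigma = sigma)
}

#' Draw a random circuit within the fitting bounds
#'
#' Free parameters are drawn uniformly within the bounds of
#' \code{config}; masked parameters keep their canonical fixed values
#' (h = -2.5; Hkb weights 0 except on \emph{hb}).  Deterministic per seed.
#'
#' @param spec a [GeneNetworkSpec-class] or [SyntheticScenario-class].
#' @param config a [fitConfig()] list (bounds used).
#' @param seed integer seed.
#' @return A [CircuitParameters-class].
#' @export
randomCircuit <- function(spec, config = fitConfig(), seed = 1L) {
  if (is(spec, "SyntheticScenario")) spec <- spec@spec
  set.seed(seed)
  template <- circuitParameters(spec)
  b <- paramBounds(template, config)
  theta <- b$lower + runif(length(b$lower)) * (b$upper - b$lower)
  updateFreeParams(template, theta)
}

#' Extract boundary positions from an expression profile
#'
#' Linear-interpolated crossings of \code{threshold} times the profile
#' maximum, labelled rising or falling by the local slope -- the
#' pseudo-embryo analogue of the 50\%-maximum boundary convention used for
#' quantified protein data.
#'
#' @param values per-nucleus expression values.
#' @param positions matching \% A--P positions.
#' @param threshold fraction of the profile maximum (default 0.5).
#' @return data frame with columns \code{x} and \code{polarity} (possibly
#'   zero rows).
#' @export
extractBoundaries <- function(values, positions, threshold = 0.5) {
  mx <- max(values)
  out <- data.frame(x = numeric(0), polarity = character(0))
  if (mx <= 0) return(out)
  thr <- threshold * mx
  d <- values - thr
  for (i in seq_len(length(values) - 1L)) {
    if (d[i] == 0) d[i] <- 1e-12   # nudge exact hits off zero
    if (d[i] * d[i + 1L] < 0) {
      x <- positions[i] + (positions[i + 1L] - positions[i]) *
        (thr - values[i]) / (values[i + 1L] - values[i])
      out <- rbind(out, data.frame(
        x = x,
        polarity = if (values[i + 1L] > values[i]) "rising" else "falling"))
    }
  }
  out
}

#' Generate a noisy pseudo-dataset from a known circuit
#'
#' Simulates \code{params} under the scenario, samples at the data times,
#' adds Gaussian concentration noise (SD = sigma x maximum concentration,
#' clamped at zero), and derives WLS weights from the normalised noisy
#' values.  Boundary annotations are extracted from the noiseless profiles
#' at the scenario threshold and jittered independently per pseudo-embryo
#' (SD \code{jitterX} \% A--P), emitting the same annotation schema as real
#' input data.  Deterministic per seed.
#'
#' @param params ground-truth [CircuitParameters-class] (defaults to the
#'   scenario's).
#' @param scenario a [SyntheticScenario-class].
#' @param seed integer seed.
#' @param epsilon weight regulariser.
#' @return list with \code{dataset} (an [ExpressionDataset-class]),
#'   \code{annotations} (data frame) and \code{trajectory}.
#' @export
synthDataset <- function(scenario, params = scenario@truth, seed = 1L,
                         epsilon = 0.1) {
  set.seed(seed)
  traj <- simulateCircuit(params, scenario@inputs, scenario@schedule,
                          lattice = scenario@lattice,
                          latticePost = scenario@lattice)
  m <- sampleAt(traj)
  mx <- max(m)
  noisy <- m + rnorm(length(m), sd = scenario@sigma * mx)
  noisy[noisy < 0] <- 0
  dts <- dataTimes(scenario@schedule)
  N <- nNuclei(scenario@lattice)
  genes <- gapGenes(scenario@spec)
  slices <- lapply(seq_along(dts), function(k) {
    cols <- ((k - 1L) * N + 1L):(k * N)
    vals <- noisy[, cols, drop = FALSE]
    yhat <- if (mx > 0) vals / mx else vals
    list(label = names(dts)[k], time = dts[[k]],
         lattice = scenario@lattice, values = vals,
         weights = makeWeights(yhat, epsilon))
  })
  ds <- expressionDataset(slices, genes)
  ## annotations from the noiseless profiles, jittered per pseudo-embryo
  pos <- nucleusPositions(scenario@lattice)
  ann <- list()
  for (k in seq_along(dts)) {
    cols <- ((k - 1L) * N + 1L):(k * N)
    for (g in genes) {
      bd <- extractBoundaries(m[g, cols], pos, scenario@threshold)
      if (!nrow(bd)) next
      for (b in seq_len(nrow(bd))) {
        for (e in seq_len(scenario@embryos)) {
          x0 <- bd$x[b] + rnorm(1L, sd = scenario@jitterX)
          w <- scenario@width
          x2 <- if (bd$polarity[b] == "rising") x0 + w else x0 - w
          ann[[length(ann) + 1L]] <- data.frame(
            embryo_id = paste0("sim", e), gene = g,
            time_class = names(dts)[k],
            boundary_id = paste(g, "d", b, sep = "."),
            polarity = bd$polarity[b], x0 = x0, y0 = 0, x2 = x2, y2 = 1)
        }
      }
    }
  }
  list(dataset = ds,
       annotations = if (length(ann)) do.call(rbind, ann) else NULL,
       trajectory = traj)
}

#' End-to-end parameter recovery experiment
#'
#' For each run: generate a noisy pseudo-dataset from the scenario's
#' ground-truth circuit, fit a circuit to it from a random start, and
#' compare the recovered parameters against the truth.  Reports the sign
#' agreement of the free gap-gap weights (entries with |true| > 0), the
#' RMS of the estimate versus the truth on the same noisy data, and the
#' QC pass rate.  With \code{shuffle = TRUE} each gene's spatial profile
#' is randomly permuted within every time class before fitting -- a
#' negative control whose sign agreement should be at chance.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param config a [fitConfig()] list.
#' @param nRuns number of seeded runs.
#' @param seed base seed; run i uses dataset seed \code{seed + i} and fit
#'   seed \code{seed + 1000 + i}.
#' @param shuffle destroy spatial structure (negative control)?
#' @param qc run [qcScreen()] on each fit (slower)?
#' @return list (class \code{recoveryReport}) with per-run data frame
#'   \code{runs} and aggregate \code{signAgreement}.
#' @export
recoveryExperiment <- function(scenario, config = fitConfig(), nRuns = 10,
                               seed = 1L, shuffle = FALSE, qc = FALSE) {
  truth <- scenario@truth
  wTrueAll <- freeParams(truth)
  isW <- grepl("^W\\.", names(wTrueAll))
  runs <- list()
  for (i in seq_len(nRuns)) {
    sd <- synthDataset(scenario, seed = seed + i)
    ds <- sd$dataset
    if (shuffle) {
      set.seed(seed + 500L + i)
      v <- datasetValues(ds); w <- datasetWeights(ds)
      cd <- SummarizedExperiment::colData(ds)
      for (lab in unique(cd$time_class)) {
        cols <- which(cd$time_class == lab)
        for (g in seq_len(nrow(v))) {
          prm <- sample(cols)
          v[g, cols] <- v[g, prm]; w[g, cols] <- w[g, prm]
        }
      }
      SummarizedExperiment::assay(ds, "value") <- v
      SummarizedExperiment::assay(ds, "weight") <- w
    }
    fit <- fitCircuit(ds, scenario@inputs, scenario@spec,
                      scenario@schedule, mode = "WLS", config = config,
                      seed = seed + 1000L + i,
                      lattice = scenario@lattice,
                      latticePost = scenario@lattice)
    wHat <- freeParams(fit@params)[isW]
    wTrue <- wTrueAll[isW]
    cmp <- abs(wTrue) > 0
    agree <- mean(sign(wHat[cmp]) == sign(wTrue[cmp]))
    rmsTruth <- circuitRMS(truth, ds, scenario@inputs, scenario@schedule,
                           lattice = scenario@lattice,
                           latticePost = scenario@lattice)
    qcPass <- if (qc)
      qcScreen(fit, ds, scenario@inputs, scenario@schedule,
               lattice = scenario@lattice,
               latticePost = scenario@lattice)$pass else NA
    runs[[i]] <- data.frame(run = i, signAgreement = agree,
                            rmsHat = fit@rms, rmsTruth = rmsTruth,
                            cost = fit@cost, qcPass = qcPass)
  }
  runs <- do.call(rbind, runs)
  out <- list(runs = runs, signAgreement = mean(runs$signAgreement),
              nW = sum(isW & abs(wTrueAll) > 0))
  class(out) <- "recoveryReport"
  out
}

#' @export
print.recoveryReport <- function(x, ...) {
  cat("Recovery experiment over", nrow(x$runs), "runs: mean W sign",
      "agreement =", round(x$signAgreement, 3), "\n")
  print(x$runs, row.names = FALSE)
  invisible(x)
}
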