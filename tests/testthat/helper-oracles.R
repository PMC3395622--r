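# Independent oracles and shared fixtures.
#
# rk4Circuit() integrates the circuit equations with a plain fixed-step
# RK4 written directly from the model definition (sigmoid synthesis,
# nearest-neighbour diffusion with no-flux edges, linear decay), entirely
# independent of the package's compiled solver path.

rk4Circuit <- function(params, inputs, lattice, t0, t1, v0, dt = 1e-3,
                       synthesis = TRUE, Dscale = 1) {
  g <- function(u) 0.5 * (u / sqrt(u * u + 1) + 1)
  pos <- nucleusPositions(lattice)
  W <- params@W; E <- params@E
  R <- params@R; D <- params@D * Dscale
  lam <- params@lambda; h <- params@h
  M <- length(inputs@funs)
  rhs <- function(v, t) {
    u <- W %*% v + h
    if (M > 0) u <- u + E %*% evaluateInputs(inputs, pos, t)
    s <- if (synthesis) R * g(u) else 0 * v
    left <- cbind(v[, 1, drop = FALSE], v[, -ncol(v), drop = FALSE])
    right <- cbind(v[, -1, drop = FALSE], v[, ncol(v), drop = FALSE])
    s + D * ((left - v) + (right - v)) - lam * v
  }
  n <- ceiling((t1 - t0) / dt)
  dt <- (t1 - t0) / n
  v <- v0
  t <- t0
  for (k in seq_len(n)) {
    k1 <- rhs(v, t)
    k2 <- rhs(v + dt / 2 * k1, t + dt / 2)
    k3 <- rhs(v + dt / 2 * k2, t + dt / 2)
    k4 <- rhs(v + dt * k3, t + dt)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  v
}

# A tiny one-gene context used across simulator tests.
oneGeneContext <- function(n = 5, tEnd = 10, label = "S") {
  spec <- geneNetworkSpec(gapGenes = "g1", externalInputs = character(0),
                          apRange = c(35, 87))
  list(spec = spec,
       lattice = customLattice(n, c(35, 87)),
       schedule = divisionSchedule(tStart = 0, tEnd = tEnd,
                                   mitosis = numeric(0),
                                   tDivision = numeric(0),
                                   dataTimes = setNames(tEnd, label)),
       inputs = externalInputSet(list()))
}

# Session-wide cache so expensive computations (the recovery experiment)
# are shared between the acceptance suite and module tests.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

benchRecoveryConfig <- function() fitConfig(maxEvals = 6000, refineEvals = 800)

benchRecovery <- function() {
  cached("recovery", recoveryExperiment(benchScenario(),
                                        benchRecoveryConfig(),
                                        nRuns = 10, seed = 42))
}

benchRecoveryShuffled <- function() {
  cached("recovery_shuffled",
         recoveryExperiment(benchScenario(), benchRecoveryConfig(),
                            nRuns = 10, seed = 42, shuffle = TRUE))
}
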