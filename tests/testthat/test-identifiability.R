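test_that("intervals on 1-parameter regression match the classical form", {
  set.seed(11)
  x <- seq(0.5, 10, length.out = 40)
  theta <- 1.7
  y <- theta * x + rnorm(length(x), sd = 0.3)
  est <- sum(x * y) / sum(x * x)             # least squares through origin
  r <- est * x - y
  J <- matrix(x, ncol = 1, dimnames = list(NULL, "W.g.g"))
  ci <- confidenceIntervals(J, sum(r^2), c(W.g.g = est), alpha = 0.05)
  ## classical: est +/- t_{0.975, n-1} * s / sqrt(sum x^2)
  n <- length(x)
  s <- sqrt(sum(r^2) / (n - 1))
  hw <- qt(0.975, n - 1) * s / sqrt(sum(x^2))
  tb <- ciTable(ci)
  expect_equal(tb$dep_hi - tb$estimate, hw, tolerance = 1e-6)
  expect_equal(tb$estimate - tb$dep_lo, hw, tolerance = 1e-6)
  ## with a single parameter both interval types coincide
  expect_equal(tb$indep_hi, tb$dep_hi, tolerance = 1e-12)
  ## weight scaling invariance: J *= sqrt(c), S *= c -> same intervals
  ci2 <- confidenceIntervals(sqrt(3) * J, 3 * sum(r^2), c(W.g.g = est))
  expect_equal(ciTable(ci2)$dep_hi, tb$dep_hi, tolerance = 1e-10)
  expect_equal(ciTable(ci2)$indep_hi, tb$indep_hi, tolerance = 1e-10)
})

test_that("orthonormal Jacobians give equal half-widths sqrt(Delta)", {
  n <- 30; p <- 3
  J <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(J) <- paste0("W.g", 1:p, ".g", 1:p)
  S <- n - p                                  # s2 = 1
  ci <- confidenceIntervals(J, S, setNames(rep(0, p), colnames(J)))
  hw <- sqrt(ci@delta)
  tb <- ciTable(ci)
  expect_equal(tb$dep_hi, rep(hw, p), tolerance = 1e-9)
  expect_equal(tb$indep_hi, rep(hw, p), tolerance = 1e-9)
})

test_that("perfectly correlated parameters become non-determinable", {
  set.seed(4)
  x <- rnorm(50)
  J <- cbind(W.a.a = x, W.b.b = x)            # exact duplicate column
  ci <- confidenceIntervals(J, 10, c(W.a.a = 0.1, W.b.b = 0.1))
  tb <- ciTable(ci)
  expect_true(all(is.infinite(tb$indep_hi)))
  rep_ <- classifyDeterminability(ci)
  expect_equal(unname(rep_$counts["non"]), 2L)
})

test_that("interval widths shrink as 1/sqrt(N) on the linear toy", {
  set.seed(21)
  widths <- vapply(c(50, 200, 800, 3200), function(n) {
    x <- runif(n, 0.5, 2)
    y <- 1.3 * x + rnorm(n, sd = 0.2)
    est <- sum(x * y) / sum(x * x)
    r <- est * x - y
    J <- matrix(x, ncol = 1, dimnames = list(NULL, "W.g.g"))
    tb <- ciTable(confidenceIntervals(J, sum(r^2), c(W.g.g = est)))
    tb$indep_hi - tb$indep_lo
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(50, 200, 800, 3200))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("residual Jacobian is exact in structure on the benchmark", {
  ## add a null input: zero concentration everywhere -> exactly zero column
  spec <- geneNetworkSpec(gapGenes = c("gA", "gB"),
                          externalInputs = c("bcd", "cad", "nul"),
                          apRange = c(35, 87))
  sc <- benchScenario(sigma = 0.02)
  inputs <- externalInputSet(c(sc@inputs@funs,
                               list(nul = function(x, t) 0 * x)),
                             provenance = "artificial")
  truth <- circuitParameters(spec,
    W = sc@truth@W, E = cbind(sc@truth@E, nul = c(0, 0)),
    R = sc@truth@R, D = sc@truth@D, lambda = sc@truth@lambda, h = -2.5)
  ds <- synthDataset(sc, seed = 6)$dataset
  J <- residualJacobian(truth, ds, inputs, sc@schedule, mode = "WLS",
                        lattice = sc@lattice, latticePost = sc@lattice)
  expect_equal(ncol(J), length(freeParams(truth)))
  expect_true(all(J[, "E.gA.nul"] == 0))
  expect_true(all(J[, "E.gB.nul"] == 0))
  ## step-consistency: a 10x smaller step changes J only marginally
  J2 <- residualJacobian(truth, ds, inputs, sc@schedule, mode = "WLS",
                         lattice = sc@lattice, latticePost = sc@lattice,
                         relStep = 1e-5, absStep = 1e-7)
  scale <- max(abs(J))
  expect_lt(max(abs(J - J2)) / scale, 1e-4)
})

test_that("dependent intervals nest inside independent ones on real fits", {
  sc <- benchScenario(sigma = 0.05)
  ds <- synthDataset(sc, seed = 8)$dataset
  p <- sc@truth
  J <- residualJacobian(p, ds, sc@inputs, sc@schedule, mode = "WLS",
                        lattice = sc@lattice, latticePost = sc@lattice)
  S <- circuitCost(p, ds, sc@inputs, sc@schedule, mode = "WLS",
                   lattice = sc@lattice, latticePost = sc@lattice)
  ci <- confidenceIntervals(J, S, freeParams(p))
  tb <- ciTable(ci)
  expect_true(all(tb$indep_lo <= tb$dep_lo + 1e-12))
  expect_true(all(tb$indep_hi >= tb$dep_hi - 1e-12))
  expect_true(all(tb$dep_lo <= tb$estimate & tb$estimate <= tb$dep_hi))
})

test_that("determinability classification follows the category rules", {
  mk <- function(lo, hi) {
    tb <- data.frame(parameter = "W.a.b", estimate = (lo + hi) / 2,
                     dep_lo = (lo + hi) / 2, dep_hi = (lo + hi) / 2,
                     indep_lo = lo, indep_hi = hi)
    new("ConfidenceIntervals", table = tb, delta = 1, s2 = 1, p = 1L,
        Nd = 10L, alpha = 0.05)
  }
  cases <- list(
    list(0.01, 0.05, "determinable", "activating"),
    list(-0.002, 0.02, "weakly determinable", NA_character_),
    list(-0.1, 0.1, "non-determinable", NA_character_),
    list(-0.004, 0.004, "determinable", "none"),
    list(-0.3, -0.006, "determinable", "repressing"),
    list(-0.3, 0.004, "weakly determinable", NA_character_))
  for (cs in cases) {
    rep_ <- classifyDeterminability(mk(cs[[1]], cs[[2]]))
    expect_equal(rep_$table$class, cs[[3]])
    expect_equal(rep_$table$category, cs[[4]])
  }
  ## counts partition the regulatory weights
  repAll <- classifyDeterminability(mk(-0.002, 0.02))
  expect_equal(sum(repAll$counts), nrow(repAll$table))
})
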