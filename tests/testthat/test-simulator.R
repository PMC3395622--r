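test_that("pure decay matches the analytic solution", {
  ctx <- oneGeneContext(n = 5, tEnd = 10)
  p <- circuitParameters(ctx$spec, R = 1e-12, D = 0, lambda = 0.05)
  tr <- simulateCircuit(p, ctx$inputs, ctx$schedule,
                        v0 = matrix(100, 1, 5), lattice = ctx$lattice,
                        solver = solverOptions(rtol = 1e-10, atol = 1e-12))
  got <- trajectoryState(tr, "S")
  expect_equal(as.numeric(got), rep(100 * exp(-0.5), 5), tolerance = 1e-7)
})

test_that("no-flux diffusion conserves total mass", {
  ctx <- oneGeneContext(n = 9, tEnd = 20)
  p <- circuitParameters(ctx$spec, R = 1e-12, D = 0.25, lambda = 1e-12,
                         h = -50)
  v0 <- matrix(c(0, 0, 40, 0, 0, 10, 0, 0, 0), 1)
  tr <- simulateCircuit(p, ctx$inputs, ctx$schedule, v0 = v0,
                        lattice = ctx$lattice)
  expect_equal(sum(trajectoryState(tr, "S")), sum(v0), tolerance = 1e-6)
  ## and the spike spreads (variance decreases towards uniformity)
  expect_lt(max(trajectoryState(tr, "S")), 40)
})

test_that("division copies mothers to both daughters and doubles mass", {
  st <- matrix(seq_len(27) * 1.0, 1, 27)
  d <- divideState(st, buildLattice("C13"))
  expect_equal(ncol(d$values), 54)
  expect_equal(as.numeric(d$values), rep(seq_len(27), each = 2))
  expect_equal(sum(d$values), 2 * sum(st))
  ## aligned to the C14A trunk: 53 nuclei, one edge daughter dropped
  d2 <- divideState(st, buildLattice("C13"), buildLattice("C14A"))
  expect_equal(ncol(d2$values), 53)
  st5 <- matrix(5.0, 1, 27)
  d5 <- divideState(st5, buildLattice("C13"), buildLattice("C14A"))
  expect_true(all(d5$values == 5.0))
  ## dividing twice is an error
  expect_error(divideState(d2$values, d2$lattice), "one division")
})

test_that("initial conditions interpolate between the C12 and C13 anchors", {
  ds <- loadTable2Fixture()
  v13 <- datasetValues(ds)[, 1:27]
  v0 <- initialConditions(ds, t0 = 0)
  expect_equal(v0, v13 * (6.2 / 16.75))
  ## identical anchors give back the anchor value
  v0b <- initialConditions(ds, t0 = 0, vC12 = v13)
  expect_equal(v0b, v13)
  expect_error(initialConditions(ds, t0 = -10), "anchor")
  expect_error(initialConditions(ds, t0 = 20), "anchor")
})

test_that("trajectory sampling follows the dataset layout", {
  ds <- loadTable2Fixture()
  spec <- geneNetworkSpec()
  inp <- artificialInputs(spec)
  p <- randomCircuit(spec, seed = 11)
  tr <- simulateCircuit(p, inp, v0 = initialConditions(ds))
  m <- sampleAt(tr)
  expect_equal(length(m), 4 * (27 + 8 * 53))   # 1804 model values
  expect_equal(dim(sampleAt(tr, c("C13"))), c(4L, 27L))
  expect_equal(dim(sampleAt(tr, c("T1"))), c(4L, 53L))
  expect_equal(ncol(sampleAt(tr, character(0))), 0L)
  expect_error(sampleAt(tr, "T9"), "unknown")
  ## division record: lattice doubles exactly once, mothers copied
  expect_equal(ncol(tr@divisionRecord$pre), 27)
  expect_equal(ncol(tr@divisionRecord$post), 53)
  ## daughters 36 and 37 both stem from mother nucleus 18 (pre column 2)
  expect_equal(tr@divisionRecord$post[, 2], tr@divisionRecord$pre[, 2])
  expect_equal(tr@divisionRecord$post[, 3], tr@divisionRecord$pre[, 2])
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  sc <- benchScenario()
  lattice <- customLattice(10, c(35, 87))
  schedule <- divisionSchedule(tStart = 0, tEnd = 10, mitosis = numeric(0),
                               tDivision = numeric(0), dataTimes = c(S = 10))
  v0 <- matrix(20, 2, 10)
  tr <- simulateCircuit(sc@truth, sc@inputs, schedule, v0 = v0,
                        lattice = lattice,
                        solver = solverOptions(rtol = 1e-8, atol = 1e-10))
  oracle <- rk4Circuit(sc@truth, sc@inputs, lattice, 0, 10, v0, dt = 1e-3)
  got <- trajectoryState(tr, "S")
  expect_lt(max(abs(got - oracle) / pmax(abs(oracle), 1)), 1e-4)
})

test_that("concentrations stay within the synthesis/decay bound", {
  sc <- benchScenario()
  bound <- max(sc@truth@R / sc@truth@lambda)
  tr <- simulateCircuit(sc@truth, sc@inputs, sc@schedule,
                        lattice = sc@lattice, latticePost = sc@lattice)
  for (nm in names(tr@times)) {
    st <- trajectoryState(tr, nm)
    expect_true(all(st >= -1e-6 & st <= bound + 1e-6))
  }
})

test_that("halving solver tolerances barely changes sampled values", {
  sc <- benchScenario()
  tr1 <- simulateCircuit(sc@truth, sc@inputs, sc@schedule,
                         lattice = sc@lattice, latticePost = sc@lattice)
  tr2 <- simulateCircuit(sc@truth, sc@inputs, sc@schedule,
                         lattice = sc@lattice, latticePost = sc@lattice,
                         solver = solverOptions(rtol = 5e-7, atol = 5e-9))
  expect_lt(max(abs(sampleAt(tr1) - sampleAt(tr2))), 1e-3)
})

test_that("permuting gene order permutes trajectories identically", {
  sc <- benchScenario()
  specP <- geneNetworkSpec(gapGenes = c("gB", "gA"),
                           externalInputs = c("bcd", "cad"),
                           apRange = c(35, 87))
  t0 <- sc@truth
  perm <- c("gB", "gA")
  pP <- circuitParameters(specP, W = t0@W[perm, perm], E = t0@E[perm, ],
                          R = t0@R[perm], D = t0@D[perm],
                          lambda = t0@lambda[perm], h = t0@h[perm])
  tr <- simulateCircuit(t0, sc@inputs, sc@schedule, lattice = sc@lattice,
                        latticePost = sc@lattice)
  trP <- simulateCircuit(pP, sc@inputs, sc@schedule, lattice = sc@lattice,
                         latticePost = sc@lattice)
  for (nm in names(tr@times))
    expect_equal(trajectoryState(trP, nm),
                 trajectoryState(tr, nm)[perm, ], tolerance = 1e-8)
})

test_that("synthesis is off during mitosis but decay continues", {
  ctx <- oneGeneContext(n = 4, tEnd = 30)
  sch <- divisionSchedule(tStart = 0, tEnd = 30, mitosis = c(10, 20),
                          tDivision = numeric(0),
                          dataTimes = c(A = 10, B = 20, C = 30))
  ## strong synthesis: without mitosis the level would keep rising
  p <- circuitParameters(ctx$spec, R = 10, D = 0, lambda = 0.1, h = 10)
  tr <- simulateCircuit(p, ctx$inputs, sch, v0 = matrix(0, 1, 4),
                        lattice = ctx$lattice)
  a <- trajectoryState(tr, "A")[1, 1]
  b <- trajectoryState(tr, "B")[1, 1]
  ## during [10, 20] only decay acts: v(20) = v(10) exp(-1)
  expect_equal(b, a * exp(-0.1 * 10), tolerance = 1e-5)
  expect_gt(trajectoryState(tr, "C")[1, 1], b)   # synthesis resumes
})
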