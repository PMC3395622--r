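test_that("boundary splines hit their anchors with flat ends", {
  b <- boundarySpline("Kr", "T1", "Kr.central.A", "rising", x0 = 45.3,
                      x2 = 50.3)
  expect_equal(boundaryProfile(b, 45.3), 0)
  expect_equal(boundaryProfile(b, 50.3), 1)
  expect_equal(boundaryProfile(b, 47.8), 0.5)   # symmetric midpoint
  ## zero derivative at both end knots (finite differences)
  hstep <- 1e-5
  dStart <- (boundaryProfile(b, 45.3 + hstep) - boundaryProfile(b, 45.3)) / hstep
  dEnd <- (boundaryProfile(b, 50.3) - boundaryProfile(b, 50.3 - hstep)) / hstep
  expect_lt(abs(dStart), 1e-3)
  expect_lt(abs(dEnd), 1e-3)
  ## clamped outside the span; monotone within
  expect_equal(boundaryProfile(b, 40), 0)
  expect_equal(boundaryProfile(b, 60), 1)
  xs <- seq(45.3, 50.3, length.out = 101)
  expect_true(all(diff(boundaryProfile(b, xs)) >= 0))
  ## falling boundary: mirrored, 1 on the domain (anterior) side
  f <- boundarySpline("Kr", "T1", "Kr.central.P", "falling", x0 = 57.8,
                      x2 = 52.8)
  expect_equal(boundaryProfile(f, 57.8), 0)
  expect_equal(boundaryProfile(f, 52.8), 1)
  expect_equal(boundaryProfile(f, 50), 1)
})

test_that("median boundaries aggregate embryos coordinate-wise", {
  mk <- function(x0, id = "Kr.central.A")
    boundarySpline("Kr", "T1", id, "rising", x0 = x0, x2 = x0 + 5,
                   embryo = paste0("e", x0))
  m <- medianBoundary(list(mk(44.3), mk(46.7), mk(45.3)))
  expect_equal(m@x0, 45.3)
  expect_equal(m@x2, 50.3)
  single <- medianBoundary(list(mk(44.0)))
  expect_equal(single@x0, 44.0)
  ## even group: mean of the two central values
  m4 <- medianBoundary(list(mk(44), mk(45), mk(46), mk(47)))
  expect_equal(m4@x0, 45.5)
  expect_error(medianBoundary(list(mk(44), mk(45, id = "other"))), "mixed")
  expect_error(medianBoundary(list()), "non-empty")
})

test_that("profile assembly builds plateaus between alternating edges", {
  lat <- buildLattice("C14A", c(35, 87))
  rise <- boundarySpline("Kr", "T1", "Kr.A", "rising", 45, 50)
  fall <- boundarySpline("Kr", "T1", "Kr.P", "falling", 65, 60)
  prof <- assembleProfile(list(rise, fall), lat)
  pos <- nucleusPositions(lat)
  expect_equal(prof[pos > 50 & pos < 60], rep(1, sum(pos > 50 & pos < 60)))
  expect_equal(prof[pos < 45 | pos > 65], rep(0, sum(pos < 45 | pos > 65)))
  ## input order does not matter
  expect_equal(assembleProfile(list(fall, rise), lat), prof)
  ## no boundaries: all-zero profile
  expect_equal(assembleProfile(list(), lat), rep(0, 53))
  ## overlapping spans of one gene are an error naming the ids
  rise2 <- boundarySpline("Kr", "T1", "Kr.A2", "rising", 58, 63)
  expect_error(assembleProfile(list(rise, fall, rise2), lat),
               "overlap.*Kr")
})

test_that("spatial and temporal scaling match their printed anchors", {
  expect_equal(spatialScalingFactor(50), 1.0)
  expect_equal(spatialScalingFactor(0), 0.5)
  expect_equal(spatialScalingFactor(100), 0.5)
  expect_equal(spatialScalingFactor(25), 0.75)
  expect_error(spatialScalingFactor(101), "within")
  expect_equal(temporalScalingFactor(0), 0.1)
  expect_equal(temporalScalingFactor(48), 1.0)
  expect_equal(temporalScalingFactor(71.1), 0.7)
  ## derived: solve the quadratic 3x3 system independently and evaluate
  A <- cbind(c(0, 48, 71.1)^2, c(0, 48, 71.1), 1)
  cf <- solve(A, c(0.1, 1.0, 0.7))
  expect_equal(temporalScalingFactor(24), sum(cf * c(24^2, 24, 1)))
  expect_equal(temporalScalingFactor(24), 0.807, tolerance = 1e-3)
  ## interior maximum lies within (40, 50) min
  tpk <- -cf[2] / (2 * cf[1])
  expect_true(tpk > 40 && tpk < 50)
  expect_equal(temporalScalingFactor(tpk),
               max(temporalScalingFactor(seq(0, 71.1, by = 0.01))))
  expect_error(temporalScalingFactor(-1), "within")
})

test_that("post-processing composes binning, scalings and the x200 factor", {
  lat13 <- buildLattice("C13", c(35, 87))
  mkSlice <- function(label, time, lattice, vals) {
    list(label = label, time = time, lattice = lattice, values = vals,
         weights = makeWeights(vals))
  }
  ## a profile that is exactly 1 everywhere
  ones <- matrix(1, 1, nNuclei(lat13))
  ds <- expressionDataset(list(mkSlice("C13", 10.55, lat13, ones)), "g1")
  out <- postprocess(ds)
  pos <- nucleusPositions(lat13)
  expect_equal(as.numeric(datasetValues(out)),
               spatialScalingFactor(pos) * temporalScalingFactor(10.55) * 200)
  ## composition at the anchor points
  expect_equal(spatialScalingFactor(50) * temporalScalingFactor(48) * 200,
               200)
  expect_equal(spatialScalingFactor(0) * temporalScalingFactor(0) * 200, 10)
  ## all-zero profile stays zero; weights untouched
  zs <- matrix(0, 1, nNuclei(lat13))
  ds0 <- expressionDataset(list(mkSlice("C13", 10.55, lat13, zs)), "g1")
  out0 <- postprocess(ds0)
  expect_true(all(datasetValues(out0) == 0))
  expect_equal(datasetWeights(out0), datasetWeights(ds0))
  ## scaling twice is an error
  expect_error(postprocess(out), "already")
})

test_that("WLS weights decrease with expression and peak at zero", {
  expect_equal(makeWeights(0), 100)
  expect_equal(makeWeights(1), 1 / 1.21)
  y <- seq(0, 1, by = 0.05)
  expect_true(all(diff(makeWeights(y)) < 0))
  expect_true(all(is.finite(makeWeights(y)) & makeWeights(y) > 0))
  expect_error(makeWeights(0.5, epsilon = 0), "positive")
  ## wherever yhat = 0 the weight attains its maximum
  expect_true(all(makeWeights(0) >= makeWeights(y)))
})

test_that("the packaged boundary table builds the full fitting dataset", {
  ds <- loadTable2Fixture()
  expect_s4_class(ds, "ExpressionDataset")
  expect_equal(nDataPoints(ds), 1804)          # 4 x (27 + 8 x 53)
  expect_length(datasetTimes(ds), 9)           # C13, T1..T8
  cd <- SummarizedExperiment::colData(ds)
  expect_equal(sum(cd$time_class == "C13"), 27)
  expect_equal(sum(cd$time_class == "T1"), 53)
  ## Kr at T1: nonzero exactly between the anterior (45.3) and posterior
  ## (57.8) boundary spans
  v <- datasetValues(ds)
  t1 <- which(cd$time_class == "T1")
  kr <- v["Kr", t1]
  pos <- cd$ap_position[t1]
  expect_true(all(kr[pos < 45.3 | pos > 57.8] == 0))
  expect_true(all(kr[pos > 50.4 & pos < 52.7] > 0))
  ## annotation table: Kr central anterior boundary at T8 sits at 42.7
  ann <- S4Vectors::metadata(ds)$annotations
  expect_equal(ann$x0[ann$boundary_id == "Kr.central.A" &
                        ann$time_class == "T8"], 42.7)
  ## hb posterior absent at C13 (dash in the table): no boundary emitted
  expect_false(any(ann$time_class == "C13" &
                     ann$boundary_id == "hb.posterior.P"))
  expect_true(validObject(ds))
})

test_that("posterior Kr removal zeroes the extra late domain idempotently", {
  ## synthetic dataset with a central and an ectopic posterior Kr run
  lat <- buildLattice("C14A", c(35, 87))
  pos <- nucleusPositions(lat)
  kr <- ifelse(pos > 45 & pos < 58, 1,
               ifelse(pos > 75 & pos < 82, 0.6, 0))
  vals <- rbind(hb = rep(0.2, 53), Kr = kr)
  mk <- function(label, time)
    list(label = label, time = time, lattice = lat, values = vals,
         weights = makeWeights(vals))
  ds <- expressionDataset(list(mk("T6", 55.475), mk("T8", 67.975)), c("hb", "Kr"))
  out <- dropPosteriorKr(ds)
  v <- datasetValues(out)
  cd <- SummarizedExperiment::colData(out)
  for (lab in c("T6", "T8")) {
    sl <- v["Kr", cd$time_class == lab]
    expect_true(all(sl[pos > 75] == 0))
    expect_true(any(sl[pos > 45 & pos < 58] > 0))
  }
  ## idempotent: applying twice equals once (second call warns)
  expect_warning(out2 <- dropPosteriorKr(out), "unchanged")
  expect_equal(datasetValues(out2), v)
  ## annotation route
  ann <- data.frame(embryo_id = "e1", gene = c("Kr", "Kr"),
                    time_class = "T8",
                    boundary_id = c("Kr.central.A", "Kr.posterior.A"),
                    polarity = "rising", x0 = c(45, 75), y0 = 0,
                    x2 = c(50, 80), y2 = 1)
  red <- dropPosteriorKr(ann)
  expect_equal(red$boundary_id, "Kr.central.A")
  expect_warning(dropPosteriorKr(red), "unchanged")
})

test_that("annotation tables round-trip through TSV", {
  ds <- loadTable2Fixture()
  ann <- S4Vectors::metadata(ds)$annotations
  path <- tempfile(fileext = ".tsv")
  writeBoundaryAnnotations(ann, path)
  back <- readBoundaryAnnotations(path)
  expect_equal(back$x0, ann$x0)
  expect_equal(back$boundary_id, ann$boundary_id)
})
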