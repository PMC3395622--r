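test_that("interaction classification respects the cutoff and symmetry", {
  expect_equal(classifyInteraction(0.004), "none")
  expect_equal(classifyInteraction(0.005), "none")    # closed boundary
  expect_equal(classifyInteraction(-0.2), "repressing")
  expect_equal(classifyInteraction(0.2), "activating")
  ## antisymmetry under negation
  w <- seq(-0.3, 0.3, by = 0.013)
  a <- classifyInteraction(w); b <- classifyInteraction(-w)
  expect_equal(a == "activating", b == "repressing")
  expect_equal(a == "none", b == "none")
  expect_error(classifyInteraction(NaN), "finite")
})

test_that("interaction summaries count triplets and find consensus", {
  spec <- geneNetworkSpec()
  mkP <- function(wHbKr) {
    p <- circuitParameters(spec)
    p@W["hb", "Kr"] <- wHbKr
    p@W["Kr", "hb"] <- 0.1
    p
  }
  ens <- list(mkP(-0.1), mkP(-0.2), mkP(0.002))
  sm <- interactionSummary(ens)
  row <- sm[sm$regulator == "Kr" & sm$target == "hb", ]
  expect_equal(row$n_repressing + row$n_none + row$n_activating, 3)
  expect_equal(row$n_repressing, 2)
  expect_equal(row$consensus, "repressing")
  row2 <- sm[sm$regulator == "hb" & sm$target == "Kr", ]
  expect_equal(row2$consensus, "activating")
  ## permutation invariance over ensemble order
  sm2 <- interactionSummary(rev(ens))
  expect_equal(sm2$n_repressing, sm$n_repressing)
  ## ties are ambiguous
  ens3 <- list(mkP(-0.1), mkP(0.1))
  sm3 <- interactionSummary(ens3)
  expect_equal(sm3[sm3$regulator == "Kr" & sm3$target == "hb", "consensus"],
               "ambiguous")
})

## hand-built 4-gene trajectory with controllable profiles
mkTraj <- function(states, times = c(P1 = 30, P2 = 40)) {
  spec <- geneNetworkSpec()
  lat <- customLattice(ncol(states[[1]]), c(35, 87))
  new("Trajectory", spec = spec, times = times, states = states,
      latticePre = lat, latticePost = lat, divisionTime = numeric(0),
      divisionRecord = list())
}

gauss <- function(pos, mu, s, amp = 100) amp * exp(-(pos - mu)^2 / (2 * s^2))

test_that("overlap regions match analytic threshold crossings", {
  pos <- customLattice(40, c(35, 87))@positions
  st <- rbind(hb = gauss(pos, 80, 6), Kr = gauss(pos, 50, 6),
              gt = gauss(pos, 70, 6), kni = gauss(pos, 60, 6))
  tr <- mkTraj(list(P1 = st, P2 = st))
  ## disjoint step profiles: empty overlap
  st2 <- st
  st2["hb", ] <- ifelse(pos > 70, 100, 0)
  st2["Kr", ] <- ifelse(pos < 50, 100, 0)
  tr2 <- mkTraj(list(P1 = st2, P2 = st2))
  expect_length(overlapRegion(tr2, "hb", "Kr", "P1"), 0)
  ## identical profiles: the full expressed region
  ident <- overlapRegion(tr, "gt", "gt", "P1")
  expect_equal(ident, which(st["gt", ] > 0.1 * max(st["gt", ])))
  ## gaussian overlap: both above 10% of their max; analytic crossings
  got <- overlapRegion(tr, "hb", "gt", "P1", threshold = 0.1)
  cut <- sqrt(-2 * 36 * log(0.1))   # |x - mu| at 10% of a gaussian max
  lo <- 80 - cut; hi <- 70 + cut
  analytic <- which(pos > lo & pos < hi)
  expect_lte(abs(min(got) - min(analytic)), 1)
  expect_lte(abs(max(got) - max(analytic)), 1)
})

test_that("net effects equal the direct weighted sums", {
  pos <- customLattice(40, c(35, 87))@positions
  st <- rbind(hb = gauss(pos, 80, 6), Kr = gauss(pos, 50, 6),
              gt = gauss(pos, 70, 6), kni = gauss(pos, 60, 6))
  tr <- mkTraj(list(P1 = st, P2 = 2 * st))
  p <- circuitParameters(geneNetworkSpec())
  p@W["gt", "hb"] <- -0.1
  ## single nucleus, single time, concentration 10: w * v = -1
  onecol <- which.min(abs(st["hb", ] - 10))
  stUnit <- st; stUnit["hb", onecol] <- 10
  trU <- mkTraj(list(P1 = stUnit, P2 = stUnit))
  expect_equal(netEffect(trU, p, "hb", "gt", onecol, "P1"), -1)
  ## zero weight: zero net effect regardless of region
  p0 <- circuitParameters(geneNetworkSpec())
  expect_equal(netEffect(trU, p0, "hb", "gt", 1:40, c("P1", "P2")), 0)
  ## direct-summation oracle over a region and two times
  region <- 25:35
  manual <- (sum(-0.1 * st["hb", region]) +
               sum(-0.1 * 2 * st["hb", region])) / (2 * length(region))
  expect_equal(netEffect(tr, p, "hb", "gt", region, c("P1", "P2")), manual)
  expect_error(netEffect(tr, p, "hb", "gt", integer(0), "P1"), "empty")
})

test_that("mechanism reports follow their per-rule definitions", {
  spec <- geneNetworkSpec()
  cushion <- function(s = 0.1) {
    p <- circuitParameters(spec)
    p@W["hb", "kni"] <- -s; p@W["kni", "hb"] <- -s
    p@W["Kr", "gt"] <- -s; p@W["gt", "Kr"] <- -s
    p@E[, "bcd"] <- 0.1
    p@E["gt", "cad"] <- 0.1; p@E["kni", "cad"] <- 0.1
    p@E["hb", "hkb"] <- -0.1
    p@E[c("Kr", "gt", "kni"), "tll"] <- -0.1
    p
  }
  ens <- list(cushion(0.1), cushion(0.2), cushion(0.05))
  rep_ <- mechanismReport(ens)
  expect_equal(unname(rep_@fractions["alternating_cushions"]), 1.0)
  expect_equal(unname(rep_@fractions["bcd_cad_activation"]), 1.0)
  expect_equal(unname(rep_@fractions["tll_hkb_inhibition"]), 1.0)
  ## all self-weights zero: no auto-activation anywhere
  expect_equal(unname(rep_@fractions[paste0("auto_activation_",
                                            c("hb", "Kr", "gt", "kni"))]),
               rep(0, 4))
  ## fraction linearity: ensemble report is the mean of singleton reports
  singles <- vapply(ens, function(p)
    mechanismReport(list(p))@fractions["alternating_cushions"], numeric(1))
  expect_equal(unname(rep_@fractions["alternating_cushions"]), mean(singles))
  ## net-effect mechanisms with a hand-built trajectory: posterior hb
  ## dominates gt in their overlap (stronger |w * v| integral)
  pos <- customLattice(40, c(35, 87))@positions
  ## hb has an anterior and a posterior domain, so it overlaps both Kr
  ## (anteriorly) and gt (posteriorly)
  st <- rbind(hb = gauss(pos, 78, 7) + gauss(pos, 42, 5),
              Kr = gauss(pos, 48, 6),
              gt = gauss(pos, 68, 7), kni = gauss(pos, 58, 6))
  tr <- mkTraj(list(P1 = st, P2 = st))
  p <- cushion(0.1)
  p@W["gt", "hb"] <- -0.2   # hb strongly represses gt
  p@W["hb", "gt"] <- -0.01  # reciprocal is weak
  p@W["kni", "gt"] <- -0.2; p@W["gt", "kni"] <- -0.01
  p@W["Kr", "kni"] <- -0.2; p@W["kni", "Kr"] <- -0.01
  p@W["Kr", "hb"] <- -0.2; p@W["hb", "Kr"] <- -0.01
  rep2 <- mechanismReport(list(p), trajectories = list(tr), times = "P1")
  expect_equal(unname(rep2@fractions["shift_gt_by_hb"]), 1)
  expect_equal(unname(rep2@fractions["shift_kni_by_gt"]), 1)
  expect_equal(unname(rep2@fractions["shift_Kr_by_kni"]), 1)
  expect_equal(unname(rep2@fractions["hb_Kr_net_repression_by_hb"]), 1)
  ## independent per-rule oracle for one pair
  region <- overlapRegion(tr, "gt", "hb", "P1")
  fwd <- mean(p@W["gt", "hb"] * st["hb", region])
  bwd <- mean(p@W["hb", "gt"] * st["gt", region])
  expect_true(fwd < bwd)
})

test_that("boundary reduction keeps at least one embryo per boundary", {
  ann <- do.call(rbind, lapply(1:5, function(e)
    data.frame(embryo_id = paste0("e", e), gene = "Kr", time_class = "T1",
               boundary_id = "Kr.central.A", polarity = "rising",
               x0 = 45 + e / 10, y0 = 0, x2 = 50 + e / 10, y2 = 1)))
  solo <- ann[1, ]; solo$boundary_id <- "Kr.central.P"
  ann <- rbind(ann, solo)
  expect_equal(reduceBoundaries(ann, 1.0, seed = 1), ann)
  r40 <- reduceBoundaries(ann, 0.4, seed = 1)
  expect_equal(sum(r40$boundary_id == "Kr.central.A"), 2)  # round(2.0)
  expect_equal(sum(r40$boundary_id == "Kr.central.P"), 1)  # floor at 1
  r20 <- reduceBoundaries(ann, 0.2, seed = 3)
  expect_equal(sum(r20$boundary_id == "Kr.central.A"), 1)
  ## determinism and measure preservation in expectation
  expect_equal(reduceBoundaries(ann, 0.6, seed = 9),
               reduceBoundaries(ann, 0.6, seed = 9))
  kept <- vapply(1:2000, function(s)
    sum(reduceBoundaries(ann, 0.6, seed = s)$boundary_id ==
          "Kr.central.A"), numeric(1))
  expect_equal(mean(kept), 3, tolerance = 0.02)  # round(0.6 * 5) = 3
})

test_that("time-class reduction always keeps the first and last class", {
  ann <- do.call(rbind, lapply(c("C13", paste0("T", 1:8)), function(tc)
    data.frame(embryo_id = "e1", gene = "Kr", time_class = tc,
               boundary_id = "Kr.central.A", polarity = "rising",
               x0 = 45, y0 = 0, x2 = 50, y2 = 1)))
  expect_equal(reduceTimeclasses(ann, 9, seed = 1)$time_class,
               ann$time_class)
  for (s in 1:50) {
    r3 <- reduceTimeclasses(ann, 3, seed = s)
    tc <- unique(r3$time_class)
    expect_length(tc, 3)
    expect_true(all(c("C13", "T8") %in% tc))
    expect_true(setdiff(tc, c("C13", "T8")) %in% paste0("T", 1:7))
  }
  expect_error(reduceTimeclasses(ann, 2, seed = 1), "\\[3, 9\\]")
  expect_error(reduceTimeclasses(ann, 10, seed = 1), "\\[3, 9\\]")
})
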