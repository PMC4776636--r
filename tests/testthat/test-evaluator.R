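test_that("queries on the linear family match closed forms exactly", {
  s <- linearStructure(V0 = 100, D0 = 100)
  expect_equal(as.numeric(volumeAtDose(s, 60)), 40, tolerance = 1e-12)
  expect_equal(as.numeric(volumeAtDose(s, 0)), totalVolume(s))
  expect_equal(as.numeric(doseAtVolume(s, 40)), 60, tolerance = 1e-12)
  expect_equal(as.numeric(doseAtVolume(s, totalVolume(s))), 0)   # first grid dose
  expect_equal(as.numeric(meanDose(s)), 50, tolerance = 1e-12)
  expect_equal(as.numeric(rtogMax(s)), 99.97, tolerance = 1e-12)
  expect_equal(as.numeric(rtogMin(s)), 0.03, tolerance = 1e-12)
})

test_that("flat segments are inverted with the supremum convention", {
  s <- StructureDVH("S", c(0, 10, 20), c(50, 50, 0))
  expect_equal(as.numeric(doseAtVolume(s, 50)), 10)
  expect_equal(as.numeric(doseAtVolume(s, 25)), 15)
  expect_equal(as.numeric(doseAtVolume(s, 0)), 20)   # v = 0 -> last grid dose
})

test_that("out-of-range and truncated-curve queries return flagged values", {
  s <- StructureDVH("S", c(0, 10, 20), c(50, 25, 5))  # ends above zero
  d <- doseAtVolume(s, 60)
  expect_equal(as.numeric(d), 0)
  expect_identical(attr(d, "flags"), "out_of_range")
  d <- doseAtVolume(s, 3)   # below the last tabulated volume
  expect_equal(as.numeric(d), 20)
  expect_identical(attr(d, "flags"), "structure_truncated")
  v <- volumeAtDose(s, 25)  # beyond the grid end
  expect_equal(as.numeric(v), 5)
  expect_identical(attr(v, "flags"), "structure_truncated")
  m <- meanDose(s)
  expect_identical(attr(m, "flags"), "structure_truncated")
  expect_error(doseAtVolume(s, -1), class = "dvhDomainError")
  expect_error(volumeAtDose(s, -1), class = "dvhDomainError")
})

test_that("a near-uniform dose structure has mean ~ max ~ min ~ plateau dose", {
  eps <- 1e-6
  s <- StructureDVH("S", c(0, 60, 60 + eps), c(30, 30, 0))
  expect_equal(as.numeric(meanDose(s)), 60, tolerance = 1e-6)
  expect_equal(as.numeric(rtogMax(s)), as.numeric(rtogMin(s)), tolerance = 1e-6)
})

test_that("degenerate structures are refused by the RTOG and mean metrics", {
  tiny <- StructureDVH("tiny", c(0, 1), c(0.02, 0))
  expect_error(rtogMax(tiny), class = "dvhDegenerateStructureError")
  expect_error(rtogMin(tiny), class = "dvhDegenerateStructureError")
  empty <- StructureDVH("empty", c(0, 1), c(0, 0))
  expect_error(meanDose(empty), class = "dvhDegenerateStructureError")
})

test_that("queries agree with a dense brute-force oracle on random curves", {
  set.seed(101)
  for (k in 1:50) {
    s <- randomStructure(truncated = k %% 7 == 0)
    orc <- denseOracle(s)
    g <- doseGrid(s)
    dq <- runif(20, 0, g[length(g)] * 1.02)
    vq <- runif(20, 0, totalVolume(s) * 1.02)
    expect_equal(as.numeric(volumeAtDose(s, dq)), orc$volumeAt(dq),
                 tolerance = 1e-9)
    expect_equal(as.numeric(doseAtVolume(s, vq)), orc$doseAt(vq),
                 tolerance = 1e-9)
    expect_equal(as.numeric(meanDose(s)), orc$mean, tolerance = 1e-9)
  }
})

test_that("both query directions are monotone non-increasing and inverse-consistent", {
  set.seed(77)
  for (k in 1:10) {
    s <- randomStructure()
    g <- doseGrid(s)
    dq <- sort(runif(50, 0, g[length(g)]))
    vals <- as.numeric(volumeAtDose(s, dq))
    expect_true(all(diff(vals) <= 1e-12))
    vq <- sort(runif(50, 1e-6, totalVolume(s) * 0.999))
    dd <- as.numeric(doseAtVolume(s, vq))
    expect_true(all(diff(dd) <= 1e-12))
    # inverse consistency on strictly decreasing parts
    back <- as.numeric(volumeAtDose(s, dd))
    expect_true(all(back >= vq - 1e-9 * pmax(vq, 1)))
  }
})

test_that("the RTOG maximum equals evaluating D(Gy)0.03(cc) bitwise", {
  p <- parseExpression("D(Gy)0.03(cc)")
  set.seed(202)
  for (k in 1:100) {
    s <- randomStructure()
    expect_identical(as.numeric(rtogMax(s)),
                     metricValue(evaluatePoint(p, s)))
  }
  # and the near-minimum equals the curve read at total - 0.03 cc
  set.seed(203)
  for (k in 1:20) {
    s <- randomStructure()
    expect_identical(as.numeric(rtogMin(s)),
                     as.numeric(doseAtVolume(s, totalVolume(s) - 0.03)))
  }
})

test_that("percent and absolute spellings are duals of each other", {
  set.seed(33)
  ref <- ReferenceDose("prescription", 55)
  for (k in 1:20) {
    s <- randomStructure()
    x <- round(runif(1, 1, 50), 1)
    vPct <- metricValue(evaluatePoint(parseExpression(sprintf("V(%%)%g(Gy)", x)), s, ref))
    vAbs <- metricValue(evaluatePoint(parseExpression(sprintf("V(cc)%g(Gy)", x)), s, ref))
    expect_equal(vPct, vAbs / totalVolume(s) * 100, tolerance = 1e-12)
    y <- round(runif(1, 0.1, totalVolume(s)), 2)
    dPct <- metricValue(evaluatePoint(parseExpression(sprintf("D(%%)%g(cc)", y)), s, ref))
    dAbs <- metricValue(evaluatePoint(parseExpression(sprintf("D(Gy)%g(cc)", y)), s, ref))
    expect_equal(dPct, dAbs / 55 * 100, tolerance = 1e-12)
  }
})

test_that("evaluatePoint composes conversions as documented", {
  s <- linearStructure(V0 = 100, D0 = 100)
  ref <- ReferenceDose("prescription", 50)
  # 40% of 100 cc -> 40 cc -> 60 Gy -> 120 % of 50 Gy
  mv <- evaluatePoint(parseExpression("D(%)40(%)"), s, ref)
  expect_equal(metricValue(mv), 120)
  expect_identical(metricUnit(mv), "%")
  # 40% of 50 Gy -> 20 Gy -> 80 cc -> 80 % of 100 cc
  mv <- evaluatePoint(parseExpression("V(%)40(%)"), s, ref)
  expect_equal(metricValue(mv), 80)
  # Dmean/Rx is dimensionless; with x 100 it is a percent
  mv <- evaluatePoint(parseExpression("Dmean/Rx"), s, ref)
  expect_equal(metricValue(mv), 1)
  expect_identical(metricUnit(mv), "dimensionless")
  mv <- evaluatePoint(parseExpression("Dmean/Rx x 100"), s, ref)
  expect_equal(metricValue(mv), 100)
  expect_identical(metricUnit(mv), "%")
  # /Rx divides by the prescription dose even under reference mode "maximum"
  mv <- evaluatePoint(parseExpression("Dmean/Rx"), s,
                      ReferenceDose("maximum", 80), rx = 50)
  expect_equal(metricValue(mv), 1)
  # but percent doses use the maximum-dose reference
  mv <- evaluatePoint(parseExpression("D(%)40(cc)"), s, ReferenceDose("maximum", 80))
  expect_equal(metricValue(mv), 60 / 80 * 100)
})

test_that("missing references are reported as such", {
  s <- linearStructure()
  expect_error(evaluatePoint(parseExpression("D(%)40(cc)"), s),
               class = "dvhMissingReferenceError")
  expect_error(evaluatePoint(parseExpression("Dmean/Rx"), s,
                             ReferenceDose("maximum", 80)),
               class = "dvhMissingReferenceError")
  # plain absolute queries need no reference at all
  expect_equal(metricValue(evaluatePoint(parseExpression("V(cc)40(Gy)"), s)), 60)
})

test_that("the reference dose resolves with per-case override semantics", {
  s <- linearStructure()
  withRx <- DVHCase("A", list(s), rxDose = 60)
  without <- DVHCase("B", list(s))
  withMax <- DVHCase("C", list(s), globalMaxDose = 80)
  glob <- runSettings("prescription", globalRx = 70)
  expect_equal(resolveReferenceDose(withRx, glob)@value, 60)   # C1 wins
  expect_equal(resolveReferenceDose(without, glob)@value, 70)  # global fallback
  expect_error(resolveReferenceDose(without, runSettings("prescription")),
               class = "dvhMissingReferenceError")
  mx <- runSettings("maximum")
  expect_equal(resolveReferenceDose(withMax, mx)@value, 80)
  expect_identical(resolveReferenceDose(withMax, mx)@mode, "maximum")
  expect_error(resolveReferenceDose(withRx, mx),
               class = "dvhMissingReferenceError")
})
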