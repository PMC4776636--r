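# Tolerance for sigmoid truths: grid-resolution limited, and the inverse
# query near the flat top of the logistic is ill-conditioned, so dose-valued
# truths get a small absolute floor on top of the relative bound.
expectTruth <- function(got, truth, relTol, absFloor = 0, info = "") {
  expect_lt(abs(got - truth), max(relTol * abs(truth), absFloor),
            label = sprintf("|%g - %g| (%s)", got, truth, info))
}

test_that("generated cases satisfy all structural invariants", {
  coh <- generateCohort(10, exampleSpec(), jitter = 0.2, seed = 4)
  for (item in coh) {
    expect_true(validObject(item$case, test = TRUE))
    for (s in structures(item$case)) {
      expect_true(all(diff(doseGrid(s)) > 0))
      expect_true(all(diff(cumVolume(s)) <= 0))
      expect_true(all(cumVolume(s) >= 0))
      expect_gt(totalVolume(s), 0.03)
    }
    expect_identical(nrow(item$truth), 5L * length(structures(item$case)))
    for (e in item$truth$expression)
      expect_s4_class(parseExpression(e), "DoseVolumePoint")
  }
})

test_that("closed-form truths are reproduced by the evaluator", {
  # linear family: exact closed forms
  spec <- syntheticSpec(list(PTV = list(volume = 100, profile = profileLinear(100))),
                        rxDose = 50)
  gen <- generateCase(spec)
  tr <- gen$truth
  expect_equal(tr$value[tr$expression == "Dmean"], 50)
  expect_equal(tr$value[tr$expression == "D(Gy)40(cc)"], 60)
  s <- structures(gen$case)[[1]]
  ref <- ReferenceDose("prescription", 50)
  for (i in seq_len(nrow(tr))) {
    got <- metricValue(evaluatePoint(parseExpression(tr$expression[i]), s, ref))
    expect_equal(got, tr$value[i], tolerance = 1e-6, info = tr$expression[i])
  }

  # uniform family: mean ~ plateau dose, near-max ~ near-min
  spec <- syntheticSpec(list(S = list(volume = 30, profile = profileUniform(60))))
  gen <- generateCase(spec)
  tr <- gen$truth
  expect_equal(tr$value[tr$expression == "Dmean"], 60, tolerance = 1e-3)
  expect_equal(tr$value[tr$expression == "Dmax"],
               tr$value[tr$expression == "Dmin"], tolerance = 1e-2)
  s <- structures(gen$case)[[1]]
  for (i in seq_len(nrow(tr))) {
    got <- metricValue(evaluatePoint(parseExpression(tr$expression[i]), s))
    expect_equal(got, tr$value[i], tolerance = 1e-6, info = tr$expression[i])
  }

  # sigmoid: half the volume is covered at d50
  spec <- syntheticSpec(list(S = list(volume = 100,
                                      profile = profileSigmoid(60, 0.5))))
  gen <- generateCase(spec)
  tr <- gen$truth
  expect_equal(tr$value[tr$expression == "V(cc)60(Gy)"], 50)
  s <- structures(gen$case)[[1]]
  for (i in seq_len(nrow(tr))) {
    got <- metricValue(evaluatePoint(parseExpression(tr$expression[i]), s))
    expectTruth(got, tr$value[i], relTol = 1e-3, absFloor = 0.01,
                info = tr$expression[i])
  }
})

test_that("evaluator matches the attached truth maps across a jittered cohort", {
  coh <- generateCohort(8, exampleSpec(), jitter = 0.15, seed = 13)
  sigmoidStructs <- c("Lungs", "Heart", "Esophagus")
  for (item in coh) {
    ref <- ReferenceDose("prescription", rxDose(item$case))
    for (i in seq_len(nrow(item$truth))) {
      tr <- item$truth[i, ]
      s <- matchStructure(item$case, tr$structure)
      got <- metricValue(evaluatePoint(parseExpression(tr$expression), s, ref))
      if (tr$structure %in% sigmoidStructs) {
        expectTruth(got, tr$value, relTol = 1e-3, absFloor = 0.01,
                    info = paste(tr$structure, tr$expression))
      } else {
        expectTruth(got, tr$value, relTol = 1e-6, absFloor = 1e-9,
                    info = paste(tr$structure, tr$expression))
      }
    }
  }
})

test_that("cohort generation is deterministic and jitter-degenerate at 0", {
  a <- generateCohort(5, exampleSpec(), jitter = 0.2, seed = 99)
  b <- generateCohort(5, exampleSpec(), jitter = 0.2, seed = 99)
  expect_equal(a, b)
  c1 <- generateCohort(3, exampleSpec(), jitter = 0, seed = 1)
  for (k in 2:3) {
    expect_equal(structures(c1[[k]]$case), structures(c1[[1]]$case))
    expect_equal(c1[[k]]$truth$value, c1[[1]]$truth$value)
  }
  # different seeds give different cohorts
  d1 <- generateCohort(3, exampleSpec(), jitter = 0.2, seed = 2)
  expect_false(isTRUE(all.equal(structures(d1[[1]]$case),
                                structures(a[[1]]$case))))
})

test_that("the cohort median of a linear-family mean dose sits at the base value", {
  base <- syntheticSpec(list(S = list(volume = 100, profile = profileLinear(80))),
                        rxDose = 50)
  coh <- generateCohort(100, base, jitter = 0.1, seed = 31)
  means <- vapply(coh, function(item)
    as.numeric(meanDose(structures(item$case)[[1]])), numeric(1))
  med <- stats::median(means)
  # lognormal jitter: median of Dmean = D0/2 = 40 Gy; allow 3 standard errors
  # of the sample median (~ 1.25 * sd / sqrt(n))
  se <- 1.25 * stats::sd(means) / sqrt(length(means))
  expect_lt(abs(med - 40), 3 * se + 0.05)   # 0.05 Gy for grid snapping
})

test_that("invalid synthetic specs are refused", {
  expect_error(syntheticSpec(list(S = list(volume = 0.02,
                                           profile = profileLinear(50)))),
               class = "dvhValidationError")
  expect_error(syntheticSpec(list(S = list(volume = 100, profile = "linear"))),
               class = "dvhValidationError")
  expect_error(profileLinear(-5))
  expect_error(profileSigmoid(60, slope = 0))
})
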