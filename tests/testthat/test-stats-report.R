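test_that("the quantile follows the stated order-statistic formula", {
  expect_equal(dvhQuantile(c(5, 5, 5), 10), 5)
  expect_equal(dvhQuantile(c(5, 5, 5), 95), 5)
  expect_equal(dvhQuantile(7, 50), 7)
  expect_equal(dvhQuantile(1:100, 99), 99.01)
  # hand-applied formula on a small unsorted sample
  x <- c(3, 1, 4, 1, 5)   # sorted: 1 1 3 4 5; h = 4*0.85 + 1 = 4.4
  expect_equal(dvhQuantile(x, 85), 4 + 0.4 * (5 - 4))
  # median of odd n is the textbook median
  expect_equal(dvhQuantile(c(9, 2, 7), 50), 7)
  expect_error(dvhQuantile(numeric(0), 50), class = "dvhDomainError")
  expect_error(dvhQuantile(1:5, 0), class = "dvhDomainError")
  expect_error(dvhQuantile(1:5, 100), class = "dvhDomainError")
})

test_that("the quantile matches the type-7 reference implementation", {
  set.seed(5)
  levels <- c(1, 2, 5, 10, 15, 85, 90, 95, 98, 99)
  for (k in 1:20) {
    x <- rnorm(sample(1:60, 1), mean = 50, sd = 10)
    expect_equal(dvhQuantile(x, levels),
                 unname(stats::quantile(x, levels / 100, type = 7)),
                 tolerance = 1e-12)
  }
})

test_that("quantiles are monotone in level and bounded by the data", {
  set.seed(8)
  for (k in 1:10) {
    x <- runif(sample(2:40, 1), 0, 100)
    q <- dvhQuantile(x, sort(runif(15, 1, 99)))
    expect_true(all(diff(q) >= -1e-12))
    expect_true(all(q >= min(x) - 1e-12 & q <= max(x) + 1e-12))
  }
})

exampleReportFixture <- function(n = 5, seed = 21) {
  coh <- generateCohort(n, exampleSpec(), jitter = 0.1, seed = seed)
  req <- exampleRequest()
  tab <- runBatch(lapply(coh, `[[`, "case"), req,
                  runSettings("prescription", globalRx = 60))
  list(tab = tab, req = req, report = buildReport(tab, req))
}

test_that("the report has one sheet per structure plus an overview", {
  fx <- exampleReportFixture()
  rep <- fx$report
  expect_length(rep@sheets, 6L)
  expect_identical(names(rep@sheets),
                   vapply(requestRows(fx$req), `[[`, character(1), "structure"))
  expect_identical(nrow(rep@overview$columns), 14L)
  # single-structure request: overview values identical to the structure sheet
  req1 <- reviewRequest(PTV = c("Dmean", "Dmax"))
  cs <- DVHCase("A", list(linearStructure(name = "PTV")), rxDose = 50)
  rep1 <- buildReport(runBatch(list(cs), req1, runSettings("prescription")), req1)
  expect_length(rep1@sheets, 1L)
  expect_identical(unname(rep1@overview$values), unname(rep1@sheets$PTV$values))
})

test_that("the stats block matches direct quantile calls and skips absences", {
  fx <- exampleReportFixture()
  ov <- fx$report@overview
  df <- cells(fx$tab)
  for (j in seq_len(nrow(ov$columns))) {
    vals <- df$value[df$structure == ov$columns$structure[j] &
                     df$expression == ov$columns$expression[j]]
    vals <- vals[!is.na(vals)]
    expect_identical(unname(ov$counts[j]), length(vals))
    expect_equal(unname(ov$stats[, j]),
                 dvhQuantile(vals, c(1, 2, 5, 10, 15, 85, 90, 95, 98, 99)))
  }

  # a case lacking one structure contributes n-1 to that column only
  cs1 <- DVHCase("A", list(linearStructure(name = "PTV"),
                           linearStructure(name = "Lungs")), rxDose = 50)
  cs2 <- DVHCase("B", list(linearStructure(name = "PTV")), rxDose = 50)
  req <- reviewRequest(PTV = "Dmean", Lungs = "Dmean")
  rep <- buildReport(runBatch(list(cs1, cs2), req, runSettings("prescription")), req)
  expect_identical(unname(rep@overview$counts), c(2L, 1L))
  expect_identical(unname(rep@sheets$Lungs$counts), 1L)
  expect_identical(rep@sheets$Lungs$notes[2, 1], "structure_missing")
})

test_that("csv output re-reads within rounding, regenerates byte-identically", {
  fx <- exampleReportFixture()
  d1 <- tempfile()
  files <- writeReport(fx$report, d1)
  expect_length(files, 7L)   # 6 structures + overview
  expect_true(file.exists(file.path(d1, "overview.csv")))

  # values in the file match the report within the 2-decimal rendering
  lines <- readLines(file.path(d1, "overview.csv"))
  headerAt <- grep("^CaseID", lines)
  valRows <- read.csv(text = lines[(headerAt + 2):(headerAt + 1 + length(fx$report@overview$caseIDs))],
                      header = FALSE, colClasses = "character")
  valueCols <- seq(2, by = 2, length.out = nrow(fx$report@overview$columns))
  got <- suppressWarnings(apply(as.matrix(valRows[, valueCols]), 2, as.numeric))
  expect_true(all(abs(got - fx$report@overview$values) <= 0.005, na.rm = TRUE))

  d2 <- tempfile()
  writeReport(fx$report, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }

  # layout: request echo precedes values precedes statistics
  expect_match(lines[1], "^Request,")
  expect_true(headerAt > sum(grepl("^Request,", lines)))
  expect_true(grep("^Statistics", lines) > headerAt)
  expect_match(lines[grep("^Statistics", lines) + 1], "^n,")
  expect_match(lines[length(lines)], "^Q99%")
})

test_that("structure sheet file names are sanitized and xlsx is refused", {
  cs <- DVHCase("A", list(linearStructure(name = "Spinal Cord/PRV")), rxDose = 50)
  req <- reviewRequest(`Spinal Cord/PRV` = "Dmax")
  rep <- buildReport(runBatch(list(cs), req, runSettings("prescription")), req)
  d <- tempfile()
  writeReport(rep, d)
  expect_true(file.exists(file.path(d, "Spinal_Cord_PRV.csv")))
  expect_error(writeReport(rep, d, format = "xlsx"), class = "dvhValidationError")
  # full-precision sidecars on request
  writeReport(rep, d, fullPrecision = TRUE)
  expect_true(file.exists(file.path(d, "overview_fullprecision.csv")))
})
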