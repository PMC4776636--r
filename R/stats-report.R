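#' @include AllClasses.R
NULL

# The ten cohort quantile levels reported for every dose/volume point.
QUANTILE_LEVELS <- c(1, 2, 5, 10, 15, 85, 90, 95, 98, 99)

#' Order-statistic quantile with linear interpolation
#'
#' The quantile convention used throughout the reports, stated as a formula so
#' it reproduces bit-for-bit anywhere: on the sorted values (1-based ranks),
#' \code{h = (n - 1) * level/100 + 1} and the result is
#' \code{x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])}.
#'
#' @param values Non-empty numeric vector (no NAs).
#' @param level Quantile level(s) in percent, strictly between 0 and 100.
#' @return The quantile value(s).
#' @examples
#' dvhQuantile(1:100, 99)   # 99.01
#' @export
dvhQuantile <- function(values, level) {
  if (!is.numeric(values) || !length(values) || anyNA(values))
    domainError("quantile needs a non-empty numeric vector without NAs")
  if (!is.numeric(level) || !length(level) || anyNA(level) ||
      any(level <= 0) || any(level >= 100))
    domainError("quantile level must lie strictly between 0 and 100 (percent)")
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * level / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

sanitizeFileName <- function(name) gsub("[^A-Za-z0-9]+", "_", name)

# Assemble one sheet: values/notes matrices ordered cases x columns, the
# per-column contributing-case count, and the quantile-statistics block
# (computed only over cells holding values).
makeSheet <- function(title, structure, columnsDf, df, caseIDs) {
  ncolV <- nrow(columnsDf)
  key <- function(cid, st, ex) paste(cid, st, ex, sep = "\r")
  idx <- match(
    key(rep(caseIDs, each = ncolV),
        rep(columnsDf$structure, times = length(caseIDs)),
        rep(columnsDf$expression, times = length(caseIDs))),
    key(df$caseID, df$structure, df$expression))
  stopifnot(!anyNA(idx))
  values <- matrix(df$value[idx], nrow = length(caseIDs), ncol = ncolV,
                   byrow = TRUE, dimnames = list(caseIDs, columnsDf$expression))
  notes <- matrix(ifelse(df$status[idx] != "ok", df$status[idx], df$flags[idx]),
                  nrow = length(caseIDs), ncol = ncolV, byrow = TRUE)
  counts <- as.integer(colSums(!is.na(values)))
  names(counts) <- columnsDf$expression
  stats <- matrix(NA_real_, nrow = length(QUANTILE_LEVELS), ncol = ncolV,
                  dimnames = list(sprintf("Q%g%%", QUANTILE_LEVELS),
                                  columnsDf$expression))
  for (j in seq_len(ncolV)) {
    ok <- values[, j][!is.na(values[, j])]
    if (length(ok)) stats[, j] <- dvhQuantile(ok, QUANTILE_LEVELS)
  }
  list(title = title, structure = structure, columns = columnsDf,
       caseIDs = caseIDs, values = values, notes = notes, counts = counts,
       stats = stats)
}

#' Build the summary report from a batch result
#'
#' Produces one sheet per requested structure (cases by that structure's
#' expressions) plus an overview sheet (cases by every structure/expression
#' pair), each ending with the statistics block: the count of contributing
#' cases and the 1, 2, 5, 10, 15, 85, 90, 95, 98 and 99\% quantiles per
#' column. Absent cells are excluded from the statistics and the count shows
#' how many cases contributed.
#'
#' @param table A \linkS4class{ResultTable} from \code{\link{runBatch}}.
#' @param request The \linkS4class{ReviewRequest} that produced it.
#' @return A \linkS4class{SummaryReport}.
#' @seealso \code{\link{writeReport}}
#' @export
buildReport <- function(table, request) {
  stopifnot(is(table, "ResultTable"), is(request, "ReviewRequest"))
  validObject(table)
  validObject(request)
  df <- table@cells
  caseIDs <- unique(df$caseID)
  sheets <- list()
  allCols <- list()
  for (row in request@rows) {
    colsDf <- data.frame(
      structure = row$structure,
      expression = vapply(row$points, formatExpression, character(1)),
      stringsAsFactors = FALSE)
    allCols[[length(allCols) + 1L]] <- colsDf
    sheets[[row$structure]] <- makeSheet(row$structure, row$structure,
                                         colsDf, df, caseIDs)
  }
  overview <- makeSheet("overview", NA_character_,
                        do.call(rbind, allCols), df, caseIDs)
  new("SummaryReport", request = request, sheets = sheets, overview = overview)
}

# Render one sheet as CSV lines, mirroring the three report regions:
# the echoed request, the value block (one annotation column beside each
# value column), and the statistics block.
renderSheetCsv <- function(sheet, request, digits = 2L) {
  fmtVal <- function(x) ifelse(is.na(x), "", sprintf(sprintf("%%.%df", digits), x))
  echoRows <- if (is.na(sheet$structure)) request@rows
              else Filter(function(r) r$structure == sheet$structure, request@rows)
  echo <- vapply(echoRows, function(row)
    csvLine(c("Request", row$structure,
              vapply(row$points, formatExpression, character(1)))),
    character(1))

  interleave <- function(vals, notes) as.vector(rbind(vals, notes))
  header1 <- csvLine(c("CaseID", interleave(sheet$columns$structure,
                                            rep("", nrow(sheet$columns)))))
  header2 <- csvLine(c("", interleave(sheet$columns$expression,
                                      rep("note", nrow(sheet$columns)))))
  valueLines <- vapply(seq_along(sheet$caseIDs), function(i)
    csvLine(c(sheet$caseIDs[i],
              interleave(fmtVal(sheet$values[i, ]), sheet$notes[i, ]))),
    character(1))

  pad <- rep("", nrow(sheet$columns))
  statHeader <- csvLine(c("Statistics", interleave(pad, pad)))
  countLine <- csvLine(c("n", interleave(as.character(sheet$counts), pad)))
  statLines <- vapply(seq_len(nrow(sheet$stats)), function(i)
    csvLine(c(rownames(sheet$stats)[i], interleave(fmtVal(sheet$stats[i, ]), pad))),
    character(1))

  c(echo, "", header1, header2, valueLines, "", statHeader, countLine, statLines)
}

#' Write a summary report to disk
#'
#' CSV mode writes one RFC 4180 file per structure sheet
#' (\code{<structure>.csv}, name sanitized to be filesystem-safe) plus
#' \code{overview.csv} into \code{path}. Numbers are rendered with 2 decimal
#' places; with \code{fullPrecision = TRUE} a
#' \code{*_fullprecision.csv} sidecar per sheet preserves 15 significant
#' digits. Regenerating the same report is byte-identical. The \code{"xlsx"}
#' format is not implemented in this package; CSV is the supported audit
#' format.
#'
#' @param report A \linkS4class{SummaryReport}.
#' @param path Output directory (created if missing).
#' @param format \code{"csv"}.
#' @param fullPrecision Also write full-precision sidecar files
#'   (default off).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, path, format = c("csv", "xlsx"),
                        fullPrecision = FALSE) {
  stopifnot(is(report, "SummaryReport"))
  format <- match.arg(format)
  if (format == "xlsx")
    validationError("format 'xlsx' is not implemented; use format = 'csv'")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    ioError(sprintf("cannot create output directory %s", path))
  allSheets <- c(report@sheets, list(overview = report@overview))
  fileNames <- c(vapply(report@sheets, function(s)
    sanitizeFileName(s$title), character(1)), "overview")
  written <- character(0)
  for (i in seq_along(allSheets)) {
    f <- file.path(path, paste0(fileNames[i], ".csv"))
    writeLinesUtf8(renderSheetCsv(allSheets[[i]], report@request), f)
    written <- c(written, f)
    if (fullPrecision) {
      f2 <- file.path(path, paste0(fileNames[i], "_fullprecision.csv"))
      writeLinesUtf8(renderSheetCsv(allSheets[[i]], report@request,
                                    digits = 15L), f2)
      written <- c(written, f2)
    }
  }
  invisible(written)
}
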