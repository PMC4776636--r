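#' @include AllClasses.R
NULL

# DVH CSV dialect (as exported by commercial DVH-review software):
#   row 1: case/site ID, (spare), optional prescription dose in cell C1,
#          optional global maximum dose in cell D1
#   row 2: label over the dose column (ignored), then structure names
#   rows 3+: dose (Gy) in column 1, absolute volumes (cc) per structure
# RFC 4180 quoting, UTF-8, BOM tolerated, '.' decimal separator. Trailing
# all-empty rows and columns are stripped before validation.

#' Parse a prescription/maximum-dose header cell
#'
#' Header cells C1/D1 carry the case-specific prescription dose and global
#' maximum dose in either the long form (\code{"Rx = 60 Gy"},
#' \code{"Dmax = 80 Gy"}) or the short form (a bare number, \code{"60"}).
#' The key and the unit are matched case-insensitively and surrounding
#' whitespace is ignored.
#'
#' @param cellText A single non-empty string.
#' @return The dose in Gy as a number.
#' @examples
#' parseHeaderDose("Rx = 60 Gy")
#' parseHeaderDose("80")
#' @export
parseHeaderDose <- function(cellText) {
  if (!is.character(cellText) || length(cellText) != 1L || is.na(cellText) ||
      !nzchar(trimWs(cellText)))
    formatError("header dose cell is empty")
  pat <- "^\\s*(?:(?:rx|dmax)\\s*=\\s*)?([0-9]+(?:\\.[0-9]+)?)\\s*(?:gy)?\\s*$"
  m <- regmatches(cellText, regexec(pat, cellText, ignore.case = TRUE))[[1L]]
  if (length(m) != 2L)
    formatError(sprintf("cannot parse header dose cell: \"%s\"", cellText),
                cellText = cellText)
  as.numeric(m[2L])
}

# Read the raw character field matrix of a DVH csv file, stripping a BOM and
# trailing all-empty rows/columns.
readCsvFields <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8-BOM", blank.lines.skip = FALSE,
                    strip.white = FALSE, na.strings = character(0)),
    error = function(e) formatError(sprintf("malformed CSV in %s: %s",
                                            path, conditionMessage(e))))
  mat <- as.matrix(df)
  mat[is.na(mat)] <- ""
  rowEmpty <- apply(mat, 1L, function(r) all(!nzchar(trimWs(r))))
  while (nrow(mat) && rowEmpty[nrow(mat)]) {
    mat <- mat[-nrow(mat), , drop = FALSE]
    rowEmpty <- rowEmpty[-length(rowEmpty)]
  }
  colEmpty <- apply(mat, 2L, function(x) all(!nzchar(trimWs(x))))
  while (ncol(mat) && colEmpty[ncol(mat)]) {
    mat <- mat[, -ncol(mat), drop = FALSE]
    colEmpty <- colEmpty[-length(colEmpty)]
  }
  mat
}

#' Read a DVH CSV file into a DVHCase
#'
#' Reads one case's cumulative DVHs from the CSV dialect described above:
#' column 1 of the numeric block becomes the shared dose grid, every further
#' column one \linkS4class{StructureDVH} named by row 2, and header cells
#' C1/D1 (when non-empty) the case prescription dose and global maximum dose
#' via \code{\link{parseHeaderDose}}. Volumes are absolute (cc).
#'
#' Malformed numeric cells raise a format error naming the row and column;
#' a non-monotone dose column, negative volumes or duplicate structure names
#' raise validation errors.
#'
#' @param path Path to the CSV file.
#' @return A \linkS4class{DVHCase}.
#' @seealso \code{\link{writeDVH}}
#' @export
readDVH <- function(path) {
  mat <- readCsvFields(path)
  if (nrow(mat) < 3L)
    formatError(sprintf("%s: a DVH file needs at least 3 rows (ID, names, data), got %d",
                        path, nrow(mat)))
  if (ncol(mat) < 2L)
    formatError(sprintf("%s: a DVH file needs at least 2 columns (dose + 1 structure), got %d",
                        path, ncol(mat)))

  caseID <- trimWs(mat[1L, 1L])
  if (!nzchar(caseID))
    formatError(sprintf("%s: cell A1 (case/site ID) is empty", path))
  rxCell <- if (ncol(mat) >= 3L) trimWs(mat[1L, 3L]) else ""
  mxCell <- if (ncol(mat) >= 4L) trimWs(mat[1L, 4L]) else ""
  rx <- if (nzchar(rxCell)) parseHeaderDose(rxCell) else NA_real_
  mx <- if (nzchar(mxCell)) parseHeaderDose(mxCell) else NA_real_

  # Header cells C1/D1 may extend row 1 beyond the data columns; columns whose
  # numeric block is entirely empty are header-only and carry no structure.
  blockEmpty <- apply(mat[-(1:2), , drop = FALSE], 2L,
                      function(x) all(!nzchar(trimWs(x))))
  while (ncol(mat) > 1L && blockEmpty[ncol(mat)]) {
    mat <- mat[, -ncol(mat), drop = FALSE]
    blockEmpty <- blockEmpty[-length(blockEmpty)]
  }
  if (ncol(mat) < 2L)
    formatError(sprintf("%s: no structure volume columns found", path))

  structNames <- trimWs(mat[2L, -1L])
  if (any(!nzchar(structNames)))
    formatError(sprintf("%s: empty structure name in row 2, column %d",
                        path, which(!nzchar(structNames))[1L] + 1L))
  if (anyDuplicated(structNames))
    validationError(sprintf("%s: duplicate structure name(s): %s", path,
                            paste(unique(structNames[duplicated(structNames)]),
                                  collapse = ", ")))

  numBlock <- mat[-(1:2), , drop = FALSE]
  nums <- suppressWarnings(
    matrix(as.numeric(trimWs(numBlock)), nrow = nrow(numBlock)))
  if (anyNA(nums)) {
    bad <- which(is.na(nums), arr.ind = TRUE)[1L, ]
    formatError(sprintf("%s: non-numeric value \"%s\" at row %d, column %d",
                        path, numBlock[bad[1L], bad[2L]], bad[1L] + 2L, bad[2L]))
  }
  dose <- nums[, 1L]
  if (any(dose < 0) || any(diff(dose) <= 0))
    validationError(sprintf("%s: dose column must be non-negative and strictly increasing",
                            path))
  structuresList <- lapply(seq_along(structNames), function(j) {
    vol <- nums[, j + 1L]
    if (any(vol < 0))
      validationError(sprintf("%s: negative volume for structure \"%s\"",
                              path, structNames[j]))
    if (any(diff(vol) > 0))
      validationError(sprintf("%s: cumulative volume for structure \"%s\" increases along the dose grid",
                              path, structNames[j]))
    StructureDVH(name = structNames[j], doseGrid = dose, cumVolume = vol)
  })
  DVHCase(caseID = caseID, rxDose = rx, globalMaxDose = mx,
          structures = structuresList)
}

#' Write a DVHCase as a DVH CSV file
#'
#' Emits the same dialect \code{\link{readDVH}} parses: reading the written
#' file back yields an equivalent case (identical grid and header doses,
#' volumes to formatting precision). Absent prescription/maximum doses leave
#' C1/D1 empty.
#'
#' @param case A valid \linkS4class{DVHCase}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeDVH <- function(case, path) {
  stopifnot(is(case, "DVHCase"))
  validObject(case)
  rxCell <- if (is.na(case@rxDose)) "" else sprintf("Rx = %s Gy", fmtNum(case@rxDose))
  mxCell <- if (is.na(case@globalMaxDose)) ""
            else sprintf("Dmax = %s Gy", fmtNum(case@globalMaxDose))
  header1 <- csvLine(c(case@caseID, "", rxCell, mxCell))
  header2 <- csvLine(c("Dose (Gy)", structureNames(case)))
  grid <- doseGrid(case@structures[[1L]])
  volCols <- lapply(case@structures, function(s) fmtNum(cumVolume(s)))
  dataLines <- do.call(paste, c(list(fmtNum(grid)), volCols, sep = ","))
  writeLinesUtf8(c(header1, header2, dataLines), path)
  invisible(path)
}
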