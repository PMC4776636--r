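#' @include AllClasses.R
NULL

# Request file grammar (plain text, UTF-8):
#   StructureName: expr1, expr2, ...
# one line per structure; blank lines and lines starting with '#' are
# ignored. Structure names may not contain ':' or ',' (commas separate
# expressions; expressions never contain colons).

#' Load a dosimetry-review request from a plain-text file
#'
#' Every expression is parsed with \code{\link{parseExpression}}; failures are
#' collected across the whole file and reported together with their line
#' numbers, so one pass shows every offending expression.
#'
#' @param path Path to the request file.
#' @return A \linkS4class{ReviewRequest}.
#' @seealso \code{\link{saveRequest}}, \code{\link{validateRequestSyntax}}
#' @export
loadRequest <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines))
    lines[1L] <- sub("^\ufeff", "", lines[1L])
  rows <- list()
  seen <- character(0)
  problems <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimWs(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L) {
      problems <- c(problems, sprintf("line %d: expected 'StructureName: expressions'", ln))
      next
    }
    name <- trimWs(substr(line, 1L, colon - 1L))
    if (!nzchar(name)) {
      problems <- c(problems, sprintf("line %d: empty structure name", ln))
      next
    }
    if (name %in% seen) {
      problems <- c(problems, sprintf("line %d: duplicate structure line \"%s\"", ln, name))
      next
    }
    seen <- c(seen, name)
    exprs <- trimWs(strsplit(substring(line, colon + 1L), ",", fixed = TRUE)[[1L]])
    exprs <- exprs[nzchar(exprs)]
    if (!length(exprs)) {
      problems <- c(problems, sprintf("line %d: no expressions for \"%s\"", ln, name))
      next
    }
    bad <- validateRequestSyntax(exprs)
    if (nrow(bad)) {
      problems <- c(problems, sprintf("line %d: %s", ln, bad$message))
      next
    }
    rows[[length(rows) + 1L]] <- list(structure = name,
                                      points = lapply(exprs, parseExpression))
  }
  if (length(problems))
    formatError(paste0(sprintf("invalid request file %s:\n", path),
                       paste(problems, collapse = "\n")))
  if (!length(rows))
    formatError(sprintf("request file %s contains no request rows", path))
  ReviewRequest(rows = rows)
}

#' Save a dosimetry-review request as a plain-text file
#'
#' Writes the canonical form (expressions via \code{\link{formatExpression}})
#' so that \code{\link{loadRequest}} inverts it and repeated saves of the same
#' request are byte-identical.
#'
#' @param request A valid \linkS4class{ReviewRequest}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
saveRequest <- function(request, path) {
  stopifnot(is(request, "ReviewRequest"))
  validObject(request)
  lines <- vapply(request@rows, function(row) {
    sprintf("%s: %s", row$structure,
            paste(vapply(row$points, formatExpression, character(1)),
                  collapse = ", "))
  }, character(1))
  writeLinesUtf8(lines, path)
  invisible(path)
}

#' Find a requested structure in a case
#'
#' Exact match on whitespace-trimmed names first; failing that, a
#' case-insensitive match is accepted but raises a \code{dvhNamingDeviation}
#' warning, since trial protocols expect exact standard structure names.
#' With no match at all, \code{NULL} is returned.
#'
#' @param case A \linkS4class{DVHCase}.
#' @param name Requested structure name.
#' @return The matching \linkS4class{StructureDVH}, or \code{NULL}.
#' @export
matchStructure <- function(case, name) {
  stopifnot(is(case, "DVHCase"))
  name <- trimWs(name)
  if (!nzchar(name)) validationError("structure name must be non-empty")
  present <- structureNames(case)
  hit <- which(present == name)
  if (length(hit)) return(case@structures[[hit[1L]]])
  hit <- which(tolower(present) == tolower(name))
  if (length(hit)) {
    warning(structure(
      class = c("dvhNamingDeviation", "warning", "condition"),
      list(message = sprintf(
        "case \"%s\": structure \"%s\" matched \"%s\" only case-insensitively; names should follow the standard naming convention exactly",
        case@caseID, name, present[hit[1L]]), call = sys.call(-1))))
    return(case@structures[[hit[1L]]])
  }
  NULL
}

# Does this point need the percent-dose reference at all?
pointNeedsRef <- function(p) {
  (p@metric == "D" && identical(p@outUnit, "%")) ||
    (p@metric == "V" && identical(p@argUnit, "%"))
}

#' Evaluate a review request over a cohort of cases
#'
#' The processing loop: cases in input order; within a case, request rows in
#' order; within a row, points in order. The reference dose (and the
#' prescription dose for \code{/Rx}) is resolved once per case. Per-cell
#' failures are recorded as data -- \code{structure_missing} when the case
#' lacks the requested structure, \code{evaluation_error} (with the message)
#' otherwise -- and never abort the batch; a case with no resolvable reference
#' still yields values for every cell that needs neither a percent dose nor
#' \code{/Rx}.
#'
#' @param cases List of \linkS4class{DVHCase} objects (at least one).
#' @param request A \linkS4class{ReviewRequest}.
#' @param settings A \code{\link{runSettings}} object.
#' @return A \linkS4class{ResultTable} with one cell per
#'   (case, request row, point) triple, in deterministic input order.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' cs <- DVHCase("PT001", list(s), rxDose = 60)
#' req <- reviewRequest(PTV = c("Dmean", "D(Gy)40(cc)"))
#' cells(runBatch(list(cs), req, runSettings("prescription")))
#' @export
runBatch <- function(cases, request, settings = runSettings()) {
  if (is(cases, "DVHCase")) cases <- list(cases)
  stopifnot(length(cases) >= 1L,
            all(vapply(cases, is, logical(1), "DVHCase")),
            is(request, "ReviewRequest"),
            inherits(settings, "dvhRunSettings"))
  validObject(request)

  rows <- list()
  for (case in cases) {
    ref <- tryCatch(resolveReferenceDose(case, settings),
                    dvhMissingReferenceError = function(e) NULL)
    rx <- if (!is.na(case@rxDose)) case@rxDose
          else if (!is.null(settings$globalRx)) settings$globalRx
          else NULL
    for (reqRow in request@rows) {
      s <- matchStructure(case, reqRow$structure)
      for (p in reqRow$points) {
        expr <- formatExpression(p)
        cell <- list(caseID = case@caseID, structure = reqRow$structure,
                     expression = expr, value = NA_real_, unit = NA_character_,
                     flags = "", status = "ok", reason = "")
        if (is.null(s)) {
          cell$status <- "structure_missing"
          cell$reason <- sprintf("structure \"%s\" not present in case",
                                 reqRow$structure)
        } else {
          mv <- tryCatch(evaluatePoint(p, s, ref = ref, rx = rx),
                         dvhError = function(e) e)
          if (is(mv, "MetricValue")) {
            cell$value <- mv@value
            cell$unit <- mv@unit
            cell$flags <- paste(mv@flags, collapse = ",")
          } else {
            cell$status <- "evaluation_error"
            cell$reason <- conditionMessage(mv)
          }
        }
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  new("ResultTable", cells = df)
}
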