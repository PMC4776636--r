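#' @include AllGenerics.R
NULL

#' StructureDVH: one structure's cumulative dose-volume histogram
#'
#' Holds the cumulative DVH of a single contoured structure: a strictly
#' increasing dose grid (Gy) and, for each grid dose, the absolute volume (cc)
#' receiving at least that dose. The total structure volume is by definition
#' the cumulative volume at the lowest grid dose.
#'
#' @slot name Structure label (whitespace-trimmed, non-empty).
#' @slot doseGrid Numeric vector of doses in Gy, strictly increasing, all >= 0.
#' @slot cumVolume Numeric vector of absolute volumes in cc, non-increasing
#'   along the grid, all >= 0, same length as \code{doseGrid}.
#'
#' @param name,doseGrid,cumVolume See slots.
#' @return \code{StructureDVH()} returns a validated \code{StructureDVH} object.
#' @examples
#' s <- StructureDVH("PTV", doseGrid = 0:100, cumVolume = 100 - 0:100)
#' totalVolume(s)
#' @exportClass StructureDVH
setClass("StructureDVH",
  representation(name = "character", doseGrid = "numeric", cumVolume = "numeric"))

#' @rdname StructureDVH-class
#' @export
StructureDVH <- function(name, doseGrid, cumVolume) {
  new("StructureDVH", name = as.character(name),
      doseGrid = as.numeric(doseGrid), cumVolume = as.numeric(cumVolume))
}

setValidity("StructureDVH", function(object) {
  msgs <- character(0)
  nm <- object@name
  d  <- object@doseGrid
  v  <- object@cumVolume
  if (length(nm) != 1L || is.na(nm) || !nzchar(trimWs(nm)))
    msgs <- c(msgs, "structure name must be a single non-empty string")
  if (length(d) < 2L)
    msgs <- c(msgs, "dose grid must have at least 2 points")
  if (anyNA(d) || anyNA(v))
    msgs <- c(msgs, "dose grid and volumes must not contain NA")
  else {
    if (any(d < 0)) msgs <- c(msgs, "dose grid values must be >= 0")
    if (any(diff(d) <= 0)) msgs <- c(msgs, "dose grid must be strictly increasing")
    if (any(v < 0)) msgs <- c(msgs, "cumulative volumes must be >= 0")
    if (any(diff(v) > 0)) msgs <- c(msgs, "cumulative volumes must be non-increasing")
  }
  if (length(d) != length(v))
    msgs <- c(msgs, "dose grid and volume vector lengths differ")
  if (length(msgs)) msgs else TRUE
})

#' DVHCase: one patient/case with its structure DVHs
#'
#' A single case as exported to a DVH CSV file: the patient/site ID, the
#' optional case-specific prescription dose (header cell C1) and global maximum
#' dose (header cell D1), and the structures, all sharing one dose grid.
#'
#' @slot caseID Patient/site identifier, non-empty.
#' @slot rxDose Case-specific prescription dose in Gy, or \code{NA} if the file
#'   does not carry one. A value present here overrides any globally configured
#'   prescription dose.
#' @slot globalMaxDose Case global maximum dose in Gy, or \code{NA}. Required
#'   when the reference-dose mode is \code{"maximum"}, since plans do not share
#'   one global maximum.
#' @slot structures List of \linkS4class{StructureDVH}, unique names after
#'   whitespace trimming, all on the same dose grid.
#'
#' @param caseID,structures,rxDose,globalMaxDose See slots.
#' @return \code{DVHCase()} returns a validated \code{DVHCase} object.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' cs <- DVHCase("PT001", list(s), rxDose = 60)
#' rxDose(cs)
#' @exportClass DVHCase
setClass("DVHCase",
  representation(caseID = "character", rxDose = "numeric",
                 globalMaxDose = "numeric", structures = "list"),
  prototype(rxDose = NA_real_, globalMaxDose = NA_real_))

#' @rdname DVHCase-class
#' @export
DVHCase <- function(caseID, structures, rxDose = NA_real_,
                    globalMaxDose = NA_real_) {
  new("DVHCase", caseID = as.character(caseID), structures = structures,
      rxDose = as.numeric(rxDose), globalMaxDose = as.numeric(globalMaxDose))
}

setValidity("DVHCase", function(object) {
  msgs <- character(0)
  if (length(object@caseID) != 1L || is.na(object@caseID) ||
      !nzchar(trimWs(object@caseID)))
    msgs <- c(msgs, "caseID must be a single non-empty string")
  for (sl in c("rxDose", "globalMaxDose")) {
    x <- slot(object, sl)
    if (length(x) != 1L)
      msgs <- c(msgs, sprintf("%s must be a single number or NA", sl))
    else if (!is.na(x) && x <= 0)
      msgs <- c(msgs, sprintf("%s must be > 0 when present", sl))
  }
  if (!length(object@structures))
    msgs <- c(msgs, "a case must contain at least one structure")
  if (!all(vapply(object@structures, is, logical(1), "StructureDVH")))
    msgs <- c(msgs, "structures must all be StructureDVH objects")
  else {
    nms <- trimWs(vapply(object@structures, slot, character(1), "name"))
    if (anyDuplicated(nms))
      msgs <- c(msgs, sprintf("duplicate structure name(s): %s",
                              paste(unique(nms[duplicated(nms)]), collapse = ", ")))
    grids <- lapply(object@structures, slot, "doseGrid")
    if (length(grids) > 1L &&
        !all(vapply(grids[-1L], identical, logical(1), grids[[1L]])))
      msgs <- c(msgs, "all structures in a case must share one dose grid")
  }
  if (length(msgs)) msgs else TRUE
})

#' DoseVolumePoint: parsed dose/volume-point expression
#'
#' The abstract syntax of one dose/volume-point expression, as produced by
#' \code{\link{parseExpression}}. Query metrics \code{D} and \code{V} carry an
#' output unit, an argument value and an argument unit; the named metrics
#' \code{Dmax}, \code{Dmin} and \code{Dmean} carry none. An optional arithmetic
#' suffix divides an absolute-dose result by the prescription dose
#' (\code{/Rx}), optionally scaled to percent (\code{x 100}).
#'
#' @slot metric One of \code{"D"}, \code{"V"}, \code{"Dmax"}, \code{"Dmin"},
#'   \code{"Dmean"}.
#' @slot outUnit For \code{D}: \code{"Gy"} or \code{"\%"}; for \code{V}:
#'   \code{"cc"} or \code{"\%"}; \code{NA} for named metrics.
#' @slot argValue Positive numeric argument; \code{NA} for named metrics.
#' @slot argUnit For \code{D}: \code{"cc"} or \code{"\%"}; for \code{V}:
#'   \code{"Gy"} or \code{"\%"}; \code{NA} for named metrics.
#' @slot divideByRx Logical; divide the absolute-dose result by the
#'   prescription dose.
#' @slot times100 Logical; multiply the \code{/Rx} ratio by 100 (only valid
#'   together with \code{divideByRx}).
#' @slot sourceText The original expression string (empty for points built
#'   programmatically).
#' @seealso \code{\link{parseExpression}}, \code{\link{formatExpression}}
#' @export
setClass("DoseVolumePoint",
  representation(metric = "character", outUnit = "character",
                 argValue = "numeric", argUnit = "character",
                 divideByRx = "logical", times100 = "logical",
                 sourceText = "character"),
  prototype(outUnit = NA_character_, argValue = NA_real_,
            argUnit = NA_character_, divideByRx = FALSE, times100 = FALSE,
            sourceText = ""))

setValidity("DoseVolumePoint", function(object) {
  msgs <- character(0)
  m <- object@metric
  if (length(m) != 1L || !m %in% c("D", "V", "Dmax", "Dmin", "Dmean"))
    return("metric must be one of D, V, Dmax, Dmin, Dmean")
  named <- m %in% c("Dmax", "Dmin", "Dmean")
  if (named) {
    if (!is.na(object@outUnit) || !is.na(object@argValue) || !is.na(object@argUnit))
      msgs <- c(msgs, sprintf("named metric %s takes no units or argument", m))
  } else {
    okOut <- if (m == "D") c("Gy", "%") else c("cc", "%")
    okArg <- if (m == "D") c("cc", "%") else c("Gy", "%")
    if (is.na(object@outUnit) || !object@outUnit %in% okOut)
      msgs <- c(msgs, sprintf("%s output unit must be one of: %s", m,
                              paste(okOut, collapse = ", ")))
    if (is.na(object@argUnit) || !object@argUnit %in% okArg)
      msgs <- c(msgs, sprintf("%s argument unit must be one of: %s", m,
                              paste(okArg, collapse = ", ")))
    if (is.na(object@argValue) || object@argValue <= 0)
      msgs <- c(msgs, "argument value must be a positive number")
  }
  if (object@times100 && !object@divideByRx)
    msgs <- c(msgs, "x 100 is only valid together with /Rx")
  if (object@divideByRx && !isAbsoluteDoseMetric(object))
    msgs <- c(msgs, "/Rx applies only to absolute-dose metrics (D(Gy)..., Dmax, Dmin, Dmean)")
  if (length(msgs)) msgs else TRUE
})

# TRUE when the metric's pre-suffix value is an absolute dose in Gy,
# i.e. the only results /Rx may normalize.
isAbsoluteDoseMetric <- function(p) {
  p@metric %in% c("Dmax", "Dmin", "Dmean") ||
    (p@metric == "D" && identical(p@outUnit, "Gy"))
}

#' Construct a DoseVolumePoint programmatically
#'
#' Most code obtains points by parsing expression text with
#' \code{\link{parseExpression}}; this constructor builds the same object from
#' its parts, validating unit pairings and the arithmetic-suffix rules.
#'
#' @param metric \code{"D"}, \code{"V"}, \code{"Dmax"}, \code{"Dmin"} or
#'   \code{"Dmean"}.
#' @param outUnit,argValue,argUnit Query parts for \code{D}/\code{V} metrics;
#'   leave as \code{NA} for named metrics.
#' @param divideByRx,times100 Arithmetic suffix flags.
#' @return A validated \linkS4class{DoseVolumePoint}.
#' @examples
#' formatExpression(doseVolumePoint("V", "%", 20, "Gy"))
#' @export
doseVolumePoint <- function(metric, outUnit = NA_character_,
                            argValue = NA_real_, argUnit = NA_character_,
                            divideByRx = FALSE, times100 = FALSE) {
  p <- new("DoseVolumePoint", metric = as.character(metric),
           outUnit = as.character(outUnit), argValue = as.numeric(argValue),
           argUnit = as.character(argUnit), divideByRx = isTRUE(divideByRx),
           times100 = isTRUE(times100), sourceText = "")
  p@sourceText <- formatExpression(p)
  p
}

#' ReferenceDose: resolved percent-dose reference
#'
#' The dose taken as 100\% for percent-dose conversions, together with the mode
#' it was resolved under: the prescription dose or the plan's global maximum
#' dose.
#'
#' @slot mode \code{"prescription"} or \code{"maximum"}.
#' @slot value Reference dose in Gy, > 0.
#' @param mode,value See slots.
#' @return \code{ReferenceDose()} returns a validated object.
#' @seealso \code{\link{resolveReferenceDose}}
#' @examples
#' ReferenceDose("prescription", 60)
#' @exportClass ReferenceDose
setClass("ReferenceDose", representation(mode = "character", value = "numeric"))

#' @rdname ReferenceDose-class
#' @export
ReferenceDose <- function(mode, value) {
  new("ReferenceDose", mode = as.character(mode), value = as.numeric(value))
}

setValidity("ReferenceDose", function(object) {
  msgs <- character(0)
  if (length(object@mode) != 1L || !object@mode %in% c("prescription", "maximum"))
    msgs <- c(msgs, "mode must be 'prescription' or 'maximum'")
  if (!isScalarNumber(object@value) || object@value <= 0)
    msgs <- c(msgs, "reference dose value must be a single number > 0")
  if (length(msgs)) msgs else TRUE
})

#' MetricValue: an evaluated dose/volume point
#'
#' Result of evaluating one \linkS4class{DoseVolumePoint} on one
#' \linkS4class{StructureDVH}: the numeric value, its unit, and quality flags
#' raised during evaluation.
#'
#' @slot value The numeric result.
#' @slot unit \code{"Gy"}, \code{"\%"}, \code{"cc"} or \code{"dimensionless"}
#'   (the latter for a bare \code{/Rx} ratio).
#' @slot flags Character vector drawn from \code{"out_of_range"} (a volume
#'   query exceeded the structure volume) and \code{"structure_truncated"}
#'   (the exported curve ends above zero volume and the query reached its tail).
#' @seealso \code{\link{evaluatePoint}}
#' @export
setClass("MetricValue",
  representation(value = "numeric", unit = "character", flags = "character"),
  prototype(flags = character(0)))

setValidity("MetricValue", function(object) {
  msgs <- character(0)
  if (length(object@value) != 1L) msgs <- c(msgs, "value must be a single number")
  if (length(object@unit) != 1L ||
      !object@unit %in% c("Gy", "%", "cc", "dimensionless"))
    msgs <- c(msgs, "unit must be Gy, %, cc or dimensionless")
  if (!all(object@flags %in% c("out_of_range", "structure_truncated")))
    msgs <- c(msgs, "unknown flag")
  if (length(msgs)) msgs else TRUE
})

metricValueNew <- function(value, unit, flags = character(0)) {
  new("MetricValue", value = value, unit = unit, flags = unique(flags))
}

#' ReviewRequest: ordered dosimetry-review request
#'
#' The set of dose/volume points to review, as an ordered list of rows, each
#' pairing one structure name with an ordered list of
#' \linkS4class{DoseVolumePoint}s. Round-trips through a plain-text file via
#' \code{\link{loadRequest}} / \code{\link{saveRequest}}.
#'
#' @slot rows List of \code{list(structure = <name>, points = <list of
#'   DoseVolumePoint>)}; at least one row, each with at least one point.
#' @param rows See slot.
#' @return \code{ReviewRequest()} returns a validated object.
#' @seealso \code{\link{reviewRequest}} for the friendlier constructor.
#' @exportClass ReviewRequest
setClass("ReviewRequest", representation(rows = "list"))

#' @rdname ReviewRequest-class
#' @export
ReviewRequest <- function(rows) new("ReviewRequest", rows = rows)

setValidity("ReviewRequest", function(object) {
  msgs <- character(0)
  if (!length(object@rows)) return("a request must have at least one row")
  for (i in seq_along(object@rows)) {
    row <- object@rows[[i]]
    if (!is.list(row) || !all(c("structure", "points") %in% names(row))) {
      msgs <- c(msgs, sprintf("row %d is not a (structure, points) pair", i))
      next
    }
    nm <- row$structure
    if (!is.character(nm) || length(nm) != 1L || !nzchar(trimWs(nm)))
      msgs <- c(msgs, sprintf("row %d: structure name must be non-empty", i))
    else if (grepl("[:,]", nm))
      msgs <- c(msgs, sprintf("row %d: structure name may not contain ':' or ','", i))
    if (!length(row$points) ||
        !all(vapply(row$points, is, logical(1), "DoseVolumePoint")))
      msgs <- c(msgs, sprintf("row %d: needs at least one DoseVolumePoint", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Build a ReviewRequest from structure names and expression strings
#'
#' @param ... Named arguments: each name is a structure, each value a character
#'   vector of expression strings (parsed with \code{\link{parseExpression}}).
#' @return A validated \linkS4class{ReviewRequest}.
#' @examples
#' reviewRequest(PTV = c("D(%)95(%)", "Dmax"), Lungs = "V(%)20(Gy)")
#' @export
reviewRequest <- function(...) {
  args <- list(...)
  if (!length(args) || is.null(names(args)) || any(!nzchar(names(args))))
    validationError("reviewRequest() needs named structure = expressions arguments")
  rows <- lapply(seq_along(args), function(i) {
    list(structure = names(args)[i],
         points = lapply(as.character(args[[i]]), parseExpression))
  })
  ReviewRequest(rows = rows)
}

#' ResultTable: evaluated cells of a batch run
#'
#' Long-format table with exactly one row per (case, request row, point)
#' triple. Cells that could not be evaluated are never dropped: they carry a
#' status of \code{"structure_missing"} or \code{"evaluation_error"} and a
#' reason, with \code{NA} in the value column.
#'
#' @slot cells \code{data.frame} with columns \code{caseID},
#'   \code{structure}, \code{expression}, \code{value}, \code{unit},
#'   \code{flags} (comma-joined), \code{status} (\code{"ok"},
#'   \code{"structure_missing"} or \code{"evaluation_error"}) and
#'   \code{reason}.
#' @seealso \code{\link{runBatch}}
#' @export
setClass("ResultTable", representation(cells = "data.frame"))

setValidity("ResultTable", function(object) {
  need <- c("caseID", "structure", "expression", "value", "unit",
            "flags", "status", "reason")
  df <- object@cells
  if (!all(need %in% names(df)))
    return(sprintf("cells must have columns: %s", paste(need, collapse = ", ")))
  if (!all(df$status %in% c("ok", "structure_missing", "evaluation_error")))
    return("invalid status value")
  bad <- df$status != "ok" & !nzchar(df$reason)
  if (any(bad)) return("absent cells must carry a reason")
  TRUE
})

#' SummaryReport: per-structure sheets plus overview with quantile statistics
#'
#' The report built from a \linkS4class{ResultTable}: one sheet per requested
#' structure (cases by that structure's expressions) plus one overview sheet
#' (cases by all structure/expression pairs). Each sheet carries the echoed
#' request block, the value block, and a statistics block holding, per column,
#' the number of contributing cases and the 1, 2, 5, 10, 15, 85, 90, 95, 98
#' and 99\% quantiles computed over the cells that hold values.
#'
#' @slot request The \linkS4class{ReviewRequest} the report answers.
#' @slot sheets Named list of per-structure sheets; each sheet is a list with
#'   \code{title}, \code{structure}, \code{columns} (data.frame of structure /
#'   expression per value column), \code{caseIDs}, \code{values} (numeric
#'   matrix, cases x columns), \code{notes} (character matrix of reason codes),
#'   \code{counts} and \code{stats} (quantile levels x columns).
#' @slot overview The overview sheet, same layout.
#' @seealso \code{\link{buildReport}}, \code{\link{writeReport}}
#' @export
setClass("SummaryReport",
  representation(request = "ReviewRequest", sheets = "list", overview = "list"))
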