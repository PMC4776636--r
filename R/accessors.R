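#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setMethod("structureName", "StructureDVH", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("doseGrid", "StructureDVH", function(x) x@doseGrid)
#' @rdname accessors
#' @export
setMethod("cumVolume", "StructureDVH", function(x) x@cumVolume)
#' @rdname accessors
#' @export
setMethod("totalVolume", "StructureDVH", function(x) x@cumVolume[1L])

#' @rdname accessors
#' @export
setMethod("caseID", "DVHCase", function(x) x@caseID)
#' @rdname accessors
#' @export
setMethod("rxDose", "DVHCase", function(x) x@rxDose)
#' @rdname accessors
#' @export
setMethod("globalMaxDose", "DVHCase", function(x) x@globalMaxDose)
#' @rdname accessors
#' @export
setMethod("structures", "DVHCase", function(x) x@structures)
#' @rdname accessors
#' @export
setMethod("structureNames", "DVHCase", function(x)
  trimWs(vapply(x@structures, slot, character(1), "name")))

#' @rdname accessors
#' @export
setMethod("metricValue", "MetricValue", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("metricUnit", "MetricValue", function(x) x@unit)
#' @rdname accessors
#' @export
setMethod("metricFlags", "MetricValue", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("requestRows", "ReviewRequest", function(x) x@rows)
#' @rdname accessors
#' @export
setMethod("cells", "ResultTable", function(x) x@cells)

#' @describeIn StructureDVH Coerce to a two-column data.frame (dose, volume).
#' @param x,row.names,optional,... Standard \code{as.data.frame} arguments.
#' @export
as.data.frame.StructureDVH <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(dose_gy = x@doseGrid, volume_cc = x@cumVolume,
             row.names = row.names)
}

#' @describeIn ResultTable Extract the long-format cell table.
#' @param x,row.names,optional,... Standard \code{as.data.frame} arguments.
#' @export
as.data.frame.ResultTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@cells
}

setMethod("show", "StructureDVH", function(object) {
  cat(sprintf("StructureDVH '%s': %d grid points, %.4g-%.4g Gy, total %.4g cc\n",
              object@name, length(object@doseGrid), object@doseGrid[1L],
              object@doseGrid[length(object@doseGrid)], totalVolume(object)))
})

setMethod("show", "DVHCase", function(object) {
  rx <- if (is.na(object@rxDose)) "none" else sprintf("%.4g Gy", object@rxDose)
  mx <- if (is.na(object@globalMaxDose)) "none"
        else sprintf("%.4g Gy", object@globalMaxDose)
  cat(sprintf("DVHCase '%s': %d structure(s), Rx %s, global max %s\n",
              object@caseID, length(object@structures), rx, mx))
  cat(sprintf("  %s\n", paste(structureNames(object), collapse = ", ")))
})

setMethod("show", "DoseVolumePoint", function(object) {
  cat(sprintf("DoseVolumePoint: %s\n", formatExpression(object)))
})

setMethod("show", "MetricValue", function(object) {
  fl <- if (length(object@flags)) sprintf(" [%s]", paste(object@flags, collapse = ", "))
        else ""
  cat(sprintf("MetricValue: %.6g %s%s\n", object@value, object@unit, fl))
})

setMethod("show", "ReferenceDose", function(object) {
  cat(sprintf("ReferenceDose: %.4g Gy (%s)\n", object@value, object@mode))
})

setMethod("show", "ReviewRequest", function(object) {
  cat(sprintf("ReviewRequest: %d structure row(s), %d point(s)\n",
              length(object@rows),
              sum(vapply(object@rows, function(r) length(r$points), integer(1)))))
  for (row in object@rows)
    cat(sprintf("  %s: %s\n", row$structure,
                paste(vapply(row$points, formatExpression, character(1)),
                      collapse = ", ")))
})

setMethod("show", "ResultTable", function(object) {
  df <- object@cells
  cat(sprintf("ResultTable: %d cell(s) (%d ok, %d structure_missing, %d evaluation_error)\n",
              nrow(df), sum(df$status == "ok"),
              sum(df$status == "structure_missing"),
              sum(df$status == "evaluation_error")))
})

setMethod("show", "SummaryReport", function(object) {
  cat(sprintf("SummaryReport: %d structure sheet(s) + overview (%d case(s), %d value column(s))\n",
              length(object@sheets), length(object@overview$caseIDs),
              nrow(object@overview$columns)))
})
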