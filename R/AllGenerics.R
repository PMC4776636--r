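#' @include utils.R
NULL

#' Accessor generics
#'
#' Accessors for the core classes: \code{structureName}, \code{doseGrid},
#' \code{cumVolume} and \code{totalVolume} for \linkS4class{StructureDVH};
#' \code{caseID}, \code{rxDose}, \code{globalMaxDose}, \code{structures} and
#' \code{structureNames} for \linkS4class{DVHCase}; \code{metricValue},
#' \code{metricUnit} and \code{metricFlags} for \linkS4class{MetricValue};
#' \code{requestRows} for \linkS4class{ReviewRequest} and \code{cells} for
#' \linkS4class{ResultTable}.
#'
#' @param x An object of the class the accessor belongs to.
#' @return The slot value (see each class page for slot descriptions).
#' @name accessors
#' @aliases structureName doseGrid cumVolume totalVolume caseID rxDose
#'   globalMaxDose structures structureNames metricValue metricUnit
#'   metricFlags requestRows cells
NULL

#' @rdname accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))
#' @rdname accessors
#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))
#' @rdname accessors
#' @export
setGeneric("cumVolume", function(x) standardGeneric("cumVolume"))
#' @rdname accessors
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))
#' @rdname accessors
#' @export
setGeneric("caseID", function(x) standardGeneric("caseID"))
#' @rdname accessors
#' @export
setGeneric("rxDose", function(x) standardGeneric("rxDose"))
#' @rdname accessors
#' @export
setGeneric("globalMaxDose", function(x) standardGeneric("globalMaxDose"))
#' @rdname accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))
#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname accessors
#' @export
setGeneric("metricValue", function(x) standardGeneric("metricValue"))
#' @rdname accessors
#' @export
setGeneric("metricUnit", function(x) standardGeneric("metricUnit"))
#' @rdname accessors
#' @export
setGeneric("metricFlags", function(x) standardGeneric("metricFlags"))
#' @rdname accessors
#' @export
setGeneric("requestRows", function(x) standardGeneric("requestRows"))
#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
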