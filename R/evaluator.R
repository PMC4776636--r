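#' @include AllClasses.R
NULL

# Evaluation conventions (piecewise-linear cumulative DVH):
#  - Both query directions interpolate linearly on the exported grid, which is
#    exact for the piecewise-linear curves the planning system exports.
#  - dose-at-volume uses the supremum convention on flat segments: the largest
#    dose whose covered volume is still >= the requested volume ("dose that
#    covers" semantics).
#  - A curve whose last volume is > 0 (truncated export) is treated as
#    dropping to 0 immediately after the last grid dose; queries that reach
#    that tail carry the "structure_truncated" flag.
#  - A volume query above the total volume returns 0 Gy with "out_of_range"
#    instead of erroring, so one bad request never aborts a batch.

flagsOf <- function(x) {
  f <- attr(x, "flags")
  if (is.null(f)) character(0) else f
}

withFlags <- function(value, flags) {
  if (length(flags)) attr(value, "flags") <- unique(flags)
  value
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative volume at dose \code{d}: below the
#' grid start the total volume is returned; beyond the grid end the last
#' tabulated volume (0 for a curve that reaches zero), with the
#' \code{structure_truncated} flag when that value is positive.
#'
#' @param s A \linkS4class{StructureDVH}.
#' @param d Dose(s) in Gy, all >= 0.
#' @return Volume(s) in cc; a \code{"flags"} attribute carries any quality
#'   flags raised.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' volumeAtDose(s, 60)   # 40 cc
#' @export
volumeAtDose <- function(s, d) {
  stopifnot(is(s, "StructureDVH"))
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    domainError("dose query must be numeric and >= 0")
  grid <- s@doseGrid
  vol <- s@cumVolume
  n <- length(grid)
  out <- stats::approx(grid, vol, xout = d, method = "linear", rule = 2)$y
  flags <- if (any(d > grid[n]) && vol[n] > 0) "structure_truncated" else character(0)
  withFlags(out, flags)
}

#' Dose covering a given volume
#'
#' The largest dose \code{d} whose interpolated covered volume is still at
#' least \code{v} (supremum convention on flat segments). \code{v = 0} returns
#' the last grid dose; \code{v} above the total volume returns 0 Gy with the
#' \code{out_of_range} flag; \code{v} at or below the last tabulated volume of
#' a truncated curve returns the last grid dose with
#' \code{structure_truncated}.
#'
#' @param s A \linkS4class{StructureDVH}.
#' @param v Volume(s) in cc, all >= 0.
#' @return Dose(s) in Gy, with a \code{"flags"} attribute as in
#'   \code{\link{volumeAtDose}}.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' doseAtVolume(s, 40)   # 60 Gy
#' @export
doseAtVolume <- function(s, v) {
  stopifnot(is(s, "StructureDVH"))
  if (!is.numeric(v) || anyNA(v) || any(v < 0))
    domainError("volume query must be numeric and >= 0")
  grid <- s@doseGrid
  vol <- s@cumVolume
  n <- length(grid)
  total <- vol[1L]
  flags <- character(0)
  out <- vapply(v, function(vi) {
    if (vi == 0) return(grid[n])
    if (vi > total) {
      flags <<- c(flags, "out_of_range")
      return(0)
    }
    if (vi <= vol[n]) {
      # truncated curve: the drop to zero is taken to sit just past the grid end
      if (vol[n] > 0) flags <<- c(flags, "structure_truncated")
      return(grid[n])
    }
    i <- max(which(vol >= vi))
    grid[i] + (vol[i] - vi) / (vol[i] - vol[i + 1L]) * (grid[i + 1L] - grid[i])
  }, numeric(1))
  withFlags(out, flags)
}

#' Mean dose of a structure
#'
#' Mean dose from the cumulative curve: the trapezoidal integral of the
#' cumulative volume over the dose grid divided by the total volume (exact
#' under the piecewise-linear assumption; equivalent to the mean of the
#' implied differential DVH). For a truncated curve the tail beyond the last
#' grid dose contributes nothing and \code{structure_truncated} is flagged.
#'
#' @param s A \linkS4class{StructureDVH} with total volume > 0.
#' @return Mean dose in Gy, with a \code{"flags"} attribute.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' meanDose(s)   # 50 Gy
#' @export
meanDose <- function(s) {
  stopifnot(is(s, "StructureDVH"))
  grid <- s@doseGrid
  vol <- s@cumVolume
  n <- length(grid)
  total <- vol[1L]
  if (total <= 0)
    degenerateStructureError(sprintf(
      "mean dose undefined for structure \"%s\" with zero total volume", s@name))
  integral <- sum(diff(grid) * (vol[-1L] + vol[-n]) / 2)
  flags <- if (vol[n] > 0) "structure_truncated" else character(0)
  withFlags(integral / total, flags)
}

#' RTOG near-maximum dose
#'
#' The RTOG maximum-dose convention: the dose covering the hottest 0.03 cc of
#' the structure, identical to evaluating \code{D(Gy)0.03(cc)}.
#'
#' @param s A \linkS4class{StructureDVH} with total volume >= 0.03 cc.
#' @return Dose in Gy, with a \code{"flags"} attribute.
#' @export
rtogMax <- function(s) {
  stopifnot(is(s, "StructureDVH"))
  if (totalVolume(s) < 0.03)
    degenerateStructureError(sprintf(
      "RTOG maximum (dose covering 0.03 cc) undefined: structure \"%s\" has only %.4g cc",
      s@name, totalVolume(s)))
  doseAtVolume(s, 0.03)
}

#' RTOG near-minimum dose
#'
#' The RTOG minimum-dose convention: the lowest dose to any 0.03 cc of the
#' structure, read off the cumulative curve at (total volume - 0.03 cc).
#'
#' @param s A \linkS4class{StructureDVH} with total volume >= 0.03 cc.
#' @return Dose in Gy, with a \code{"flags"} attribute.
#' @export
rtogMin <- function(s) {
  stopifnot(is(s, "StructureDVH"))
  if (totalVolume(s) < 0.03)
    degenerateStructureError(sprintf(
      "RTOG minimum (0.03 cc from the cold end) undefined: structure \"%s\" has only %.4g cc",
      s@name, totalVolume(s)))
  doseAtVolume(s, totalVolume(s) - 0.03)
}

#' Evaluate a dose/volume point on one structure
#'
#' Dispatches a parsed \linkS4class{DoseVolumePoint} to the query primitives
#' and applies the unit conversions: a percent argument of a D-metric is
#' \code{arg/100 x total volume} (cc); a percent argument of a V-metric is
#' \code{arg/100 x reference dose} (Gy); a percent D output divides the Gy
#' result by the reference dose (x 100); a percent V output divides the cc
#' result by the total volume (x 100). The \code{/Rx} suffix always divides by
#' the prescription dose -- also under reference mode \code{"maximum"}, where
#' the reference governs only percent units.
#'
#' @param point A \linkS4class{DoseVolumePoint}.
#' @param s A \linkS4class{StructureDVH}.
#' @param ref A \linkS4class{ReferenceDose}, required whenever the expression
#'   uses a percent dose.
#' @param rx Prescription dose in Gy for \code{/Rx}; defaults to
#'   \code{ref}'s value when the reference mode is \code{"prescription"}.
#' @return A \linkS4class{MetricValue}; flags raised by the inner queries
#'   propagate into it.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' evaluatePoint(parseExpression("D(%)40(%)"), s, ReferenceDose("prescription", 50))
#' @export
evaluatePoint <- function(point, s, ref = NULL, rx = NULL) {
  stopifnot(is(point, "DoseVolumePoint"), is(s, "StructureDVH"))
  validObject(point)
  if (!is.null(ref)) {
    stopifnot(is(ref, "ReferenceDose"))
    validObject(ref)
  }
  if (is.null(rx) && !is.null(ref) && ref@mode == "prescription")
    rx <- ref@value

  needsRef <- (point@metric == "D" && identical(point@outUnit, "%")) ||
              (point@metric == "V" && identical(point@argUnit, "%"))
  if (needsRef && is.null(ref))
    missingReferenceError(sprintf(
      "expression \"%s\" uses a percent dose but no reference dose is available",
      formatExpression(point)))
  if (point@divideByRx && is.null(rx))
    missingReferenceError(sprintf(
      "expression \"%s\" uses /Rx but no prescription dose is available",
      formatExpression(point)))

  total <- totalVolume(s)
  flags <- character(0)

  if (point@metric %in% c("Dmax", "Dmin", "Dmean")) {
    raw <- switch(point@metric, Dmax = rtogMax(s), Dmin = rtogMin(s),
                  Dmean = meanDose(s))
    flags <- c(flags, flagsOf(raw))
    value <- as.numeric(raw)
    unit <- "Gy"
  } else if (point@metric == "D") {
    argCc <- if (identical(point@argUnit, "%")) point@argValue / 100 * total
             else point@argValue
    raw <- doseAtVolume(s, argCc)
    flags <- c(flags, flagsOf(raw))
    value <- as.numeric(raw)
    unit <- "Gy"
    if (identical(point@outUnit, "%")) {
      value <- value / ref@value * 100
      unit <- "%"
    }
  } else { # V
    argGy <- if (identical(point@argUnit, "%")) point@argValue / 100 * ref@value
             else point@argValue
    raw <- volumeAtDose(s, argGy)
    flags <- c(flags, flagsOf(raw))
    value <- as.numeric(raw)
    unit <- "cc"
    if (identical(point@outUnit, "%")) {
      if (total <= 0)
        degenerateStructureError(sprintf(
          "percent volume undefined for structure \"%s\" with zero total volume",
          s@name))
      value <- value / total * 100
      unit <- "%"
    }
  }

  if (point@divideByRx) {
    value <- value / rx
    unit <- "dimensionless"
    if (point@times100) {
      value <- value * 100
      unit <- "%"
    }
  }
  metricValueNew(value, unit, flags)
}

#' Run settings for a batch evaluation
#'
#' @param refMode Reference-dose mode: \code{"prescription"} (percent doses
#'   are relative to the prescription dose) or \code{"maximum"} (relative to
#'   each case's global maximum dose from header cell D1).
#' @param globalRx Optional trial-wide prescription dose in Gy; a case-specific
#'   value in the DVH file overrides it.
#' @return A \code{list} with class \code{"dvhRunSettings"}.
#' @examples
#' runSettings("prescription", globalRx = 60)
#' @export
runSettings <- function(refMode = c("prescription", "maximum"), globalRx = NULL) {
  refMode <- match.arg(refMode)
  if (!is.null(globalRx)) {
    if (!isScalarNumber(globalRx) || globalRx <= 0)
      validationError("globalRx must be a single dose > 0 (Gy)")
    globalRx <- as.numeric(globalRx)
  }
  structure(list(refMode = refMode, globalRx = globalRx),
            class = "dvhRunSettings")
}

#' Resolve the reference dose for one case
#'
#' Under mode \code{"prescription"} the case-specific prescription dose (header
#' cell C1) wins over the globally configured one; under mode \code{"maximum"}
#' the case's global maximum dose (header cell D1) is required, since plans do
#' not share one maximum dose.
#'
#' @param case A \linkS4class{DVHCase}.
#' @param settings A \code{\link{runSettings}} object.
#' @return A \linkS4class{ReferenceDose}.
#' @examples
#' s <- StructureDVH("PTV", 0:100, 100 - 0:100)
#' cs <- DVHCase("PT001", list(s), rxDose = 60)
#' resolveReferenceDose(cs, runSettings("prescription", globalRx = 70))  # 60 Gy
#' @export
resolveReferenceDose <- function(case, settings) {
  stopifnot(is(case, "DVHCase"), inherits(settings, "dvhRunSettings"))
  if (settings$refMode == "prescription") {
    value <- if (!is.na(case@rxDose)) case@rxDose else settings$globalRx
    if (is.null(value))
      missingReferenceError(sprintf(
        "case \"%s\": no prescription dose (neither header cell C1 nor a global setting)",
        case@caseID))
    ReferenceDose(mode = "prescription", value = value)
  } else {
    if (is.na(case@globalMaxDose))
      missingReferenceError(sprintf(
        "case \"%s\": reference mode 'maximum' needs the global maximum dose in header cell D1",
        case@caseID))
    ReferenceDose(mode = "maximum", value = case@globalMaxDose)
  }
}
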