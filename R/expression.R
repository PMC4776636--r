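#' @include AllClasses.R
NULL

# Grammar of dose/volume-point expressions
#
#   expr   := base suffix?
#   base   := ('D' | 'V') '(' unit ')' number '(' unit ')'
#           | 'Dmax' | 'Dmin' | 'Dmean'
#   suffix := '/Rx' mult?
#   mult   := ('x' | 'X' | '*' | U+00D7) '100'
#
# Whitespace between tokens is ignored. Unit keywords (Gy, cc, %), metric
# names and 'Rx' are case-sensitive. Numbers are positive decimals with an
# optional fractional part; scientific notation is not part of the syntax.
# Unit pairings: D outputs Gy|% and takes a cc|% argument; V outputs cc|% and
# takes a Gy|% argument. '/Rx' is accepted only where the pre-suffix value is
# an absolute dose (D(Gy)..., Dmax, Dmin, Dmean); 'x 100' only after '/Rx'.

#' Parse a dose/volume-point expression
#'
#' Parses one expression in the standard dose/volume-point syntax, e.g.
#' \code{"D(Gy)40(cc)"} (the dose in Gy covering 40 cc), \code{"V(\%)20(Gy)"}
#' (the percent of the structure receiving at least 20 Gy), \code{"Dmax"} /
#' \code{"Dmin"} (RTOG near-maximum/near-minimum at 0.03 cc from the curve
#' ends), \code{"Dmean"}, and \code{"Dmean/Rx x 100"} (mean dose as a percent
#' of the prescription dose).
#'
#' Errors are signalled as classed conditions: \code{dvhSyntaxError} (with a
#' \code{position} field giving the 1-based character offset),
#' \code{dvhUnitError} for an illegal unit pairing or a misplaced \code{/Rx},
#' and \code{dvhValueError} for a non-positive argument.
#'
#' @param text A single expression string.
#' @return A \linkS4class{DoseVolumePoint}.
#' @examples
#' parseExpression("D(Gy)40(cc)")
#' parseExpression("Dmean/Rx x 100")
#' @seealso \code{\link{formatExpression}}, \code{\link{validateRequestSyntax}}
#' @export
parseExpression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    syntaxError("expression must be a single string", position = 1L)
  n <- nchar(text)
  pos <- 1L

  peekLen <- function(pat) {
    m <- regexpr(paste0("^(?:", pat, ")"), substring(text, pos), perl = TRUE)
    if (m == 1L) attr(m, "match.length") else 0L
  }
  take <- function(pat) {
    len <- peekLen(pat)
    if (len == 0L) return(NULL)
    out <- substring(text, pos, pos + len - 1L)
    pos <<- pos + len
    out
  }
  skipWs <- function() { take("[ \t]+"); invisible(NULL) }
  fail <- function(msg) {
    syntaxError(sprintf("%s at position %d in \"%s\"", msg, pos, text),
                position = pos)
  }
  expectTok <- function(pat, what) {
    tok <- take(pat)
    if (is.null(tok)) fail(sprintf("expected %s", what))
    tok
  }

  skipWs()
  if (pos > n) fail("empty expression")

  named <- take("Dmean|Dmax|Dmin")
  if (!is.null(named)) {
    point <- new("DoseVolumePoint", metric = named, sourceText = text)
  } else {
    metric <- take("[DV]")
    if (is.null(metric)) fail("expected metric D, V, Dmax, Dmin or Dmean")
    readUnit <- function(allowed, role) {
      skipWs()
      expectTok("\\(", "'('")
      skipWs()
      upos <- pos
      unit <- expectTok("Gy|cc|%", "unit Gy, cc or %")
      if (!unit %in% allowed)
        unitError(sprintf(
          "illegal %s unit '%s' for metric %s (allowed: %s) at position %d in \"%s\"",
          role, unit, metric, paste(allowed, collapse = ", "), upos, text),
          position = upos)
      skipWs()
      expectTok("\\)", "')'")
      unit
    }
    outUnit <- readUnit(if (metric == "D") c("Gy", "%") else c("cc", "%"),
                        "output")
    skipWs()
    npos <- pos
    numTok <- expectTok("[0-9]+(?:\\.[0-9]+)?", "a number")
    argValue <- as.numeric(numTok)
    if (argValue <= 0)
      valueError(sprintf("argument must be positive, got %s at position %d in \"%s\"",
                         numTok, npos, text), position = npos)
    argUnit <- readUnit(if (metric == "D") c("cc", "%") else c("Gy", "%"),
                        "argument")
    point <- new("DoseVolumePoint", metric = metric, outUnit = outUnit,
                 argValue = argValue, argUnit = argUnit, sourceText = text)
  }

  skipWs()
  if (!is.null(take("/"))) {
    skipWs()
    rpos <- pos
    expectTok("Rx", "'Rx'")
    if (!isAbsoluteDoseMetric(point))
      unitError(sprintf(
        "'/Rx' applies only to absolute-dose metrics (D(Gy)..., Dmax, Dmin, Dmean) at position %d in \"%s\"",
        rpos - 1L, text), position = rpos - 1L)
    point@divideByRx <- TRUE
    skipWs()
    if (!is.null(take("[xX*\u00d7]"))) {
      skipWs()
      expectTok("100(?![0-9.])", "'100'")
      point@times100 <- TRUE
    }
  }
  skipWs()
  if (pos <= n) fail("unexpected trailing text")

  validObject(point)
  point
}

#' Check a batch of expressions without raising
#'
#' Runs \code{\link{parseExpression}} over a vector of expression strings and
#' collects, rather than raises, every failure, so a whole review request can
#' be checked in one pass and all offending expressions reported back.
#'
#' @param expressions Character vector of expression strings.
#' @return A \code{data.frame} with columns \code{index} (position in the
#'   input) and \code{message}; zero rows when every expression parses.
#' @examples
#' validateRequestSyntax(c("Dmax", "D40Gy"))
#' @export
validateRequestSyntax <- function(expressions) {
  expressions <- as.character(expressions)
  idx <- integer(0)
  msg <- character(0)
  for (i in seq_along(expressions)) {
    err <- tryCatch({ parseExpression(expressions[i]); NULL },
                    dvhSyntaxError = function(e) conditionMessage(e))
    if (!is.null(err)) {
      idx <- c(idx, i)
      msg <- c(msg, err)
    }
  }
  data.frame(index = idx, message = msg, stringsAsFactors = FALSE)
}

#' Render a DoseVolumePoint as canonical expression text
#'
#' Produces the canonical spelling of a point: no internal whitespace except
#' around the multiplication sign, \code{\u00d7} (times sign) as that sign, and the
#' argument printed as a plain decimal. Parsing the result reproduces the
#' point, so \code{formatExpression} followed by \code{\link{parseExpression}}
#' canonicalizes any accepted spelling.
#'
#' @param point A \linkS4class{DoseVolumePoint}.
#' @return The canonical expression string.
#' @examples
#' formatExpression(parseExpression("  Dmean /Rx * 100 "))
#' @export
formatExpression <- function(point) {
  stopifnot(is(point, "DoseVolumePoint"))
  validObject(point)
  base <- if (point@metric %in% c("Dmax", "Dmin", "Dmean")) {
    point@metric
  } else {
    sprintf("%s(%s)%s(%s)", point@metric, point@outUnit,
            fmtNum(point@argValue), point@argUnit)
  }
  suffix <- if (point@times100) "/Rx \u00d7 100"
            else if (point@divideByRx) "/Rx"
            else ""
  paste0(base, suffix)
}
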