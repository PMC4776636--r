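# Shared condition constructors and small formatting helpers.

dvhStop <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "dvhError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

formatError     <- function(msg, ...) dvhStop(msg, "dvhFormatError", ...)
validationError <- function(msg, ...) dvhStop(msg, "dvhValidationError", ...)
syntaxError     <- function(msg, position = NA_integer_, ...)
  dvhStop(msg, "dvhSyntaxError", position = position, ...)
unitError       <- function(msg, position = NA_integer_, ...)
  dvhStop(msg, c("dvhUnitError", "dvhSyntaxError"), position = position, ...)
valueError      <- function(msg, position = NA_integer_, ...)
  dvhStop(msg, c("dvhValueError", "dvhSyntaxError"), position = position, ...)
domainError     <- function(msg, ...) dvhStop(msg, "dvhDomainError", ...)
missingReferenceError <- function(msg, ...) dvhStop(msg, "dvhMissingReferenceError", ...)
degenerateStructureError <- function(msg, ...) dvhStop(msg, "dvhDegenerateStructureError", ...)
ioError         <- function(msg, ...) dvhStop(msg, "dvhIOError", ...)

# Locale-independent plain-decimal rendering of a dose/volume number.
fmtNum <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE, digits = 15),
         character(1))
}

# RFC 4180 field quoting: quote only when the field needs it.
csvField <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csvLine <- function(fields) paste(csvField(fields), collapse = ",")

# Write lines as UTF-8 with "\n" endings regardless of platform/locale,
# so regenerated reports and request files are byte-stable.
writeLinesUtf8 <- function(lines, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) ioError(sprintf("cannot open '%s' for writing: %s",
                                                      path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

trimWs <- function(x) trimws(x, which = "both")

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
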