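#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all printed counts and percentages: 0.5 always
#' rounds up in magnitude (base R `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage under the mixed-precision table convention
#'
#' Percentages are rounded half-up to one decimal; the decimal is dropped when
#' it is zero ("85", "9.5"); values strictly between 0 and 1 print as "<1".
#'
#' @param p numeric percentage (0..100 scale)
#' @return character vector
#' @export
format_percent <- function(p) {
  p1 <- round_half_up(p, 1)
  out <- ifelse(p1 %% 1 == 0, sprintf("%d", as.integer(round(p1))),
                sprintf("%.1f", p1))
  out[p > 0 & p1 < 1] <- "<1"
  out
}

# XML-escape a character vector for attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# Deterministic numeric formatting for serialized coordinates.
num_fmt <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- NA_character_
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
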