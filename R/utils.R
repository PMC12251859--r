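#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the
#' "round half up" convention of most published QTL tables), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector of the same length.
#' @examples
#' roundHalfUp(c(0.125, 26.265, -0.125), 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## internal: treat "" and NA as absent in parsed tables
.isAbsent <- function(x) is.na(x) | (is.character(x) & !is.na(x) & x == "")

## internal: numeric parse that reports the offending row/column
.parseNum <- function(x, col, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    stop("malformed value in column '", col, "' at row ", rows[bad[1]],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out[.isAbsent(x)] <- NA_real_
  out
}

.POP_TYPES <- c("F2", "BC", "F2:3", "F3", "F4", "RIL", "DH")
.TRAITS <- c("PH", "EH")
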