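# internal helpers shared across modules

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-up rounding (what clinical tables print), as opposed to round()'s
# round-half-even
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# integer-valued ordinal score validation; returns an integer vector or
# aborts naming the offending field and position
check_item <- function(x, name, lo, hi, allow_na = FALSE) {
  if (length(x) == 0L) {
    stop(sprintf("'%s' must be non-empty", name), call. = FALSE)
  }
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric (integer-valued)", name), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  }
  ok <- is.na(x) | x == round(x)
  if (!all(ok)) {
    stop(sprintf("'%s' must be integer-valued (got %s)", name,
                 format(x[!ok][1])), call. = FALSE)
  }
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    stop(sprintf("'%s' out of range [%d, %d] at position %d (value %s)",
                 name, as.integer(lo), as.integer(hi), bad[1],
                 format(x[bad[1]])), call. = FALSE)
  }
  as.integer(x)
}

check_equal_lengths <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) > 1L) {
    stop(sprintf("arguments must have equal lengths (got %s)",
                 paste(lens, collapse = ", ")), call. = FALSE)
  }
  invisible(lens[1])
}
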