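#' Exact rational fit scores
#'
#' Consistency and coverage are ratios of case counts. To keep threshold tests
#' at exactly 1.0 (or any rational cut such as 13/14) free of floating-point
#' error, all fit scores are carried as exact integer fractions and only
#' converted to decimals for display.
#'
#' @param num integer numerator (a case count).
#' @param den integer denominator (a case count); `den = 0` yields the
#'   designated *undefined* score, which is neither 0 nor 1 and is excluded
#'   by model searches.
#' @return An object of class `"cna_fraction"`.
#' @examples
#' f <- cna_fraction(13, 14)
#' as.numeric(f)
#' format(f)
#' @export
cna_fraction <- function(num, den) {
  num <- as.integer(num)
  den <- as.integer(den)
  stopifnot(length(num) == 1L, length(den) == 1L, !is.na(num), !is.na(den),
            num >= 0L, den >= 0L)
  if (den > 0L) {
    g <- .gcd(num, den)
    if (g > 1L) {
      num <- num %/% g
      den <- den %/% g
    }
  }
  structure(list(num = num, den = den), class = "cna_fraction")
}

.gcd <- function(a, b) {
  while (b > 0L) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  max(a, 1L)
}

#' @export
as.double.cna_fraction <- function(x, ...) {
  if (is_undefined(x)) NA_real_ else x$num / x$den
}

#' Test whether a fit score is the designated undefined value
#'
#' A consistency with no instantiating case, or a coverage with no outcome
#' case, has a zero denominator and is reported as undefined rather than being
#' coerced to 0 or 1 (either coercion would create spurious models).
#'
#' @param x a [cna_fraction()].
#' @return `TRUE` if the score is undefined.
#' @export
is_undefined <- function(x) {
  stopifnot(inherits(x, "cna_fraction"))
  x$den == 0L
}

#' @export
format.cna_fraction <- function(x, ...) {
  if (is_undefined(x)) return("undefined")
  sprintf("%d/%d (%.2f)", x$num, x$den, round_half_up(x))
}

#' @export
print.cna_fraction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Round a fit score half-up to a fixed number of decimals
#'
#' Display rounding for fit scores. Half-up (0.875 -> 0.88, 13/14 -> 0.93)
#' rather than R's banker's rounding, computed in integer arithmetic so the
#' result is exact.
#'
#' @param x a [cna_fraction()] or a plain number.
#' @param digits decimal places (default 2).
#' @return a numeric scalar (`NA` for undefined scores).
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  if (inherits(x, "cna_fraction")) {
    if (is_undefined(x)) return(NA_real_)
    # floor((2*p*num + den) / (2*den)) / p, all in exact integer arithmetic
    return(((2 * p * x$num + x$den) %/% (2 * x$den)) / p)
  }
  floor(x * p + 0.5) / p
}

# Parse a threshold given as a number or a string like "1", "0.95" or "13/14"
# into an exact integer pair c(num, den).
parse_rational <- function(x) {
  if (inherits(x, "cna_fraction")) return(c(x$num, x$den))
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("/", x, fixed = TRUE)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed rational: ", x, call. = FALSE)
      num <- suppressWarnings(as.numeric(parts[1]))
      den <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(num) || is.na(den) || den <= 0) {
        stop("malformed rational: ", x, call. = FALSE)
      }
      g <- .gcd(as.integer(num), as.integer(den))
      return(c(num, den) / g)
    }
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) stop("malformed rational", call. = FALSE)
  }
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x >= 0)
  # decimal inputs have at most a few digits; scale by 10^6 and reduce
  den <- 1e6
  num <- round(x * den)
  g <- .gcd(as.integer(num), as.integer(den))
  c(num, den) / g
}

# Exact comparison fraction >= threshold, threshold as c(num, den).
frac_ge <- function(x, thr) {
  if (is_undefined(x)) return(NA)
  x$num * thr[2] >= thr[1] * x$den
}
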