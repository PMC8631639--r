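#' Create a digit-extraction specification
#'
#' The default reads the first and second digits after the decimal point --
#' the first unbounded digits in a normalized copy-number table, where the
#' leading (pre-decimal) digit is range-bound and carries no Benford-like
#' signal.
#'
#' @param positions integer decimal positions after the decimal point.
#' @param precision decimal places of the fixed-point rendering digits are
#'   read from.
#' @return a [DigitSpec-class].
#' @examples
#' digitSpec()          # positions 1 and 2 -> 20 features
#' digitSpec(3:4)       # for tables concentrated below 0.01
#' @export
digitSpec <- function(positions = c(1L, 2L), precision = 10L) {
  spec <- new("DigitSpec", positions = as.integer(positions),
              precision = as.integer(precision))
  msg <- validObject(spec, test = TRUE)
  if (!isTRUE(msg)) stop("invalid DigitSpec -- ", msg, call. = FALSE)
  spec
}

# Canonical position-major feature names: pos1_digit0 ... pos2_digit9.
digitFeatureNames <- function(spec) {
  as.vector(vapply(spec@positions,
                   function(p) paste0("pos", p, "_digit", 0:9),
                   character(10)))
}

# Digit at decimal position `pos` of |x|, read from the fixed-point rendering
# with `precision` places. Vectorized; NA in -> NA out. The string route
# guarantees 0.1 reads as digit 1, not as its binary neighbour 0.0999... .
digitsAtPosition <- function(x, pos, precision) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (any(is.infinite(x) | is.nan(x)))
    stop("cannot extract digits from non-finite values", call. = FALSE)
  if (!any(ok)) return(out)
  s <- sprintf("%.*f", precision, abs(x[ok]))
  # decimal point sits `precision + 1` characters before the end
  at <- nchar(s) - precision + pos
  out[ok] <- as.integer(substr(s, at, at))
  out
}

#' Extract decimal digits from a single value
#'
#' Renders `abs(value)` as a fixed-point decimal string with
#' `spec@precision` places (round-half-even) and reads off the character at
#' each requested position after the decimal point. The sign is ignored;
#' integer-valued inputs yield digit 0 at every position.
#'
#' @param value a finite numeric scalar.
#' @param spec a [DigitSpec-class].
#' @return named integer vector, one digit per requested position.
#' @examples
#' extractDigits(0.123)   # c(pos1 = 1, pos2 = 2)
#' extractDigits(-0.507)  # c(pos1 = 5, pos2 = 0)
#' extractDigits(2.0)     # c(pos1 = 0, pos2 = 0)
#' @export
extractDigits <- function(value, spec = digitSpec()) {
  if (length(value) != 1L || !is.numeric(value) || !is.finite(value))
    stop("'value' must be a single finite number", call. = FALSE)
  d <- vapply(spec@positions,
              function(p) digitsAtPosition(value, p, spec@precision),
              integer(1))
  names(d) <- paste0("pos", spec@positions)
  d
}

#' Benford-like digit-frequency features per sample
#'
#' Converts each sample's gene values into the proportional frequency of the
#' digits 0-9 at each requested decimal position: the count of occurrences of
#' a digit at that position across the sample's non-missing values, divided
#' by the number of non-missing values. Under the default spec every sample
#' is summarized by exactly 20 features regardless of how many genes it
#' carries, which is what lets one model score tables of different widths.
#'
#' @param table a [CNACohort-class] (labels are carried over).
#' @param spec a [DigitSpec-class].
#' @return a [DigitFrequencySet-class], `10 * length(positions)` features by
#'   `nSamples`.
#' @examples
#' co <- cnaCohort(matrix(c(0.11, 0.12, 0.25, 0.19), 1, 4))
#' featureMatrix(digitFrequencies(co))
#' @export
digitFrequencies <- function(table, spec = digitSpec()) {
  stopIfNotCohort(table)
  X <- cnaMatrix(table)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty table", call. = FALSE)
  usable <- rowSums(!is.na(X))
  if (any(usable == 0L))
    stop("sample(s) with no usable values: ",
         paste(rownames(X)[usable == 0L], collapse = ", "), call. = FALSE)
  freq <- matrix(0, nrow(X), 10L * length(spec@positions),
                 dimnames = list(rownames(X), digitFeatureNames(spec)))
  for (k in seq_along(spec@positions)) {
    d <- digitsAtPosition(as.vector(X), spec@positions[k], spec@precision)
    d <- matrix(d, nrow(X), ncol(X))
    counts <- t(apply(d, 1L, function(r) tabulate(r[!is.na(r)] + 1L, 10L)))
    freq[, (k - 1L) * 10L + 1:10] <- counts / usable
  }
  se <- SummarizedExperiment(
    assays = list(freq = t(freq)),
    colData = DataFrame(label = as.character(sampleLabels(table)),
                        row.names = rownames(X)))
  metadata(se)$digitSpec <- spec
  new("DigitFrequencySet", se)
}

#' Benford's first-digit law
#'
#' Expected frequency of leading digit `d` under Benford's law,
#' `log10(1 + 1/d)`: digit 1 occurs about 30% of the time, decaying to under
#' 5% for digit 9.
#'
#' @param d integer digit(s) in 1..9.
#' @return expected frequency, same length as `d`.
#' @examples
#' benfordExpected(1)            # 0.30103
#' sum(benfordExpected(1:9))     # 1
#' @export
benfordExpected <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d != as.integer(d)) ||
      any(d < 1) || any(d > 9))
    stop("'d' must be integer digit(s) in 1..9", call. = FALSE)
  log10(1 + 1 / as.numeric(d))
}

#' Percent increase between two values
#'
#' The relative-change arithmetic behind Benford's law: stepping from 1,000
#' to 2,000 is a 100% increase, while 8,000 to 9,000 is only 12.5%, which is
#' why low leading digits linger and dominate.
#'
#' @param from,to numeric scalars, `from != 0`.
#' @return percent increase, `100 * (to - from) / from`.
#' @examples
#' percentIncrease(1000, 2000)  # 100
#' percentIncrease(8000, 9000)  # 12.5
#' @export
percentIncrease <- function(from, to) {
  if (any(from == 0)) stop("'from' must be nonzero", call. = FALSE)
  100 * (to - from) / from
}

#' Divergence between an observed and an expected digit distribution
#'
#' @param observed,expected frequency vectors of equal length, each summing
#'   to 1 (within 1e-6); `expected` strictly positive.
#' @return list with `chi_square` (sample-size-free Pearson-style statistic,
#'   `sum((o - e)^2 / e)`) and `mad` (mean absolute deviation).
#' @examples
#' digitDivergence(rep(1/9, 9), benfordExpected(1:9))
#' @export
digitDivergence <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("length mismatch between observed and expected", call. = FALSE)
  if (abs(sum(observed) - 1) > 1e-6 || abs(sum(expected) - 1) > 1e-6)
    stop("frequency vectors must each sum to 1", call. = FALSE)
  if (any(expected <= 0)) stop("'expected' must be strictly positive",
                               call. = FALSE)
  list(chi_square = sum((observed - expected)^2 / expected),
       mad = mean(abs(observed - expected)))
}
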