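# Converting synonymous divergence to time and back: gene-pair/WGD dating and
# LTR insertion-time estimation via T = K / 2r.

#' Convert a divergence K to a time in Ma
#'
#' `T = K / (2 r)`: the divergence accumulates along both lineages, so half of
#' it is assigned to each. Linear in `K` at fixed rate.
#'
#' @param k substitutions per site (>= 0); vectorized.
#' @param cal a [RateCalibration-class].
#' @return Time(s) in Ma.
#' @examples
#' divergenceTime(0.26, rateCalibration(1.3e-8))  # 10 Ma
#' @export
divergenceTime <- function(k, cal) {
  stopifnot(is(cal, "RateCalibration"))
  if (any(k < 0, na.rm = TRUE)) stop("k must be >= 0")
  k / (2 * cal@rate) / 1e6
}

#' Calibrate a substitution rate from a dated divergence
#'
#' Inverse of [divergenceTime()]: given a divergence peak `kPeak` whose age is
#' known (e.g. a Ks peak matched to a fossil-dated split), returns the rate
#' K / (2 T) such that dating the same peak recovers the known time.
#'
#' @param kPeak divergence (> 0).
#' @param knownTimeMa age in Ma (> 0).
#' @param source free-text provenance stored in the calibration.
#' @return A [RateCalibration-class].
#' @examples
#' calibrateRate(0.2, 10)  # r = 1e-8
#' @export
calibrateRate <- function(kPeak, knownTimeMa, source = "calibrated") {
  if (!isTRUE(knownTimeMa > 0)) stop("knownTimeMa must be > 0")
  if (!isTRUE(kPeak > 0)) stop("kPeak must be > 0 (rate would not be positive)")
  rateCalibration(kPeak / (2 * knownTimeMa * 1e6), source)
}

#' Estimate the insertion time of an LTR retrotransposon
#'
#' The 5' and 3' LTRs of an element are identical at insertion; their
#' Jukes-Cantor corrected distance `K` over unambiguous aligned columns dates
#' the insertion as `T = K / (2 r)`.
#'
#' @param ltrPair an aligned pair: a `DNAStringSet` of length 2 or a character
#'   vector of two equal-length sequences.
#' @param cal a [RateCalibration-class].
#' @return Insertion time in Ma, rounded to 3 decimals; `NA` when the pair is
#'   saturated (p >= 3/4).
#' @export
ltrInsertionTime <- function(ltrPair, cal) {
  stopifnot(is(cal, "RateCalibration"))
  s <- toupper(as.character(ltrPair))
  if (length(s) != 2L) stop("ltrPair must contain exactly two sequences")
  if (nchar(s[1]) != nchar(s[2])) stop("LTR sequences must be aligned (equal length)")
  a <- strsplit(s[1], "", fixed = TRUE)[[1]]
  b <- strsplit(s[2], "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  if (!any(ok)) stop("no comparable (unambiguous) aligned columns")
  p <- mean(a[ok] != b[ok])
  k <- .jcCorrect(p)
  if (is.na(k)) return(NA_real_)  # saturated
  round(divergenceTime(k, cal), 3L)
}
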