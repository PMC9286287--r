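# Second, spectrum-based detector and p-value combination.

#' Lomb-Scargle rhythm test on the detection period grid
#'
#' Computes the Scargle-normalised periodogram (tau-shifted, mean-centred
#' data, power normalised by the maximum-likelihood sample variance) at each
#' candidate period and converts the best power to a p-value with the exact
#' beta-distribution tail `(1 - 2z/n)^((n-3)/2)`, which holds for Gaussian
#' noise when the trial frequency is orthogonal to the mean (exact at Fourier
#' frequencies, a close approximation elsewhere). The minimum single-period p
#' is Sidak-corrected for the number of periods tested; because neighbouring
#' periods on a short series are strongly correlated this correction is
#' conservative.
#'
#' @param values,times_h One (non-concatenated) cycle of data; length >= 4.
#' @param grid A [period_grid()]; defaults to 20-28 h on the sampling
#'   interval.
#' @param cycle_h Unused placeholder for interface symmetry.
#' @return A single p-value in (0, 1]; constant series return 1.
#' @export
lomb_scargle_test <- function(values, times_h, grid = NULL, cycle_h = 24) {
  n <- length(values)
  if (n < 4) stop("series length must be >= 4")
  if (length(times_h) != n) stop("values/times length mismatch")
  if (is.null(grid)) grid <- period_grid(min(diff(times_h)))
  x <- values - mean(values)
  ssx <- sum(x^2)
  if (ssx == 0) return(1)
  v_ml <- ssx / n
  p_single <- vapply(grid$periods_h, function(per) {
    w <- 2 * pi / per
    tau <- atan2(sum(sin(2 * w * times_h)), sum(cos(2 * w * times_h))) / (2 * w)
    ct <- cos(w * (times_h - tau))
    st <- sin(w * (times_h - tau))
    P <- 0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    z <- P / v_ml
    u <- 1 - 2 * z / n
    if (u <= 0) return(1e-300)
    max(u^((n - 3) / 2), 1e-300)
  }, numeric(1))
  m <- length(p_single)
  p <- 1 - (1 - min(p_single))^m
  min(max(p, 1e-300), 1)
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom. A single p-value is returned
#' unchanged (chi-square-2 identity).
#'
#' @param p_values p-values in (0, 1].
#' @return Combined meta p-value.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("empty p-value set")
  stop_if_not_prob(p_values)
  x2 <- -2 * sum(log(p_values))
  pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}
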