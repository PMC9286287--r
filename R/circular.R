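# Circular summaries of peak phases, in ZT hours (0 = lights on), plus the
# rhythmic-gene enrichment test.

#' Circular mean vector of a phase sample
#'
#' Phases (hours) are mapped to angles, averaged as unit vectors (optionally
#' weighted); the resultant length R measures concentration (R = 1 iff all
#' phases coincide) and the resultant direction is the population peak time.
#' The mean direction is undefined when R = 0 (e.g. antipodal pairs) and is
#' returned as NA.
#'
#' @param phases_h Phases in hours (reduced modulo `cycle_h`); non-empty.
#' @param weights Optional non-negative weights.
#' @param cycle_h Cycle length (default 24).
#' @return List with `mean_phase_h` (in [0, 24) or NA) and `R` in [0, 1].
#' @export
mean_vector <- function(phases_h, weights = NULL, cycle_h = 24) {
  if (!length(phases_h)) stop("empty phase sample")
  if (!is.null(weights) && (length(weights) != length(phases_h) ||
                            any(weights < 0))) {
    stop("weights must be non-negative and match phases in length")
  }
  rv <- circ_resultant(phases_h, weights, cycle_h)
  mean_h <- if (rv$R < 1e-12) NA_real_ else
    rad_to_hours(atan2(rv$S, rv$C), cycle_h)
  list(mean_phase_h = mean_h, R = rv$R)
}

#' Rayleigh test of circular uniformity
#'
#' Z = n * R^2 with the standard fourth-order series approximation to the
#' tail, clipped to (0, 1].
#'
#' @inheritParams mean_vector
#' @return p-value.
#' @export
rayleigh_test <- function(phases_h, cycle_h = 24) {
  n <- length(phases_h)
  if (n < 2) stop("Rayleigh test needs n >= 2")
  R <- circ_resultant(phases_h, NULL, cycle_h)$R
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Large-sample 95% confidence arc for the circular mean direction
#'
#' Half-width `asin(z_0.975 * sigma_hat)` from the circular dispersion
#' `delta_hat = (1 - rho2_hat) / (2 * Rbar^2)` with
#' `sigma_hat = sqrt(delta_hat / n)` (Fisher's large-sample method). When the
#' concentration is too low for the approximation (`z * sigma_hat >= 1`) the
#' arc is flagged unbounded and NA limits are returned.
#'
#' @inheritParams mean_vector
#' @return List: `lower_h`, `upper_h` (hours, NA when unbounded),
#'   `half_width_h`, `unbounded`.
#' @export
mean_direction_ci95 <- function(phases_h, cycle_h = 24) {
  n <- length(phases_h)
  if (n < 3) stop("confidence arc needs n >= 3")
  mv <- mean_vector(phases_h, cycle_h = cycle_h)
  if (is.na(mv$mean_phase_h) || mv$R < 1e-12) {
    stop("mean direction undefined (R = 0)")
  }
  theta <- hours_to_rad(phases_h, cycle_h)
  mu <- hours_to_rad(mv$mean_phase_h, cycle_h)
  rho2 <- mean(cos(2 * (theta - mu)))
  delta <- (1 - rho2) / (2 * mv$R^2)
  sigma <- sqrt(max(delta, 0) / n)
  z <- qnorm(0.975)
  if (z * sigma >= 1) {
    return(list(lower_h = NA_real_, upper_h = NA_real_,
                half_width_h = NA_real_, unbounded = TRUE))
  }
  hw <- asin(z * sigma) * cycle_h / (2 * pi)
  list(lower_h = (mv$mean_phase_h - hw) %% cycle_h,
       upper_h = (mv$mean_phase_h + hw) %% cycle_h,
       half_width_h = hw, unbounded = FALSE)
}

#' Binned phase histogram across the day
#'
#' Half-open bins `[0, bin_h), [bin_h, 2*bin_h), ...`; counts conserve n.
#'
#' @inheritParams mean_vector
#' @param bin_h Bin width in hours; must divide the cycle evenly.
#' @return Named integer vector of counts, one per bin.
#' @export
phase_histogram <- function(phases_h, bin_h = 3, cycle_h = 24) {
  if (bin_h <= 0 || abs(cycle_h / bin_h - round(cycle_h / bin_h)) > 1e-9) {
    stop("bin_h must divide the cycle evenly")
  }
  ph <- phases_h %% cycle_h
  nb <- as.integer(round(cycle_h / bin_h))
  idx <- pmin(floor(ph / bin_h), nb - 1) + 1
  counts <- tabulate(idx, nbins = nb)
  names(counts) <- sprintf("[%g,%g)", (0:(nb - 1)) * bin_h, (1:nb) * bin_h)
  counts
}

#' Enrichment of rhythmic genes against a background expectation
#'
#' Fold enrichment `(k/n) / rate` and an exact two-sided binomial p-value
#' against the background rate, using the minimum-likelihood rule (the sum of
#' all outcome probabilities no larger than the observed one, the common
#' exact-test convention). When an explicit background gene set is supplied
#' as `background = c(K, N)` a 2x2 Fisher exact test is used instead.
#'
#' @param k_hits Number of rhythmic genes among the set of interest.
#' @param n_total Size of the set of interest.
#' @param background_rate Expected rhythmic fraction (default 0.16).
#' @param background Optional `c(K, N)`: K rhythmic of N background genes.
#' @return List with `fold` and `p`.
#' @export
enrichment_test <- function(k_hits, n_total, background_rate = 0.16,
                            background = NULL) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (k_hits < 0 || k_hits > n_total) stop("k_hits must be in [0, n_total]")
  if (background_rate <= 0 || background_rate >= 1) {
    stop("background_rate must be in (0, 1)")
  }
  fold <- (k_hits / n_total) / background_rate
  if (!is.null(background)) {
    K <- background[1]; N <- background[2]
    tab <- matrix(c(k_hits, n_total - k_hits, K - k_hits,
                    N - K - (n_total - k_hits)), nrow = 2)
    return(list(fold = fold, p = fisher.test(tab)$p.value))
  }
  d <- dbinom(0:n_total, n_total, background_rate)
  d_obs <- d[k_hits + 1]
  p <- sum(d[d <= d_obs * (1 + 1e-7)])
  list(fold = fold, p = min(p, 1))
}

#' Per-category circular phase summaries
#'
#' For each differential-rhythmicity category, summarises the peak phases of
#' the chosen group: n, circular mean, resultant length R, Rayleigh p, 95%
#' confidence arc and a binned histogram.
#'
#' @param classified The `classified` data.frame from [classify_all()].
#' @param phase_column Which phase column to summarise (`"phase_g1_h"` or
#'   `"phase_g2_h"`).
#' @param bin_h Histogram bin width.
#' @return data.frame, one row per category present.
#' @export
summarize_phases <- function(classified, phase_column = "phase_g1_h",
                             bin_h = 3) {
  cats <- unique(classified$category)
  rows <- lapply(cats, function(cc) {
    ph <- classified[[phase_column]][classified$category == cc]
    ph <- ph[!is.na(ph)]
    if (length(ph) < 3) {
      return(data.frame(category = cc, n = length(ph),
                        mean_phase_h = NA_real_, R = NA_real_,
                        rayleigh_p = NA_real_, ci_lower_h = NA_real_,
                        ci_upper_h = NA_real_, stringsAsFactors = FALSE))
    }
    mv <- mean_vector(ph)
    ci <- if (mv$R > 1e-12) mean_direction_ci95(ph) else
      list(lower_h = NA_real_, upper_h = NA_real_)
    data.frame(category = cc, n = length(ph),
               mean_phase_h = mv$mean_phase_h, R = mv$R,
               rayleigh_p = rayleigh_test(ph),
               ci_lower_h = ci$lower_h, ci_upper_h = ci$upper_h,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
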