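# Harmonic (cosinor) regression and between-group rhythm-difference tests.
# The published differential-rhythmicity suite this emulates is not
# reproduced bit-for-bit: the parametric F-test and the robust Wald test
# below are this package's own stand-ins, combined by Fisher's method into a
# meta p-value (documented as an approximation).

harmonic_design <- function(times_h, period_h) {
  w <- 2 * pi / period_h
  cbind(intercept = 1, a_cos = cos(w * times_h), b_sin = sin(w * times_h))
}

#' Least-squares cosinor fit
#'
#' Ordinary least squares of `value ~ 1 + cos(2*pi*t/period) +
#' sin(2*pi*t/period)`. With `y = m + A*cos(2*pi*(t - phi)/period)` the
#' coefficients are `a_cos = A*cos(2*pi*phi/period)` and
#' `b_sin = A*sin(2*pi*phi/period)`, so `amplitude = sqrt(a^2 + b^2)` and
#' `phase_h = period/(2*pi) * atan2(b_sin, a_cos)` (the peak time).
#'
#' @param values,times_h Series of at least 4 points spanning at least half
#'   a period.
#' @param period_h Fitted period (default 24).
#' @return List: mesor, a_cos, b_sin, amplitude, phase_h (in [0, 24)), rss,
#'   df_resid, fitted.
#' @export
harmonic_fit <- function(values, times_h, period_h = 24) {
  n <- length(values)
  if (n < 4) stop("need >= 4 points")
  if (length(times_h) != n) stop("values/times length mismatch")
  if (diff(range(times_h %% period_h)) < period_h / 2 - 1e-9 &&
      diff(range(times_h)) < period_h / 2 - 1e-9) {
    stop("times must span at least half a period")
  }
  X <- harmonic_design(times_h, period_h)
  fit <- lm.fit(X, values)
  if (fit$rank < 3) stop("rank-deficient harmonic design")
  cf <- fit$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (period_h / (2 * pi) * atan2(cf[3], cf[2])) %% 24
  list(mesor = unname(cf[1]), a_cos = unname(cf[2]), b_sin = unname(cf[3]),
       amplitude = unname(amp), phase_h = unname(phase),
       rss = sum(fit$residuals^2), df_resid = n - 3L,
       fitted = unname(fit$fitted.values))
}

#' Parametric test for a rhythm difference between two groups
#'
#' Nested-model F-test of H0: equal harmonic coefficients (a_cos, b_sin) in
#' the two groups, with group-specific mesors left free in both models (level
#' differences are deliberately not part of the null; set
#' `include_mesor = TRUE` to add the mesor to H0) and a shared error
#' variance. Identical inputs give F = 0, p = 1.
#'
#' @param values_a,times_a,values_b,times_b The two series.
#' @param period_h Fixed comparison period (default 24).
#' @param include_mesor Add mesor equality to the null hypothesis.
#' @return p-value of the F-test.
#' @export
compare_rhythms <- function(values_a, times_a, values_b, times_b = times_a,
                            period_h = 24, include_mesor = FALSE) {
  fa <- harmonic_fit(values_a, times_a, period_h)
  fb <- harmonic_fit(values_b, times_b, period_h)
  rss_full <- fa$rss + fb$rss
  n <- length(values_a) + length(values_b)
  df_full <- n - 6L
  if (df_full < 1) stop("too few points for the group comparison")
  Xa <- harmonic_design(times_a, period_h)
  Xb <- harmonic_design(times_b, period_h)
  y <- c(values_a, values_b)
  ga <- c(rep(1, length(values_a)), rep(0, length(values_b)))
  if (include_mesor) {
    X0 <- rbind(Xa, Xb)
    q <- 3L
  } else {
    X0 <- cbind(ga, 1 - ga, rbind(Xa[, 2:3, drop = FALSE],
                                  Xb[, 2:3, drop = FALSE]))
    q <- 2L
  }
  rss_null <- sum(lm.fit(X0, y)$residuals^2)
  num <- max(rss_null - rss_full, 0)
  if (num <= 1e-12 * max(rss_null, 1e-300)) return(1)
  if (rss_full <= 0) return(.Machine$double.xmin)
  f_stat <- (num / q) / (rss_full / df_full)
  max(pf(f_stat, q, df_full, lower.tail = FALSE), .Machine$double.xmin)
}

#' Robust (Huber) test for a rhythm difference
#'
#' Fits each group's harmonic model by iteratively reweighted least squares
#' with Huber's psi (tuning constant 1.345, at most 50 iterations, tolerance
#' 1e-8) via `MASS::rlm`, then tests equality of the (a_cos, b_sin) pairs
#' with a Wald chi-square statistic on the coefficient differences using the
#' robust coefficient covariances. If either fit fails to converge the
#' parametric p-value is returned with a warning.
#'
#' @inheritParams compare_rhythms
#' @return p-value of the robust Wald test.
#' @export
robust_compare <- function(values_a, times_a, values_b, times_b = times_a,
                           period_h = 24) {
  Xa <- harmonic_design(times_a, period_h)
  Xb <- harmonic_design(times_b, period_h)
  fit1 <- tryCatch(MASS::rlm(Xa, values_a, psi = MASS::psi.huber,
                             maxit = 50, acc = 1e-8),
                   error = function(e) NULL)
  fit2 <- tryCatch(MASS::rlm(Xb, values_b, psi = MASS::psi.huber,
                             maxit = 50, acc = 1e-8),
                   error = function(e) NULL)
  fallback <- function() {
    warning("robust fit did not converge; falling back to the parametric test",
            call. = FALSE)
    compare_rhythms(values_a, times_a, values_b, times_b, period_h)
  }
  if (is.null(fit1) || is.null(fit2) || !fit1$converged || !fit2$converged) {
    return(fallback())
  }
  vc <- function(fit) {
    sm <- summary(fit, method = "XtWX")
    sm$stddev^2 * sm$cov.unscaled
  }
  V <- vc(fit1)[2:3, 2:3] + vc(fit2)[2:3, 2:3]
  d <- coef(fit1)[2:3] - coef(fit2)[2:3]
  W <- tryCatch(drop(t(d) %*% solve(V, d)), error = function(e) NA_real_)
  if (!is.finite(W)) return(fallback())
  max(pchisq(W, df = 2, lower.tail = FALSE), .Machine$double.xmin)
}

#' Combined meta p-value for a rhythm difference
#'
#' Fisher combination of the parametric and robust p-values (two components,
#' chi-square with 4 df).
#'
#' @param p_param,p_robust Component p-values in (0, 1].
#' @return Combined meta p-value.
#' @export
meta_p <- function(p_param, p_robust) {
  if (missing(p_param) || missing(p_robust) ||
      is.na(p_param) || is.na(p_robust)) {
    stop("both component p-values are required")
  }
  fisher_combine(c(p_param, p_robust))
}

# Vectorised parametric comparison for a genes x samples pair of matrices
# sharing the two design matrices; used by compare_groups and the
# calibration machinery. Returns the F-test p-value per gene.
compare_rhythms_matrix <- function(mat_a, times_a, mat_b, times_b = times_a,
                                   period_h = 24) {
  Xa <- harmonic_design(times_a, period_h)
  Xb <- harmonic_design(times_b, period_h)
  rss_of <- function(X, Y) colSums(lm.fit(X, Y)$residuals^2)
  rss_full <- rss_of(Xa, t(mat_a)) + rss_of(Xb, t(mat_b))
  na <- ncol(mat_a); nb <- ncol(mat_b)
  ga <- c(rep(1, na), rep(0, nb))
  X0 <- cbind(ga, 1 - ga,
              rbind(Xa[, 2:3, drop = FALSE], Xb[, 2:3, drop = FALSE]))
  Y0 <- rbind(t(mat_a), t(mat_b))
  rss_null <- rss_of(X0, Y0)
  df_full <- na + nb - 6L
  num <- pmax(rss_null - rss_full, 0)
  f_stat <- (num / 2) / (rss_full / df_full)
  p <- pf(f_stat, 2, df_full, lower.tail = FALSE)
  p[num <= 1e-12 * pmax(rss_null, 1e-300)] <- 1
  pmax(p, .Machine$double.xmin)
}

#' Per-gene rhythm-difference testing between two groups
#'
#' Runs the parametric F-test (vectorised) and the robust Wald test
#' (gene-by-gene) for every gene and combines them into a meta p-value,
#' together with each group's cosinor amplitude and phase.
#'
#' @param et An [expression_table()].
#' @param group_a,group_b Group labels to compare.
#' @param period_h Fixed comparison period (default 24).
#' @param robust If FALSE, skip the robust test and set meta_p from the
#'   parametric p alone.
#' @return data.frame: gene_id, p_param, p_robust, meta_p, phase_a, phase_b,
#'   amp_a, amp_b.
#' @export
compare_groups <- function(et, group_a, group_b, period_h = 24,
                           robust = TRUE) {
  stopifnot(inherits(et, "expression_table"))
  get_grp <- function(g) {
    sel <- et$samples$group == g
    if (!any(sel)) stop("no samples for group '", g, "'")
    ord <- order(et$samples$zt_h[sel])
    list(mat = et$expr[, which(sel)[ord], drop = FALSE],
         times = et$samples$zt_h[sel][ord])
  }
  A <- get_grp(group_a); B <- get_grp(group_b)
  p_param <- compare_rhythms_matrix(A$mat, A$times, B$mat, B$times, period_h)
  ng <- nrow(et$expr)
  fit_stats <- function(mat, times) {
    X <- harmonic_design(times, period_h)
    cf <- lm.fit(X, t(mat))$coefficients
    amp <- sqrt(cf[2, ]^2 + cf[3, ]^2)
    phase <- (period_h / (2 * pi) * atan2(cf[3, ], cf[2, ])) %% 24
    list(amp = amp, phase = phase)
  }
  sa <- fit_stats(A$mat, A$times); sb <- fit_stats(B$mat, B$times)
  if (robust) {
    p_robust <- numeric(ng)
    for (g in seq_len(ng)) {
      p_robust[g] <- suppressWarnings(
        robust_compare(A$mat[g, ], A$times, B$mat[g, ], B$times, period_h))
    }
    mp <- mapply(meta_p, p_param, p_robust)
  } else {
    p_robust <- rep(NA_real_, ng)
    mp <- p_param
  }
  data.frame(gene_id = rownames(et$expr),
             p_param = p_param, p_robust = p_robust, meta_p = mp,
             phase_a = unname(sa$phase), phase_b = unname(sb$phase),
             amp_a = unname(sa$amp), amp_b = unname(sb$amp),
             stringsAsFactors = FALSE, row.names = NULL)
}
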