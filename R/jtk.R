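# Rank-based rhythm detection: Kendall's S against tie-grouped cosine
# reference waveforms on a discrete period grid, with an exact permutation
# null computed by convolution of Gaussian-binomial inversion distributions.

#' Concatenate a single-cycle series into a multi-cycle series
#'
#' Duplicates one measured cycle end-to-end (e.g. an 8-point, 0-21 h day into
#' a 16-point, 0-45 h series). Rank-based detection was designed around two
#' cycles of data, so duplicating the single measured cycle stabilises it at
#' the documented cost of an inflated false-positive rate (the duplicated
#' points are not independent observations).
#'
#' @param values Abundances for one cycle.
#' @param times_h Strictly increasing sampling times, spanning at most one
#'   cycle.
#' @param n_cycles Number of copies (>= 1).
#' @param cycle_h Cycle length in hours.
#' @return List with elements `values` and `times_h`, each of length
#'   `length(values) * n_cycles`.
#' @export
concatenate_cycle <- function(values, times_h, n_cycles = 2, cycle_h = 24) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (length(values) != length(times_h)) stop("values/times length mismatch")
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  if (max(times_h) - min(times_h) >= cycle_h) {
    stop("series must span at most one cycle")
  }
  reps <- seq_len(n_cycles) - 1
  list(values = rep(values, n_cycles),
       times_h = as.vector(outer(times_h, reps * cycle_h, `+`)))
}

#' Candidate period grid for rhythm detection
#'
#' Periods are the integer multiples of the sampling interval falling inside
#' `[minper_h, maxper_h]` (3-h sampling with the default 20-28 h window gives
#' 21, 24 and 27 h), mirroring the discrete-period requirement of rank-based
#' detection.
#'
#' @param sampling_interval_h Sampling interval in hours.
#' @param minper_h,maxper_h Period window in hours (defaults 20 and 28).
#' @return Object of class `period_grid` with the derived `periods_h`.
#' @export
period_grid <- function(sampling_interval_h, minper_h = 20, maxper_h = 28) {
  if (sampling_interval_h <= 0) stop("sampling_interval_h must be > 0")
  if (maxper_h < minper_h) stop("maxper_h must be >= minper_h")
  ks <- seq(ceiling(minper_h / sampling_interval_h - 1e-9),
            floor(maxper_h / sampling_interval_h + 1e-9))
  periods <- ks * sampling_interval_h
  periods <- periods[periods >= minper_h - 1e-9 & periods <= maxper_h + 1e-9]
  if (!length(periods)) stop("no candidate periods in [minper_h, maxper_h]")
  structure(list(sampling_interval_h = sampling_interval_h,
                 minper_h = minper_h, maxper_h = maxper_h,
                 periods_h = periods),
            class = "period_grid")
}

#' Cosine reference waveforms as tie-grouped ranks
#'
#' One reference per (period, lag) with lags stepping at the sampling
#' resolution across one full period. Cosine values at the sample times are
#' rounded to 10 decimal places and converted to mid-ranks, so symmetric time
#' points with equal cosine value form tie groups that are excluded from
#' concordance counting.
#'
#' @param grid A [period_grid()].
#' @param times_h Sampling times of the (possibly concatenated) series.
#' @return List of waveforms, each with `period_h`, `lag_h`, `ranks` and the
#'   tie-group sizes `tie_sizes`.
#' @export
build_references <- function(grid, times_h) {
  stopifnot(inherits(grid, "period_grid"))
  refs <- list()
  for (per in grid$periods_h) {
    lags <- seq(0, per - grid$sampling_interval_h, by = grid$sampling_interval_h)
    for (lag in lags) {
      cosv <- round(cos(2 * pi * (times_h - lag) / per), 10)
      r <- rank(cosv, ties.method = "average")
      refs[[length(refs) + 1L]] <- list(
        period_h = per, lag_h = lag, ranks = r,
        tie_sizes = sort(as.integer(table(r))))
    }
  }
  refs
}

pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Kendall's S between data values and a (possibly tied) reference ranking
#'
#' S = concordant minus discordant pairs; pairs tied in the reference are
#' excluded. tau normalises S by the maximum attainable |S| given the
#' reference tie structure (data values are assumed tie-free; tied data pairs
#' contribute zero to S).
#'
#' @param values Numeric data values.
#' @param ref_ranks Reference ranks of the same length (ties allowed).
#' @return List with integer `S`, `tau`, and `max_S`.
#' @export
kendall_S <- function(values, ref_ranks) {
  n <- length(values)
  if (length(ref_ranks) != n) stop("values and ref_ranks length mismatch")
  pr <- pair_index(n)
  dv <- sign(values[pr$j] - values[pr$i])
  dr <- sign(ref_ranks[pr$j] - ref_ranks[pr$i])
  S <- sum(dv * dr)
  max_S <- sum(dr != 0)
  list(S = as.integer(S),
       tau = if (max_S > 0) S / max_S else NA_real_,
       max_S = as.integer(max_S))
}

# Coefficients of the Gaussian binomial [a+b choose b]_q (degrees 0..a*b):
# the inversion-count distribution added when a block of b tied elements is
# interleaved with a previously placed elements. Recurrence
# [m,k]_q = [m-1,k-1]_q + q^k [m-1,k]_q; coefficients stay below C(25,12),
# exactly representable in doubles.
gauss_binom_coeffs <- function(a, b) {
  if (a == 0 || b == 0) return(1)
  prev <- list(1)            # m = 0: only k = 0
  for (m in seq_len(a + b)) {
    kmax <- min(m, b)
    cur <- vector("list", kmax + 1L)
    cur[[1L]] <- 1
    for (k in seq_len(kmax)) {
      t1 <- if (k <= length(prev)) prev[[k]] else numeric(0)       # [m-1,k-1]
      t2 <- if (k + 1L <= length(prev)) prev[[k + 1L]] else numeric(0) # [m-1,k]
      if (length(t2)) t2 <- c(numeric(k), t2)                      # * q^k
      L <- max(length(t1), length(t2))
      s <- numeric(L)
      if (length(t1)) s[seq_along(t1)] <- t1
      if (length(t2)) s[seq_along(t2)] <- s[seq_along(t2)] + t2
      cur[[k + 1L]] <- s
    }
    prev <- cur
  }
  prev[[b + 1L]]
}

conv_open <- function(x, y) {
  # direct open convolution (exact; lengths stay small)
  nx <- length(x); ny <- length(y)
  out <- numeric(nx + ny - 1L)
  for (k in seq_len(ny)) out[k:(k + nx - 1L)] <- out[k:(k + nx - 1L)] + x * y[k]
  out
}

#' Exact permutation null of Kendall's S for a tied reference
#'
#' Distribution of S when tie-free data are assigned uniformly at random to a
#' reference ranking with tie groups of the given sizes. The discordance
#' count equals the inversion count of a random multiset permutation, whose
#' distribution is built by convolving Gaussian-binomial blocks; S is then a
#' linear transform of the discordance. Exact (matches exhaustive
#' enumeration) for any n; intended for n <= 25, beyond which
#' [jtk_test()] switches to a normal approximation.
#'
#' @param n_points Series length.
#' @param tie_sizes Integer sizes of the reference tie groups (must sum to
#'   `n_points`); default: no ties.
#' @return List with support `S` (decreasing), `prob`, and `max_S`.
#' @export
exact_null_S <- function(n_points, tie_sizes = rep(1L, n_points)) {
  if (sum(tie_sizes) != n_points) stop("tie_sizes must sum to n_points")
  M <- (n_points * (n_points - 1) - sum(tie_sizes * (tie_sizes - 1))) / 2
  d <- 1
  placed <- 0L
  for (sz in tie_sizes) {
    if (placed > 0L) {
      g <- gauss_binom_coeffs(placed, sz)
      d <- conv_open(d, g / sum(g))
    }
    placed <- placed + as.integer(sz)
  }
  list(S = M - 2 * (seq_along(d) - 1L), prob = d, max_S = as.integer(M))
}

# Two-sided tail lookup: vector tail[k] = P(|S| >= s_k) for the descending
# positive support values, queried by absolute observed S.
null_tail_fun <- function(null) {
  s <- null$S
  p <- null$prob
  abs_s <- sort(unique(abs(s)), decreasing = TRUE)
  tails <- vapply(abs_s, function(a) sum(p[abs(s) >= a]), numeric(1))
  function(s_obs) {
    idx <- which(abs_s >= abs(s_obs) - 1e-9)
    if (!length(idx)) return(1)
    min(1, tails[max(idx)])
  }
}

# Normal approximation to the two-sided S tail with continuity correction,
# using the tie-corrected Kendall variance (ties in the reference only).
normal_tail_S <- function(s_obs, n, tie_sizes) {
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  if (v <= 0) return(1)
  z <- (abs(s_obs) - 1) / sqrt(v)
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' Rank-based rhythm test of one series against a cosine reference family
#'
#' For every (period, lag) reference the two-sided exact p-value of |S| is
#' computed from the permutation null; the reported p is the minimum across
#' references, the reported lag/period are those of the best reference
#' (preferring positive S, then earlier grid order), and `adj_p` applies a
#' within-gene multiplicity correction controlled by `adjust`:
#' `"bonferroni_all"` (default; all period-lag references, the original
#' convention for rank-based rhythm screens), `"bonferroni_periods"` (lags
#' within a period treated as one family), or `"none"`.
#'
#' @param values,times_h The (optionally concatenated) series; length >= 4.
#' @param grid A [period_grid()]; defaults to 20-28 h on the series' sampling
#'   interval.
#' @param adjust Within-gene multiplicity correction mode.
#' @param cycle_h Clock cycle for phase reporting; lags are reported modulo
#'   24 h regardless of the fitted period.
#' @param exact_max_n Above this series length the normal approximation with
#'   continuity correction replaces the exact null.
#' @return List with `p`, `adj_p`, `period_h`, `lag_h`, `tau`,
#'   `amplitude_est` (half peak-to-trough of per-timepoint means) and
#'   `constant` (TRUE when the series carries no ordering information, in
#'   which case p = adj_p = 1 and period/lag/tau are NA).
#' @export
jtk_test <- function(values, times_h, grid = NULL,
                     adjust = c("bonferroni_all", "bonferroni_periods", "none"),
                     cycle_h = 24, exact_max_n = 25) {
  adjust <- match.arg(adjust)
  n <- length(values)
  if (n < 4) stop("series length must be >= 4")
  if (length(times_h) != n) stop("values/times length mismatch")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.null(grid)) {
    grid <- period_grid(min(diff(times_h)))
  }
  if (length(unique(values)) == 1L) {
    return(list(p = 1, adj_p = 1, period_h = NA_real_, lag_h = NA_real_,
                tau = NA_real_, amplitude_est = 0, constant = TRUE))
  }
  refs <- build_references(grid, times_h)
  null_cache <- list()
  best <- NULL
  for (ref in refs) {
    ks <- kendall_S(values, ref$ranks)
    key <- paste(ref$tie_sizes, collapse = ",")
    if (n <= exact_max_n) {
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- null_tail_fun(exact_null_S(n, ref$tie_sizes))
      }
      p <- null_cache[[key]](ks$S)
    } else {
      p <- normal_tail_S(ks$S, n, ref$tie_sizes)
    }
    cand <- list(p = p, S = ks$S, tau = ks$tau,
                 period_h = ref$period_h, lag_h = ref$lag_h)
    if (is.null(best) || p < best$p - 1e-15 ||
        (abs(p - best$p) <= 1e-15 && ks$S > best$S)) {
      best <- cand
    }
  }
  n_fam <- switch(adjust,
                  bonferroni_periods = length(grid$periods_h),
                  bonferroni_all = length(refs),
                  none = 1)
  tp_means <- tapply(values, round(times_h %% cycle_h, 9), mean)
  list(p = best$p,
       adj_p = min(1, best$p * n_fam),
       period_h = best$period_h,
       lag_h = best$lag_h %% 24,
       tau = best$tau,
       amplitude_est = (max(tp_means) - min(tp_means)) / 2,
       constant = FALSE)
}

#' Benjamini-Hochberg adjustment across genes
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values p-values in (0, 1].
#' @return BH step-up q-values (monotone in p, q >= p).
#' @export
bh_adjust <- function(p_values) {
  stop_if_not_prob(p_values)
  p.adjust(p_values, method = "BH")
}

#' Detect rhythmic genes in one group of an expression table
#'
#' Runs the rank-based rhythm test gene-by-gene on the samples of one group
#' (internally vectorised across genes: the sign matrix of data pairs is
#' multiplied against the reference pair signs once per group). The single
#' measured cycle is concatenated `n_cycles` times before testing (set
#' `n_cycles = 1` to analyse the raw cycle). Optionally a Lomb-Scargle test
#' is run on the same period grid and combined with the rank-based p by
#' Fisher's method (`meta_p_detect`), emulating an ensemble detector.
#'
#' @param et An [expression_table()].
#' @param group Group label to analyse.
#' @param minper_h,maxper_h Period window (hours).
#' @param n_cycles Concatenation factor (default 2, i.e. a 48-h series from
#'   one 24-h cycle).
#' @param adjust Within-gene correction mode, see [jtk_test()].
#' @param lomb_scargle If TRUE, add `ls_p` and `meta_p_detect` columns.
#' @param cycle_h Cycle length (default 24).
#' @return data.frame: gene_id, group, p, adj_p, q_bh (BH across genes of
#'   adj_p), period_h, lag_h, tau, amplitude_est.
#' @export
detect_rhythms <- function(et, group, minper_h = 20, maxper_h = 28,
                           n_cycles = 2,
                           adjust = c("bonferroni_all", "bonferroni_periods",
                                      "none"),
                           lomb_scargle = FALSE, cycle_h = 24) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(et, "expression_table"))
  sel <- et$samples$group == group
  if (!any(sel)) stop("no samples for group '", group, "'")
  ord <- order(et$samples$zt_h[sel])
  times1 <- et$samples$zt_h[sel][ord]
  V1 <- et$expr[, which(sel)[ord], drop = FALSE]
  cc <- concatenate_cycle(times1, times1, n_cycles, cycle_h)  # times only
  times <- cc$times_h
  V <- V1[, rep(seq_along(times1), n_cycles), drop = FALSE]
  n <- length(times)

  grid <- period_grid(min(diff(times1)), minper_h, maxper_h)
  refs <- build_references(grid, times)
  pr <- pair_index(n)
  # gene x pair sign matrix
  D <- sign(V[, pr$j, drop = FALSE] - V[, pr$i, drop = FALSE])
  # pair x waveform reference signs
  R <- vapply(refs, function(rf) sign(rf$ranks[pr$j] - rf$ranks[pr$i]),
              numeric(length(pr$i)))
  S <- D %*% R  # genes x waveforms
  max_S <- colSums(R != 0)

  use_exact <- n <= 25
  tail_funs <- list()
  P <- matrix(1, nrow(S), ncol(S))
  for (w in seq_along(refs)) {
    key <- paste(refs[[w]]$tie_sizes, collapse = ",")
    if (use_exact) {
      if (is.null(tail_funs[[key]])) {
        null <- exact_null_S(n, refs[[w]]$tie_sizes)
        # vectorised tail: map |S| -> P(|S'| >= |S|)
        abs_s <- sort(unique(abs(null$S)), decreasing = TRUE)
        tails <- vapply(abs_s, function(a) sum(null$prob[abs(null$S) >= a]),
                        numeric(1))
        tail_funs[[key]] <- function(sv) {
          idx <- vapply(abs(sv), function(a) max(which(abs_s >= a - 1e-9)),
                        integer(1))
          pmin(1, tails[idx])
        }
      }
      P[, w] <- tail_funs[[key]](S[, w])
    } else {
      P[, w] <- vapply(S[, w], normal_tail_S, numeric(1),
                       n = n, tie_sizes = refs[[w]]$tie_sizes)
    }
  }
  # best waveform per gene: min p, prefer larger S on ties
  periods <- vapply(refs, `[[`, numeric(1), "period_h")
  lags <- vapply(refs, `[[`, numeric(1), "lag_h")
  ng <- nrow(S)
  best_w <- integer(ng)
  for (g in seq_len(ng)) {
    pmin_g <- min(P[g, ])
    cand <- which(P[g, ] <= pmin_g + 1e-15)
    best_w[g] <- cand[which.max(S[g, cand])]
  }
  n_fam <- switch(adjust, bonferroni_periods = length(grid$periods_h),
                  bonferroni_all = length(refs), none = 1)
  p <- P[cbind(seq_len(ng), best_w)]
  tau <- S[cbind(seq_len(ng), best_w)] / max_S[best_w]
  lag_h <- lags[best_w] %% 24
  period_h <- periods[best_w]
  # constant series carry no ordering information
  const <- apply(V, 1, function(v) length(unique(v)) == 1L)
  p[const] <- 1; tau[const] <- NA_real_
  lag_h[const] <- NA_real_; period_h[const] <- NA_real_
  adj_p <- pmin(1, p * n_fam)

  tp_key <- round(times %% cycle_h, 9)
  amp <- apply(V, 1, function(v) {
    m <- tapply(v, tp_key, mean); (max(m) - min(m)) / 2
  })

  out <- data.frame(gene_id = rownames(et$expr), group = group,
                    p = p, adj_p = adj_p, q_bh = bh_adjust(adj_p),
                    period_h = period_h, lag_h = lag_h, tau = tau,
                    amplitude_est = amp, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (lomb_scargle) {
    out$ls_p <- apply(V1, 1, function(v)
      lomb_scargle_test(v, times1, grid, cycle_h = cycle_h))
    out$meta_p_detect <- mapply(function(a, b) fisher_combine(c(a, b)),
                                out$p, out$ls_p)
  }
  out
}
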