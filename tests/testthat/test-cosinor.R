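# Harmonic regression and the between-group rhythm-difference tests.

t8 <- seq(0, 21, by = 3)
t16 <- c(t8, t8 + 24)

test_that("harmonic_fit recovers model-matched inputs exactly", {
  y <- cosine_wave(t8, 100, 50, 6)
  f <- harmonic_fit(y, t8)
  expect_equal(f$mesor, 100, tolerance = 1e-9)
  expect_equal(f$amplitude, 50, tolerance = 1e-9)
  expect_equal(f$phase_h, 6, tolerance = 1e-9)
  expect_lt(f$rss, 1e-18)
  expect_equal(f$df_resid, 5L)
  fc <- harmonic_fit(rep(7, 8), t8)
  expect_equal(fc$mesor, 7)
  expect_equal(fc$amplitude, 0)
  expect_error(harmonic_fit(1:3, c(0, 3, 6)), ">= 4")
})

test_that("amplitude estimates respect OLS sampling theory", {
  # var(a_cos) = var(b_sin) = sigma^2 / (n/2) on a balanced grid; at high
  # signal-to-noise the amplitude is approximately normal with that variance
  se <- sqrt(1 / (16 / 2))
  set.seed(61)
  hits <- replicate(600, {
    y <- cosine_wave(t16, 100, 50, 6) + rnorm(16, sd = 1)
    abs(harmonic_fit(y, t16)$amplitude - 50) <= 3 * se
  })
  expect_gte(mean(hits), 0.99 - 0.015)
})

test_that("identical series give p = 1 and shared shifts leave p unchanged", {
  set.seed(62)
  y <- cosine_wave(t16, 100, 30, 9) + rnorm(16, sd = 5)
  z <- cosine_wave(t16, 90, 30, 15) + rnorm(16, sd = 5)
  expect_equal(compare_rhythms(y, t16, y, t16), 1)
  expect_equal(suppressWarnings(robust_compare(y, t16, y, t16)), 1,
               tolerance = 1e-6)
  p0 <- compare_rhythms(y, t16, z, t16)
  expect_equal(compare_rhythms(y + 50, t16, z + 50, t16), p0)
  expect_equal(compare_rhythms(y * 3, t16, z * 3, t16), p0)
  pr0 <- robust_compare(y, t16, z, t16)
  expect_equal(robust_compare(y * 3 + 50, t16, z * 3 + 50, t16), pr0,
               tolerance = 1e-6)
})

test_that("a 12 h phase flip is detected with high power", {
  set.seed(63)
  rej <- replicate(200, {
    a <- cosine_wave(t16, 100, 50, 20) * exp(rnorm(16, sd = 0.1))
    b <- cosine_wave(t16, 100, 50, 8) * exp(rnorm(16, sd = 0.1))
    compare_rhythms(a, t16, b, t16) < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("rejection rate grows with the programmed phase difference", {
  set.seed(64)
  rate <- vapply(c(0, 3, 6, 9, 12), function(shift) {
    mean(replicate(150, {
      a <- cosine_wave(t16, 100, 30, 18) + rnorm(16, sd = 12)
      b <- cosine_wave(t16, 100, 30, 18 + shift) + rnorm(16, sd = 12)
      compare_rhythms(a, t16, b, t16) < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.03))  # monotone up to Monte-Carlo noise
  expect_lt(rate[1], 0.12)
  expect_gt(rate[5], 0.9)
})

test_that("the robust test keeps detecting a flip through a gross outlier", {
  # a true 12 h flip is overwhelming evidence for both tests on clean data;
  # one x10 outlier destroys the parametric test (its variance estimate
  # explodes) but barely touches the Huber-weighted one
  set.seed(65)
  a <- cosine_wave(t16, 100, 50, 20) + rnorm(16, sd = 5)
  b <- cosine_wave(t16, 100, 50, 8) + rnorm(16, sd = 5)
  expect_lt(compare_rhythms(a, t16, b, t16), 1e-10)
  expect_lt(robust_compare(a, t16, b, t16), 1e-10)
  b_out <- b
  b_out[4] <- b_out[4] * 10
  expect_gt(compare_rhythms(a, t16, b_out, t16), 0.01)
  expect_lt(robust_compare(a, t16, b_out, t16), 1e-10)
})

test_that("robust and parametric tests agree on clean Gaussian data", {
  set.seed(66)
  dl <- replicate(200, {
    a <- cosine_wave(t16, 100, 40, 20) + rnorm(16, sd = 8)
    b <- cosine_wave(t16, 100, 40, 20) + rnorm(16, sd = 8)
    abs(log10(robust_compare(a, t16, b, t16)) -
          log10(compare_rhythms(a, t16, b, t16)))
  })
  expect_lt(median(dl), 0.3)
})

test_that("meta_p is the two-component Fisher combination", {
  expect_equal(meta_p(1, 1), 1)
  expect_equal(meta_p(0.05, 0.05), 0.0174787, tolerance = 1e-4)
  expect_error(meta_p(0.5), "both component")
  # dominance: meta_p <= max component whenever the smaller one sits below
  # the two-component Fisher fixed point (~0.284)
  grid <- expand.grid(u = seq(0.01, 0.99, by = 0.007),
                      v = seq(0.01, 0.99, by = 0.007))
  sel <- pmin(grid$u, grid$v) < 0.28
  mp <- mapply(meta_p, grid$u, grid$v)
  expect_true(all(mp[sel] <= pmax(grid$u, grid$v)[sel] + 1e-12))
})

test_that("compare_groups matches the single-gene functions", {
  ds <- small_sim(25, seed = 19)
  res <- compare_groups(ds$table, "KO", "WT")
  sel_a <- ds$table$samples$group == "KO"
  sel_b <- ds$table$samples$group == "WT"
  tp <- ds$table$samples$zt_h[sel_a]
  for (i in c(2, 11, 23)) {
    a <- ds$table$expr[i, sel_a]
    b <- ds$table$expr[i, sel_b]
    expect_equal(res$p_param[i], compare_rhythms(a, tp, b, tp),
                 tolerance = 1e-10)
    expect_equal(res$p_robust[i],
                 suppressWarnings(robust_compare(a, tp, b, tp)),
                 tolerance = 1e-8)
    expect_equal(res$meta_p[i], meta_p(res$p_param[i], res$p_robust[i]))
    expect_equal(res$phase_a[i], harmonic_fit(a, tp)$phase_h,
                 tolerance = 1e-9)
  }
})
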