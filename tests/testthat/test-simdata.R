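# Synthetic-data generator: category apportionment, waveform, pooling noise,
# determinism, round trips.

test_that("category counts follow largest-remainder rounding exactly", {
  tr <- generate_truth(10, fractions = c(arrhythmic_both = 0.5,
                                         gained_in_B = 0.5), seed = 1)
  expect_equal(sum(tr$category == "arrhythmic_both"), 5)
  expect_equal(sum(tr$category == "gained_in_B"), 5)

  # 7 genes at 1/3 each: floors 2/2/2, one remainder seat to the first
  tr7 <- generate_truth(7, fractions = c(arrhythmic_both = 1 / 3,
                                         rhythmic_unchanged = 1 / 3,
                                         gained_in_B = 1 / 3), seed = 1)
  expect_equal(unname(table(tr7$category)[c("arrhythmic_both",
                                            "rhythmic_unchanged",
                                            "gained_in_B")]),
               c(3L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(nrow(tr7), 7)

  expect_error(generate_truth(10, fractions = c(arrhythmic_both = 0.7)),
               "sum to 1")
  expect_error(generate_truth(10, fractions = c(nonsense = 1)), "unknown")
  expect_error(generate_truth(0), ">= 1")
})

test_that("gained-category phases cluster tightly around their target", {
  tr <- generate_truth(2000, fractions = c(arrhythmic_both = 0.5,
                                           gained_in_B = 0.5), seed = 3)
  ph <- tr$phase_h_KO[tr$category == "gained_in_B"]
  mv <- mean_vector(ph)
  expect_lt(abs(mv$mean_phase_h - 6), 0.5)
  expect_gt(mv$R, 0.8)  # concentration parameter 8 is a tight cluster
})

test_that("truth generation is seed-reproducible with per-gene substreams", {
  a <- generate_truth(50, seed = 42)
  b <- generate_truth(50, seed = 42)
  expect_identical(a, b)
  d <- generate_truth(50, seed = 43)
  expect_false(identical(a, d))
  # adding genes must not perturb earlier genes' draws (same category layout)
  small <- generate_truth(50, fractions = c(rhythmic_unchanged = 1), seed = 9)
  big <- generate_truth(100, fractions = c(rhythmic_unchanged = 1), seed = 9)
  expect_equal(small$mesor_WT, big$mesor_WT[1:50])
  expect_equal(small$phase_h_WT, big$phase_h_WT[1:50])
})

test_that("expression_profile is a cosinor with peak at phase", {
  expect_equal(expression_profile(100, 0.5, 6, 6), 150)
  expect_equal(expression_profile(100, 0.5, 6, 18), 50)
  expect_equal(expression_profile(7, 0, 3, seq(0, 21, 3)), rep(7, 8))
  # peak location: maximum over a fine grid sits at t = phase (mod 24)
  tt <- seq(0, 23.99, by = 0.01)
  prof <- expression_profile(10, 0.3, 17, tt)
  expect_equal(tt[which.max(prof)], 17)
  expect_error(expression_profile(100, 1.2, 6, 0), "negative abundance")
})

test_that("zero-noise simulation reproduces profiles to machine precision", {
  design <- sim_design(seed = 5)
  truth <- generate_truth(20, fractions = c(rhythmic_unchanged = 1),
                          noise_cv = 0, seed = 5)
  ds <- simulate_dataset(design, truth)
  tp <- design$timepoints_h
  for (i in c(1, 7, 20)) {
    expected <- expression_profile(truth$mesor_WT[i],
                                   truth$rel_amplitude_WT[i],
                                   truth$phase_h_WT[i], tp)
    expect_equal(unname(ds$table$expr[i, paste0("WT_ZT",
                                                sprintf("%02d", tp))]),
                 expected, tolerance = 1e-12)
  }
})

test_that("pooling three animals cuts noise variance to about one third", {
  mk <- function(k, seed) {
    design <- sim_design(animals_per_pool = k, seed = seed)
    truth <- generate_truth(400, fractions = c(arrhythmic_both = 1),
                            noise_cv = 0.2, mesor_sdlog = 0, seed = seed)
    ds <- simulate_dataset(design, truth)
    as.vector(ds$table$expr) / 100  # constant true mean 100
  }
  v3 <- var(mk(3, 21))
  v1 <- var(mk(1, 22))
  expect_lt(abs(v3 / v1 - 1 / 3), 0.05)
})

test_that("noisy draws are mean-preserving around the profile", {
  # lognormal mode: empirical mean over many genes converges to the mesor
  design <- sim_design(animals_per_pool = 1, seed = 31)
  truth <- generate_truth(3500, fractions = c(arrhythmic_both = 1),
                          noise_cv = 0.3, mesor_sdlog = 0, seed = 31)
  ds <- simulate_dataset(design, truth)
  expect_lt(abs(mean(ds$table$expr) / 100 - 1), 0.01)
  expect_true(all(ds$table$expr > 0))
})

test_that("negative-binomial mode yields non-negative integer counts", {
  design <- sim_design(animals_per_pool = 1, seed = 8)
  truth <- generate_truth(100, seed = 8)
  ds <- simulate_dataset(design, truth,
                         noise_model = "negative_binomial_dispersion")
  expect_true(all(ds$table$expr >= 0))
  expect_true(all(ds$table$expr == round(ds$table$expr)))
  expect_identical(ds$table$kind, "counts")
})

test_that("datasets round-trip through TSV files", {
  ds <- small_sim(40)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  et <- read_expression(paths[["expression"]])
  expect_equal(et$expr, ds$table$expr, tolerance = 1e-12)
  expect_identical(et$samples, ds$table$samples)
  tr <- read_truth(paths[["truth"]])
  expect_equal(nrow(tr), 40)
  expect_identical(tr$category, ds$truth$category)
  expect_identical(attr(tr, "groups"), c("WT", "KO"))
  # sample naming convention
  expect_true(all(grepl("^(WT|KO)_ZT[0-9]{2}$", colnames(et$expr))))
})
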