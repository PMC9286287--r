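# The decision-table classifier.

test_that("circular phase differences wrap and stay below half a cycle", {
  expect_equal(circular_phase_diff(18, 6), 12)
  expect_equal(circular_phase_diff(2, 22), 4)
  expect_equal(circular_phase_diff(6, 6), 0)
  expect_equal(circular_phase_diff(1, 23), circular_phase_diff(23, 1))
  expect_true(is.na(circular_phase_diff(NA, 5)))
  ph <- runif(200, 0, 24)
  expect_true(all(circular_phase_diff(ph, rev(ph)) <= 12))
})

test_that("the default rule table reproduces the printed criteria", {
  rt <- default_rule_table("as_printed")
  gained <- rt[rt$category == "gained_in_g1_only", ]
  expect_equal(gained$p1_op, "lt"); expect_equal(gained$p1_thr, 0.05)
  expect_equal(gained$p2_op, "gt"); expect_equal(gained$p2_thr, 0.1)
  expect_equal(gained$meta_op, "gt"); expect_equal(gained$meta_thr, 0.01)
  expect_equal(gained$phase_op, "none")

  dc <- default_rule_table("difference_consistent")
  plain <- function(x) {
    x <- as.data.frame(x)
    attr(x, "orientation") <- NULL
    rownames(x) <- NULL
    x
  }
  # the phase-change row uses no meta predicate, hence is orientation-free
  expect_identical(plain(rt[rt$category == "rhythmic_both_phase_change", ]),
                   plain(dc[dc$category == "rhythmic_both_phase_change", ]))
  # the presets differ only in the meta inequality of the other four rows
  differs <- vapply(seq_len(nrow(rt)), function(i)
    !identical(rt$meta_op[i], dc$meta_op[i]), logical(1))
  expect_equal(sum(differs), 4)
  expect_identical(plain(rt[, setdiff(names(rt), "meta_op")]),
                   plain(dc[, setdiff(names(dc), "meta_op")]))
})

test_that("single-gene classification matches the printed examples", {
  rt <- default_rule_table("as_printed")
  expect_equal(classify_gene(list(adjp_g1 = 0.01, adjp_g2 = 0.05,
                                  meta_p = 0.5, phase_diff_h = 11),
                             rt)$category,
               "rhythmic_both_phase_change")
  expect_equal(classify_gene(list(adjp_g1 = 0.01, adjp_g2 = 0.5,
                                  meta_p = 0.5, phase_diff_h = NA),
                             rt)$category,
               "gained_in_g1_only")
  expect_equal(classify_gene(list(adjp_g1 = 0.5, adjp_g2 = 0.5,
                                  meta_p = 0.5, phase_diff_h = NA),
                             rt)$category,
               "unclassified")
})

test_that("boundary-value enumeration matches the hand-applied table", {
  vals <- c(0.04, 0.05, 0.06, 0.09, 0.1, 0.11)
  grid <- expand.grid(p1 = vals, p2 = vals, metap = c(0.005, 0.02),
                      dphi = c(5, 7))
  for (orient in c("as_printed", "difference_consistent")) {
    rt <- default_rule_table(orient)
    got <- vapply(seq_len(nrow(grid)), function(i)
      classify_gene(list(adjp_g1 = grid$p1[i], adjp_g2 = grid$p2[i],
                         meta_p = grid$metap[i],
                         phase_diff_h = grid$dphi[i]), rt)$category,
      character(1))
    want <- vapply(seq_len(nrow(grid)), function(i)
      oracle_classify(grid$p1[i], grid$p2[i], grid$metap[i], grid$dphi[i],
                      flip_meta = (orient == "difference_consistent")),
      character(1))
    expect_identical(got, want)
  }
})

test_that("thresholds are strict: 0.05 and 6 h fall outside their rules", {
  rt <- default_rule_table("as_printed")
  at_p1 <- classify_gene(list(adjp_g1 = 0.05, adjp_g2 = 0.01, meta_p = 0.5,
                              phase_diff_h = 2), rt)
  expect_false(at_p1$category %in% c("rhythmic_both_unchanged",
                                     "rhythmic_both_phase_change",
                                     "rhythmic_both_other_difference"))
  at_phase <- classify_gene(list(adjp_g1 = 0.01, adjp_g2 = 0.01,
                                 meta_p = 0.5, phase_diff_h = 6), rt)
  expect_false(at_phase$category == "rhythmic_both_phase_change")
})

test_that("every gene receives exactly one label and counts partition", {
  set.seed(33)
  n <- 500
  stats <- data.frame(gene_id = paste0("g", 1:n),
                      adjp_g1 = runif(n), adjp_g2 = runif(n),
                      meta_p = runif(n),
                      phase_g1_h = runif(n, 0, 24),
                      phase_g2_h = runif(n, 0, 24))
  stats$phase_g1_h[stats$adjp_g1 > 0.5] <- NA  # undefined arrhythmic phases
  res <- classify_all(stats, default_rule_table("difference_consistent"))
  expect_equal(sum(res$counts), n)
  expect_equal(nrow(res$classified), n)
  expect_true(all(res$classified$category %in% names(res$counts)))
  expect_error(classify_all(stats[c(1, 1, 2), ]), "duplicate")
})

test_that("tightening the rhythm cutoffs never inflates rhythmic categories", {
  set.seed(34)
  n <- 800
  stats <- data.frame(gene_id = paste0("g", 1:n),
                      adjp_g1 = runif(n)^2, adjp_g2 = runif(n)^2,
                      meta_p = runif(n),
                      phase_g1_h = runif(n, 0, 24),
                      phase_g2_h = runif(n, 0, 24))
  loose <- classify_all(stats, default_rule_table("difference_consistent"))
  tight <- classify_all(stats, default_rule_table("difference_consistent",
                                                  adjp1 = 0.01,
                                                  adjp2 = 0.02))
  rhythmic_cats <- c("rhythmic_both_unchanged", "rhythmic_both_phase_change",
                     "rhythmic_both_other_difference")
  expect_true(all(tight$counts[rhythmic_cats] <= loose$counts[rhythmic_cats]))
})

test_that("swapping groups exchanges gained and lost labels", {
  set.seed(35)
  n <- 600
  stats <- data.frame(gene_id = paste0("g", 1:n),
                      adjp_g1 = runif(n), adjp_g2 = runif(n),
                      meta_p = runif(n),
                      phase_g1_h = runif(n, 0, 24),
                      phase_g2_h = runif(n, 0, 24))
  swapped <- stats
  swapped$adjp_g1 <- stats$adjp_g2; swapped$adjp_g2 <- stats$adjp_g1
  swapped$phase_g1_h <- stats$phase_g2_h; swapped$phase_g2_h <- stats$phase_g1_h
  rt <- default_rule_table("difference_consistent")
  a <- classify_all(stats, rt)$classified$category
  b <- classify_all(swapped, rt)$classified$category
  expect_identical(b[a == "gained_in_g1_only"],
                   rep("lost_in_g1", sum(a == "gained_in_g1_only")))
  expect_identical(b[a == "lost_in_g1"],
                   rep("gained_in_g1_only", sum(a == "lost_in_g1")))
  # away from the asymmetric 0.05/0.1 boundary zone the rhythmic-in-both
  # block is symmetric too
  clear <- (stats$adjp_g1 < 0.05 & stats$adjp_g2 < 0.05) |
    (stats$adjp_g1 > 0.1 & stats$adjp_g2 > 0.1)
  both_cats <- c("rhythmic_both_unchanged", "rhythmic_both_phase_change",
                 "rhythmic_both_other_difference")
  expect_identical((a %in% both_cats)[clear], (b %in% both_cats)[clear])
})
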