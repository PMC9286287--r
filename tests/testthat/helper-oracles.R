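# Independent oracles used across the suite. These deliberately use naive
# enumeration / closed forms, never the package's own computational path.

# All permutations of a vector (n <= 7 only; used for exhaustive nulls).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Kendall S by literal pair counting (independent of kendall_S).
naive_S <- function(values, ref) {
  n <- length(values)
  s <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(values[j] - values[i]) * sign(ref[j] - ref[i])
  }
  s
}

# Exhaustive two-sided p-value of |S| under all n! data orderings.
brute_force_p <- function(s_obs, ref) {
  n <- length(ref)
  svals <- vapply(all_perms(seq_len(n)), naive_S, numeric(1), ref = ref)
  mean(abs(svals) >= abs(s_obs))
}

# Exhaustive pmf of S for a fixed reference ranking.
brute_force_null <- function(ref) {
  n <- length(ref)
  svals <- vapply(all_perms(seq_len(n)), naive_S, numeric(1), ref = ref)
  tab <- table(svals)
  list(S = as.numeric(names(tab)), prob = as.numeric(tab) / length(svals))
}

# Cosine profile in the package's waveform convention.
cosine_wave <- function(times_h, mesor, amp, phase_h, period_h = 24) {
  mesor + amp * cos(2 * pi * (times_h - phase_h) / period_h)
}

# Hand application of the printed five-row decision table (plus catch-all),
# written as literal nested conditions; `flip_meta` selects the
# difference-consistent orientation.
oracle_classify <- function(p1, p2, metap, dphi, flip_meta = FALSE) {
  m_lt <- if (flip_meta) metap > 0.01 else metap < 0.01   # "unchanged" rule
  m_gt <- if (flip_meta) metap < 0.01 else metap > 0.01   # "difference" rules
  if (p1 < 0.05 && p2 < 0.1 && m_lt && !is.na(dphi) && dphi < 6) {
    return("rhythmic_both_unchanged")
  }
  if (p1 < 0.05 && p2 < 0.1 && !is.na(dphi) && dphi > 6) {
    return("rhythmic_both_phase_change")
  }
  if (p1 < 0.05 && p2 < 0.1 && m_gt && !is.na(dphi) && dphi < 6) {
    return("rhythmic_both_other_difference")
  }
  if (p1 < 0.05 && p2 > 0.1 && m_gt) return("gained_in_g1_only")
  if (p1 > 0.1 && p2 < 0.05 && m_gt) return("lost_in_g1")
  "unclassified"
}

# Truth-category -> expected classifier label, for recovery tests run with
# group 1 = perturbed condition (B) and group 2 = reference (A).
truth_to_class <- c(arrhythmic_both = "unclassified",
                    rhythmic_unchanged = "rhythmic_both_unchanged",
                    phase_shifted = "rhythmic_both_phase_change",
                    other_changed = "rhythmic_both_other_difference",
                    gained_in_B = "gained_in_g1_only",
                    lost_in_B = "lost_in_g1")

# Shared small simulated dataset for pipeline-level tests.
small_sim <- function(n_genes = 150, seed = 7, ...) {
  design <- sim_design(seed = seed)
  truth <- generate_truth(n_genes, seed = seed, ...)
  simulate_dataset(design, truth)
}
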