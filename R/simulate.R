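#' Simulation design for a pooled circadian expression experiment
#'
#' Describes the sampling design the simulator emulates: one light-dark cycle
#' sampled at fixed Zeitgeber times, two or more groups, and equal-mass RNA
#' pooling of several animals per group and timepoint (pooling is modelled as
#' the arithmetic mean of independent noisy per-animal profiles).
#'
#' @param timepoints_h Strictly increasing sampling times within one cycle,
#'   in ZT hours. Default: 8 timepoints at 3-h intervals (0, 3, ..., 21).
#' @param cycle_h Cycle length in hours (default 24).
#' @param groups Ordered group labels. The first label is the reference
#'   condition ("A"), the second the perturbed condition ("B") for the
#'   two-group truth categories.
#' @param animals_per_pool Number of animals pooled per group and timepoint.
#' @param seed Integer master seed for all simulator randomness.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(timepoints_h = seq(0, 21, by = 3), cycle_h = 24,
                       groups = c("WT", "KO"), animals_per_pool = 3L,
                       seed = 1L) {
  if (cycle_h <= 0) stop("cycle_h must be positive")
  if (length(timepoints_h) < 1 || any(diff(timepoints_h) <= 0)) {
    stop("timepoints_h must be strictly increasing")
  }
  if (any(timepoints_h < 0 | timepoints_h >= cycle_h)) {
    stop("timepoints_h must lie in [0, cycle_h)")
  }
  if (length(groups) < 1 || anyDuplicated(groups)) {
    stop("groups must be distinct labels")
  }
  if (animals_per_pool < 1) stop("animals_per_pool must be >= 1")
  structure(list(timepoints_h = timepoints_h, cycle_h = cycle_h,
                 groups = groups, animals_per_pool = as.integer(animals_per_pool),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Circadian simulation design\n")
  cat("  timepoints (ZT h):", paste(x$timepoints_h, collapse = ", "), "\n")
  cat("  cycle:", x$cycle_h, "h; groups:", paste(x$groups, collapse = ", "),
      "; animals/pool:", x$animals_per_pool, "; seed:", x$seed, "\n")
  invisible(x)
}

sim_categories <- c("arrhythmic_both", "rhythmic_unchanged", "phase_shifted",
                    "other_changed", "gained_in_B", "lost_in_B")

#' Default per-category fractions and phase model
#'
#' The default category mix (60% arrhythmic, 20% rhythmic-unchanged, 10%
#' phase-shifted by 12 h, 7% gained, 3% lost) and phase model (reference
#' rhythms concentrated around ZT20.5, gained rhythms strongly clustered at
#' ZT6, gains outnumbering losses) mirror a liver study design in which a
#' perturbation adds day-peaking rhythms and flips night-peaking genes to the
#' day.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_category_fractions <- function() {
  c(arrhythmic_both = 0.60, rhythmic_unchanged = 0.20, phase_shifted = 0.10,
    other_changed = 0.00, gained_in_B = 0.07, lost_in_B = 0.03)
}

#' @rdname default_category_fractions
#' @param base_mu_h,base_kappa Circular mean (ZT h) and von Mises
#'   concentration of peak phases for genes rhythmic in the reference group.
#' @param gained_mu_h,gained_kappa Mean and concentration for rhythms gained
#'   in the perturbed group.
#' @param shift_h Programmed phase shift (hours) for the phase_shifted
#'   category.
#' @export
default_phase_model <- function(base_mu_h = 20.5, base_kappa = 2,
                                gained_mu_h = 6, gained_kappa = 8,
                                shift_h = 12) {
  list(base_mu_h = base_mu_h, base_kappa = base_kappa,
       gained_mu_h = gained_mu_h, gained_kappa = gained_kappa,
       shift_h = shift_h)
}

# Largest-remainder apportionment of n among fractions (deterministic,
# ties broken in category order).
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- raw - counts
  left <- n - sum(counts)
  if (left > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

#' Generate per-gene ground truth for a two-group circadian simulation
#'
#' Assigns each gene a differential-rhythmicity category and cosinor
#' parameters (mesor, relative amplitude, peak phase) for the reference group
#' A and the perturbed group B. Category counts follow the requested
#' fractions exactly via largest-remainder rounding. Phases are drawn from
#' von Mises distributions: reference rhythms around `base_mu_h`, gained
#' rhythms around `gained_mu_h`; phase-shifted genes carry a programmed
#' circular shift of `shift_h` in group B.
#'
#' @param n_genes Number of genes (>= 1).
#' @param fractions Named fractions over the categories
#'   `arrhythmic_both, rhythmic_unchanged, phase_shifted, other_changed,
#'   gained_in_B, lost_in_B`; must sum to 1.
#' @param phase_model See [default_phase_model()].
#' @param rel_amplitude Relative amplitude A of rhythmic genes (peak =
#'   mesor*(1+A), trough = mesor*(1-A)); must be in [0, 1].
#' @param noise_cv Coefficient of variation of per-animal noise.
#' @param mesor_meanlog,mesor_sdlog Log-normal parameters for per-gene mesors
#'   (abundance units).
#' @param groups Two group labels (reference first).
#' @param seed Integer seed; per-gene substreams make the truth for gene i
#'   independent of n_genes.
#' @return A data.frame of class `gene_truth` with one row per gene:
#'   gene_id, category, per-group mesor/rel_amplitude/phase_h, noise_cv.
#' @export
generate_truth <- function(n_genes,
                           fractions = default_category_fractions(),
                           phase_model = default_phase_model(),
                           rel_amplitude = 0.5, noise_cv = 0.1,
                           mesor_meanlog = log(100), mesor_sdlog = 1,
                           groups = c("WT", "KO"), seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(groups) != 2) stop("truth generation needs exactly 2 groups")
  unknown <- setdiff(names(fractions), sim_categories)
  if (length(unknown)) stop("unknown categories: ", paste(unknown, collapse = ", "))
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named by category")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (rel_amplitude < 0 || rel_amplitude > 1) stop("rel_amplitude must be in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")

  frac <- setNames(numeric(length(sim_categories)), sim_categories)
  frac[names(fractions)] <- fractions
  counts <- largest_remainder(n_genes, frac)
  category <- rep(sim_categories, counts)

  pm <- phase_model
  n <- n_genes
  mesor <- numeric(n); phA <- numeric(n); phB <- numeric(n)
  ampA <- numeric(n); ampB <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(seed, i, stage = 1L), {
      mesor[i] <- rlnorm(1, mesor_meanlog, mesor_sdlog)
      base_ph <- rvonmises_h(1, pm$base_mu_h, pm$base_kappa)
      gain_ph <- rvonmises_h(1, pm$gained_mu_h, pm$gained_kappa)
      unif_ph <- runif(1, 0, 24)
      switch(category[i],
        arrhythmic_both = {
          ampA[i] <- 0; ampB[i] <- 0; phA[i] <- unif_ph; phB[i] <- unif_ph
        },
        rhythmic_unchanged = {
          ampA[i] <- rel_amplitude; ampB[i] <- rel_amplitude
          phA[i] <- base_ph; phB[i] <- base_ph
        },
        phase_shifted = {
          ampA[i] <- rel_amplitude; ampB[i] <- rel_amplitude
          phA[i] <- base_ph; phB[i] <- (base_ph + pm$shift_h) %% 24
        },
        other_changed = {
          ampA[i] <- rel_amplitude; ampB[i] <- rel_amplitude / 2
          phA[i] <- base_ph; phB[i] <- base_ph
        },
        gained_in_B = {
          ampA[i] <- 0; ampB[i] <- rel_amplitude
          phA[i] <- gain_ph; phB[i] <- gain_ph
        },
        lost_in_B = {
          ampA[i] <- rel_amplitude; ampB[i] <- 0
          phA[i] <- base_ph; phB[i] <- base_ph
        })
    })
  }
  truth <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                      category = category, stringsAsFactors = FALSE)
  truth[[paste0("mesor_", groups[1])]] <- mesor
  truth[[paste0("mesor_", groups[2])]] <- mesor
  truth[[paste0("rel_amplitude_", groups[1])]] <- ampA
  truth[[paste0("rel_amplitude_", groups[2])]] <- ampB
  truth[[paste0("phase_h_", groups[1])]] <- phA
  truth[[paste0("phase_h_", groups[2])]] <- phB
  truth$noise_cv <- noise_cv
  attr(truth, "groups") <- groups
  class(truth) <- c("gene_truth", "data.frame")
  truth
}

#' Noise-free cosinor expression profile
#'
#' Single-harmonic waveform `m * (1 + A * cos(2*pi*(t - phi)/cycle_h))`:
#' mesor m, relative amplitude A (so peak/trough = (1+A)/(1-A)) and peak at
#' t = phi (mod cycle_h), matching the lag-as-peak-time convention of the
#' rhythm detector.
#'
#' @param mesor Mesor (abundance units, > 0).
#' @param rel_amplitude Relative amplitude in [0, 1]; A > 1 would imply
#'   negative abundance and is rejected.
#' @param phase_h Peak time in hours.
#' @param t_h Time(s) in hours (>= 0).
#' @param cycle_h Cycle length (default 24).
#' @return Expected abundance at `t_h` (vectorised over `t_h`).
#' @export
expression_profile <- function(mesor, rel_amplitude, phase_h, t_h,
                               cycle_h = 24) {
  if (any(t_h < 0)) stop("t_h must be >= 0")
  if (rel_amplitude > 1) stop("rel_amplitude > 1 would imply negative abundance")
  if (rel_amplitude < 0) stop("rel_amplitude must be >= 0")
  mesor * (1 + rel_amplitude * cos(2 * pi * (t_h - phase_h) / cycle_h))
}

#' Simulate a pooled circadian expression dataset from ground truth
#'
#' For every gene, group and timepoint, draws `animals_per_pool` independent
#' noisy per-animal abundances around the gene's cosinor profile and records
#' their arithmetic mean (equal-mass RNA pooling behaves as averaging). Two
#' noise models are provided: `lognormal_cv` (multiplicative log-normal noise
#' with the gene's `noise_cv`, mean-preserving) and
#' `negative_binomial_dispersion` (integer counts with variance
#' mu + dispersion * mu^2).
#'
#' @param design A [sim_design()].
#' @param truth A `gene_truth` table from [generate_truth()].
#' @param noise_model `"lognormal_cv"` or `"negative_binomial_dispersion"`.
#' @param dispersion Negative-binomial dispersion (used by the NB model only).
#' @return A list of class `synthetic_dataset` with elements `table` (an
#'   [expression_table()]), `truth`, and `design`.
#' @export
simulate_dataset <- function(design, truth,
                             noise_model = c("lognormal_cv",
                                             "negative_binomial_dispersion"),
                             dispersion = 0.05) {
  noise_model <- match.arg(noise_model)
  if (!inherits(truth, "gene_truth") || nrow(truth) == 0) {
    stop("truth must be a non-empty gene_truth table")
  }
  if (noise_model == "negative_binomial_dispersion" && dispersion <= 0) {
    stop("dispersion must be > 0")
  }
  groups <- attr(truth, "groups")
  if (!all(groups %in% design$groups)) {
    stop("truth groups must be present in the design")
  }
  tp <- design$timepoints_h
  k <- design$animals_per_pool
  n <- nrow(truth)
  ncol_total <- length(groups) * length(tp)
  mat <- matrix(0, nrow = n, ncol = ncol_total)
  cn <- character(ncol_total)
  col <- 0L
  for (g in groups) {
    for (t in tp) {
      col <- col + 1L
      cn[col] <- sample_name(g, t)
    }
  }
  for (i in seq_len(n)) {
    cv <- truth$noise_cv[i]
    sdlog <- sqrt(log(1 + cv^2))
    row <- numeric(ncol_total)
    with_seed(substream_seed(design$seed, i, stage = 2L), {
      col <- 0L
      for (g in groups) {
        m <- truth[[paste0("mesor_", g)]][i]
        a <- truth[[paste0("rel_amplitude_", g)]][i]
        ph <- truth[[paste0("phase_h_", g)]][i]
        mu <- expression_profile(m, a, ph, tp, design$cycle_h)
        for (j in seq_along(tp)) {
          col <- col + 1L
          animals <- switch(noise_model,
            lognormal_cv =
              mu[j] * exp(rnorm(k, mean = -sdlog^2 / 2, sd = sdlog)),
            negative_binomial_dispersion =
              rnbinom(k, mu = mu[j], size = 1 / dispersion))
          row[col] <- mean(animals)
        }
      }
    })
    mat[i, ] <- row
  }
  rownames(mat) <- truth$gene_id
  colnames(mat) <- cn
  kind <- if (noise_model == "negative_binomial_dispersion") "counts" else "abundance"
  structure(list(table = expression_table(mat, kind = kind),
                 truth = truth, design = design),
            class = "synthetic_dataset")
}

sample_name <- function(group, zt_h) {
  zt <- if (abs(zt_h - round(zt_h)) < 1e-9) sprintf("%02d", as.integer(round(zt_h)))
        else format(zt_h)
  paste0(group, "_ZT", zt)
}

#' Write a synthetic dataset to TSV files
#'
#' Writes `expression.tsv` (first column `gene_id`, remaining columns named
#' `<GROUP>_ZT<hh>`) and `truth.tsv` (gene_id, category, per-group
#' mesor/rel_amplitude/phase_h, noise_cv) into `dir`.
#'
#' @param ds A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_expression(ds$table, expr_path)
  truth <- as.data.frame(ds$truth)
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, truth = truth_path))
}

#' Read a ground-truth TSV written by [write_dataset()]
#' @param path Path to truth.tsv.
#' @return A `gene_truth` data.frame.
#' @export
read_truth <- function(path) {
  truth <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  grp_cols <- grep("^mesor_", names(truth), value = TRUE)
  attr(truth, "groups") <- sub("^mesor_", "", grp_cols)
  class(truth) <- c("gene_truth", "data.frame")
  truth
}
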