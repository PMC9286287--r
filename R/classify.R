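# Decision-table classifier for differential rhythmicity. The rules are
# data, not code: each row holds threshold predicates on the two groups'
# rhythm adjusted p-values, the meta p of the difference test, and the
# circular phase difference; the first matching row assigns the category and
# a terminal catch-all assigns "unclassified" (the printed criteria are not
# exhaustive: both groups arrhythmic, or adjusted p in the (0.05, 0.1]
# boundary zone, match no row).

#' Circular difference between two peak phases
#'
#' `min(|d|, cycle - |d|)` with `d = phi1 - phi2` reduced modulo the cycle;
#' symmetric, bounded by `cycle_h / 2`. NA phases (arrhythmic genes)
#' propagate to NA, and rules requiring a phase difference do not match.
#'
#' @param phi1_h,phi2_h Phases in hours (vectorised).
#' @param cycle_h Cycle length (default 24).
#' @return Difference in hours, in [0, cycle_h/2].
#' @export
circular_phase_diff <- function(phi1_h, phi2_h, cycle_h = 24) {
  d <- abs(phi1_h - phi2_h) %% cycle_h
  pmin(d, cycle_h - d)
}

op_match <- function(x, op, thr) {
  # strict inequalities, exactly as printed: "< 0.05" excludes 0.05
  switch(op,
         none = rep(TRUE, length(x)),
         lt = !is.na(x) & x < thr,
         gt = !is.na(x) & x > thr,
         stop("unknown predicate operator: ", op))
}

#' Default differential-rhythmicity rule table
#'
#' Builds the five-row decision table over (adjp_g1, adjp_g2, meta_p,
#' |phase difference|) plus the terminal `unclassified` catch-all. All
#' inequalities are strict. Two orientations of the meta-p predicates are
#' provided because the printed criteria pair "unchanged" with a small meta p
#' and the change categories with a large one, which is inconsistent with a
#' difference-detecting test whose small p-values indicate a difference:
#' \describe{
#'   \item{as_printed}{unchanged requires meta_p < `metap`; the
#'     other-difference, gained and lost rows require meta_p > `metap`.}
#'   \item{difference_consistent}{the meta-p inequalities are flipped so
#'     that every category implying a rhythm difference requires
#'     meta_p < `metap` and "unchanged" requires meta_p > `metap`.}
#' }
#' The phase-change row uses no meta-p predicate in either orientation, and
#' the gained/lost rows use no phase predicate (the arrhythmic group has no
#' defined phase).
#'
#' @param orientation `"as_printed"` or `"difference_consistent"`.
#' @param adjp1 Rhythm threshold for the primary group (default 0.05).
#' @param adjp2 Laxer rhythm threshold for the secondary group (default 0.1).
#' @param metap Meta-p threshold (default 0.01).
#' @param phase_h Phase-difference threshold in hours (default 6).
#' @return data.frame of class `rule_table`; rules apply first-match-wins.
#' @export
default_rule_table <- function(orientation = c("as_printed",
                                               "difference_consistent"),
                               adjp1 = 0.05, adjp2 = 0.1, metap = 0.01,
                               phase_h = 6) {
  orientation <- match.arg(orientation)
  stopifnot(adjp1 > 0, adjp1 < 1, adjp2 > 0, adjp2 < 1,
            metap > 0, metap < 1, phase_h > 0, phase_h <= 12)
  meta_unch <- if (orientation == "as_printed") "lt" else "gt"
  meta_diff <- if (orientation == "as_printed") "gt" else "lt"
  rules <- data.frame(
    category = c("rhythmic_both_unchanged", "rhythmic_both_phase_change",
                 "rhythmic_both_other_difference", "gained_in_g1_only",
                 "lost_in_g1"),
    p1_op = c("lt", "lt", "lt", "lt", "gt"),
    p1_thr = c(adjp1, adjp1, adjp1, adjp1, adjp2),
    p2_op = c("lt", "lt", "lt", "gt", "lt"),
    p2_thr = c(adjp2, adjp2, adjp2, adjp2, adjp1),
    meta_op = c(meta_unch, "none", meta_diff, meta_diff, meta_diff),
    meta_thr = metap,
    phase_op = c("lt", "gt", "lt", "none", "none"),
    phase_thr = phase_h,
    stringsAsFactors = FALSE)
  attr(rules, "orientation") <- orientation
  class(rules) <- c("rule_table", "data.frame")
  rules
}

rule_matches <- function(rule, adjp_g1, adjp_g2, meta_p, phase_diff_h) {
  op_match(adjp_g1, rule$p1_op, rule$p1_thr) &
    op_match(adjp_g2, rule$p2_op, rule$p2_thr) &
    op_match(meta_p, rule$meta_op, rule$meta_thr) &
    op_match(phase_diff_h, rule$phase_op, rule$phase_thr)
}

#' Classify one gene's statistics
#'
#' @param stats Named list or one-row data.frame with `adjp_g1`, `adjp_g2`,
#'   `meta_p`, and either `phase_diff_h` or both `phase_g1_h`/`phase_g2_h`.
#' @param rules A [default_rule_table()] (or a customised rule table).
#' @return List with `category` and `matched_rule` (index into the table;
#'   0 for the catch-all `unclassified`).
#' @export
classify_gene <- function(stats, rules = default_rule_table()) {
  pd <- if (!is.null(stats$phase_diff_h)) stats$phase_diff_h
        else circular_phase_diff(stats$phase_g1_h, stats$phase_g2_h)
  for (r in seq_len(nrow(rules))) {
    if (rule_matches(rules[r, ], stats$adjp_g1, stats$adjp_g2,
                     stats$meta_p, pd)) {
      return(list(category = rules$category[r], matched_rule = r))
    }
  }
  list(category = "unclassified", matched_rule = 0L)
}

#' Classify all genes and tally categories
#'
#' Applies the rule table first-match-wins to every row of a joined
#' statistics table; every gene receives exactly one category (the counts
#' partition the input).
#'
#' @param stats_table data.frame with columns gene_id, adjp_g1, adjp_g2,
#'   meta_p, phase_g1_h, phase_g2_h (phases may be NA when arrhythmic).
#' @param rules A rule table.
#' @return List with `classified` (input plus phase_diff_h, category,
#'   matched_rule) and `counts` (named integer vector over all categories
#'   incl. unclassified).
#' @export
classify_all <- function(stats_table, rules = default_rule_table()) {
  if (anyDuplicated(stats_table$gene_id)) stop("duplicate gene_ids")
  pd <- circular_phase_diff(stats_table$phase_g1_h, stats_table$phase_g2_h)
  n <- nrow(stats_table)
  category <- rep("unclassified", n)
  matched <- integer(n)
  open <- rep(TRUE, n)
  for (r in seq_len(nrow(rules))) {
    hit <- open & rule_matches(rules[r, ], stats_table$adjp_g1,
                               stats_table$adjp_g2, stats_table$meta_p, pd)
    category[hit] <- rules$category[r]
    matched[hit] <- r
    open <- open & !hit
  }
  out <- stats_table
  out$phase_diff_h <- pd
  out$category <- category
  out$matched_rule <- matched
  lvl <- c(rules$category, "unclassified")
  counts <- table(factor(category, levels = lvl))
  list(classified = out, counts = setNames(as.integer(counts), lvl))
}

#' Join per-group rhythm results and difference tests into classifier input
#'
#' Merges two [detect_rhythms()] tables and one [compare_groups()] table by
#' gene_id. Group 1 is the primary group of the rule table (the perturbed
#' condition when comparing perturbed vs reference). A group's phase is set
#' to NA (undefined) when its rhythm adjusted p exceeds the laxer rhythm
#' threshold actually used by phase-dependent rules, i.e. phases are carried
#' only for genes detectably rhythmic in that group.
#'
#' @param rhythm_g1,rhythm_g2 Per-group results from [detect_rhythms()].
#' @param diff Results from [compare_groups()] run as (group 1, group 2).
#' @param p_column Which rhythm column feeds the classifier: the within-gene
#'   `"adj_p"` (default) or the across-genes `"q_bh"`.
#' @return data.frame with gene_id, adjp_g1, adjp_g2, meta_p, phase_g1_h,
#'   phase_g2_h.
#' @export
build_gene_stats <- function(rhythm_g1, rhythm_g2, diff,
                             p_column = c("adj_p", "q_bh")) {
  p_column <- match.arg(p_column)
  stopifnot(identical(rhythm_g1$gene_id, rhythm_g2$gene_id),
            identical(rhythm_g1$gene_id, diff$gene_id))
  data.frame(gene_id = rhythm_g1$gene_id,
             adjp_g1 = rhythm_g1[[p_column]],
             adjp_g2 = rhythm_g2[[p_column]],
             meta_p = diff$meta_p,
             phase_g1_h = rhythm_g1$lag_h,
             phase_g2_h = rhythm_g2$lag_h,
             stringsAsFactors = FALSE)
}
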