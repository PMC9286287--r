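# Expression-table container and TSV I/O. Sample columns follow the
# <GROUP>_ZT<hh> convention (group labels may themselves contain
# underscores, e.g. F_KO_ZT06 -> group "F_KO", ZT 6).

#' Gene-by-sample expression table
#'
#' Lightweight container pairing an abundance (or count) matrix with
#' per-sample metadata parsed from the column names.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns named `<GROUP>_ZT<hh>`.
#' @param kind `"abundance"` (FPKM-like, used for rhythm analyses) or
#'   `"counts"` (raw counts, used for low-count filtering).
#' @return Object of class `expression_table` with elements `expr`,
#'   `samples` (sample, group, zt_h) and `kind`.
#' @export
expression_table <- function(expr, kind = c("abundance", "counts")) {
  kind <- match.arg(kind)
  if (is.null(rownames(expr))) stop("expr must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (!is.numeric(expr)) stop("expr must be numeric")
  samples <- parse_sample_names(colnames(expr))
  structure(list(expr = expr, samples = samples, kind = kind),
            class = "expression_table")
}

parse_sample_names <- function(nms) {
  if (is.null(nms)) stop("expression columns must be named <GROUP>_ZT<hh>")
  m <- regmatches(nms, regexec("^(.+)_ZT([0-9]+(?:\\.[0-9]+)?)$", nms))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("malformed sample name(s): ", paste(nms[bad], collapse = ", "))
  }
  group <- vapply(m, `[[`, character(1), 2)
  zt <- as.numeric(vapply(m, `[[`, character(1), 3))
  out_of_range <- zt < 0 | zt >= 24
  if (any(out_of_range)) {
    stop("ZT out of [0, 24) in sample name(s): ",
         paste(nms[out_of_range], collapse = ", "))
  }
  data.frame(sample = nms, group = group, zt_h = zt,
             stringsAsFactors = FALSE)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table (%s): %d genes x %d samples, groups: %s\n",
              x$kind, nrow(x$expr), ncol(x$expr),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Read an expression TSV
#'
#' Tab-delimited, UTF-8, `.` decimal; first column `gene_id`, remaining
#' columns named `<GROUP>_ZT<hh>`. Duplicate gene ids, non-numeric cells and
#' unparseable headers are rejected with the offending column named.
#'
#' @param path File path.
#' @param kind `"abundance"` or `"counts"`.
#' @return An [expression_table()].
#' @export
read_expression <- function(path, kind = c("abundance", "counts")) {
  kind <- match.arg(kind)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "))
  }
  rownames(mat) <- ids
  expression_table(mat, kind = kind)
}

#' Write an expression table to TSV
#' @param et An [expression_table()].
#' @param path Output path.
#' @export
write_expression <- function(et, path) {
  stopifnot(inherits(et, "expression_table"))
  df <- data.frame(gene_id = rownames(et$expr), et$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Low-count gene filter
#'
#' Removes genes whose raw-count sum across ALL samples (every timepoint of
#' every group) is strictly less than `min_total` (default 100); a sum of
#' exactly `min_total` is retained. Only meaningful for count tables; an
#' abundance table is rejected. Idempotent.
#'
#' @param et An [expression_table()] of kind `"counts"`.
#' @param min_total Threshold on the total raw count (default 100).
#' @return List: `table` (filtered expression_table), `n_removed`.
#' @export
low_count_filter <- function(et, min_total = 100) {
  stopifnot(inherits(et, "expression_table"))
  if (et$kind != "counts") stop("low-count filtering applies to count tables")
  keep <- rowSums(et$expr) >= min_total
  list(table = expression_table(et$expr[keep, , drop = FALSE], kind = "counts"),
       n_removed = sum(!keep))
}

#' Relative quantification by the 2^-ddCt method
#'
#' `fold = 2^-((ct_target - ct_reference) - (ct_target_calibrator -
#' ct_reference_calibrator))`: target Ct values are normalised to a reference
#' gene and expressed relative to a calibrator condition.
#'
#' @param ct_target,ct_reference Sample Ct values (target and reference
#'   gene).
#' @param ct_target_calibrator,ct_reference_calibrator Calibrator Ct values.
#' @return Fold change (vectorised).
#' @export
ddct_fold_change <- function(ct_target, ct_reference,
                             ct_target_calibrator, ct_reference_calibrator) {
  args <- c(ct_target, ct_reference, ct_target_calibrator,
            ct_reference_calibrator)
  if (any(!is.finite(args))) stop("Ct values must be finite")
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
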