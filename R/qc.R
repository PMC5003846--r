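#' Screen sorted samples for effector-cell contamination via marker genes
#'
#' Sorted tumor-cell samples from a co-culture can carry over contaminating
#' T cells; their presence shows up as CD3/CD8 marker counts above the panel
#' background. The background threshold is estimated from the
#' negative-control probes after putting them on the normalized scale
#' (each sample's negatives are multiplied by `2^(-d_j)` with `d_j` that
#' sample's normalization shift): `B = mean + bg_k * SD` of the pooled
#' normalized negative-control counts. A marker in a sample is flagged iff
#' its normalized linear count exceeds `B`; marker values that are missing
#' (at or below the subtracted background) count as zero and pass.
#'
#' @param norm A [normalize_counts()] result.
#' @param run The [panel_run()] that produced `norm` (source of the
#'   negative-control counts).
#' @param markers Marker gene names; default [CTL_MARKERS].
#' @param bg_k Number of SDs above the mean background. Default 2.
#' @return Object of class `qc_report`: data.frame with columns `sample`,
#'   `marker`, `count`, `verdict` (`"pass"`/`"flag"`), with attributes
#'   `threshold` (B) and `flagged` (named list: flagged sample -> offending
#'   markers).
#' @export
contamination_check <- function(norm, run, markers = CTL_MARKERS,
                                bg_k = 2) {
  stopifnot(inherits(norm, "normalization_result"),
            inherits(run, "panel_run"))
  absent <- setdiff(markers, rownames(norm$linear_values))
  if (length(absent))
    stop("marker(s) absent from panel: ", paste(absent, collapse = ", "))

  neg <- run$counts[run$probe_class == "negative", , drop = FALSE]
  neg_norm <- sweep(neg, 2, 2 ^ (-norm$sample_shift), `*`)
  B <- mean(neg_norm) + bg_k * stats::sd(neg_norm)
  if (!is.finite(B)) B <- mean(neg_norm)  # single negative probe x sample

  cnt <- norm$linear_values[markers, , drop = FALSE]
  cnt[is.na(cnt)] <- 0
  long <- data.frame(
    sample = rep(colnames(cnt), each = nrow(cnt)),
    marker = rep(rownames(cnt), times = ncol(cnt)),
    count = as.vector(cnt),
    verdict = ifelse(as.vector(cnt) > B, "flag", "pass"),
    stringsAsFactors = FALSE)
  flagged <- split(long$marker[long$verdict == "flag"],
                   long$sample[long$verdict == "flag"])
  structure(long, class = c("qc_report", "data.frame"),
            threshold = B, flagged = flagged)
}

#' Cross-platform fold-change concordance
#'
#' Compares per-gene log2 fold-changes measured on two platforms (e.g. a
#' genome-wide microarray versus a targeted count panel) over their shared
#' genes: Pearson correlation and the compression slope, the ordinary
#' least-squares slope of platform-a logFC regressed on platform-b logFC. A
#' slope below 1 means platform a compresses (systematically underestimates)
#' the fold-changes relative to platform b. A per-cell-line breakdown is
#' computed whenever the two tables share cell-line labels.
#'
#' @param fc_a,fc_b [fold_change_table()] objects.
#' @param genes Optional gene subset; default: all shared genes with finite
#'   mean logFC on both platforms (at least 3 required).
#' @return List with `pearson_r`, `compression_slope`, `n_genes`, and
#'   `per_cell_line` (data.frame, possibly 0 rows).
#' @export
compare_platforms <- function(fc_a, fc_b, genes = NULL) {
  stopifnot(inherits(fc_a, "fold_change_table"),
            inherits(fc_b, "fold_change_table"))
  shared <- genes %||% intersect(names(fc_a$mean_logfc),
                                 names(fc_b$mean_logfc))
  a <- fc_a$mean_logfc[shared]
  b <- fc_b$mean_logfc[shared]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop("need at least 3 shared genes with finite fold-changes, got ",
         length(a))
  r <- stats::cor(a, b)
  slope <- stats::cov(a, b) / stats::var(b)

  per_line <- data.frame(cell_line = character(0), pearson_r = numeric(0),
                         compression_slope = numeric(0),
                         n_genes = integer(0))
  shared_lines <- intersect(colnames(fc_a$logfc), colnames(fc_b$logfc))
  for (cl in shared_lines) {
    av <- fc_a$logfc[shared[ok], cl]
    bv <- fc_b$logfc[shared[ok], cl]
    okl <- is.finite(av) & is.finite(bv)
    if (sum(okl) >= 3L)
      per_line <- rbind(per_line, data.frame(
        cell_line = cl,
        pearson_r = stats::cor(av[okl], bv[okl]),
        compression_slope = stats::cov(av[okl], bv[okl]) /
          stats::var(bv[okl]),
        n_genes = sum(okl)))
  }
  list(pearson_r = unname(r), compression_slope = unname(slope),
       n_genes = length(a), per_cell_line = per_line)
}
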