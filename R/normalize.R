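#' Subtract negative-control background from raw counts
#'
#' For every sample the arithmetic mean of its negative-control probes is
#' taken as the background estimate \eqn{b_j} and subtracted from the counts
#' of all endogenous and housekeeping probes. Corrected values may be zero or
#' negative; they are carried forward and masked later at the log step, not
#' truncated here.
#'
#' @param run A [panel_run()] with at least one negative-control probe.
#' @param pooled If `TRUE`, a single background (the mean over all
#'   negative-control counts of all samples) is subtracted everywhere instead
#'   of per-sample means.
#' @return List with `corrected` (endogenous + housekeeping probes x samples)
#'   and `background` (one value per sample, count units).
#' @export
#'
#' @examples
#' cnt <- rbind(ACTB = c(110, 50), NEG_A = c(8, 8), NEG_B = c(12, 12))
#' colnames(cnt) <- c("s1", "s2")
#' run <- panel_run(cnt, c("endogenous", "negative", "negative"),
#'                  c("untreated", "treated"))
#' subtract_background(run)$corrected["ACTB", ]  # 100, 40
subtract_background <- function(run, pooled = FALSE) {
  stopifnot(inherits(run, "panel_run"))
  neg <- run$counts[run$probe_class == "negative", , drop = FALSE]
  b <- if (pooled) rep(mean(neg), ncol(neg)) else colMeans(neg)
  names(b) <- colnames(run$counts)
  keep <- run$probe_class %in% c("endogenous", "housekeeping")
  corrected <- sweep(run$counts[keep, , drop = FALSE], 2, b, `-`)
  list(corrected = corrected, background = b)
}

#' Log2-transform background-corrected counts, masking undefined values
#'
#' Values \eqn{\le 0} (zero counts, or counts at or below the subtracted
#' background) have no defined logarithm and become missing (`NA`); positive
#' values become `log2(value)`. Entries already missing stay missing, so the
#' missing mask can only grow through the pipeline.
#'
#' @param corrected Numeric matrix of background-corrected counts.
#' @return Matrix of the same shape on log2 scale with `NA` where undefined.
#' @export
log2_with_na <- function(corrected) {
  out <- corrected
  undef <- is.na(corrected) | corrected <= 0
  out[undef] <- NA_real_
  out[!undef] <- log2(corrected[!undef])
  out
}

#' Reference-gene shift normalization of a log2 count matrix
#'
#' Computes, for each sample, the additive log2 offset that best aligns the
#' reference genes with their cross-sample means: with \eqn{m_g} the mean of
#' reference gene \eqn{g} over the samples where it is defined, the shift is
#' \eqn{d_j = \mathrm{mean}_g (x_{gj} - m_g)} over the reference genes defined
#' in sample \eqn{j}. This is the closed-form least-squares solution of the
#' per-sample shift model \eqn{x_{gj} \approx m_g + d_j} ("simple regression
#' with the mean as offset"). The shift is then subtracted from all probes of
#' that sample.
#'
#' @param log_values Log2 matrix (genes x samples), `NA` allowed.
#' @param refgenes Character vector of reference gene names; each must be
#'   present and defined in at least one sample.
#' @return List with `log_values` (shifted matrix), `sample_shift` (`d_j`,
#'   log2 units, one per sample), `refgene_means` (`m_g`) and
#'   `refgenes_used`.
#' @export
#'
#' @examples
#' x <- rbind(A = c(5, 7), B = c(6, 8))
#' colnames(x) <- c("s1", "s2")
#' refgene_shift(x, c("A", "B"))$sample_shift  # -0.5, 0.5
refgene_shift <- function(log_values, refgenes) {
  refgenes <- as.character(refgenes)
  missing_genes <- setdiff(refgenes, rownames(log_values))
  if (length(missing_genes))
    stop("reference gene(s) absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  ref <- log_values[refgenes, , drop = FALSE]
  never <- rowSums(!is.na(ref)) == 0
  if (any(never))
    stop("reference gene(s) undefined in every sample: ",
         paste(refgenes[never], collapse = ", "))
  m <- rowMeans(ref, na.rm = TRUE)
  resid <- sweep(ref, 1, m, `-`)
  usable <- colSums(!is.na(resid)) > 0
  if (!all(usable))
    stop("all reference genes missing in sample(s): ",
         paste(colnames(log_values)[!usable], collapse = ", "))
  d <- colMeans(resid, na.rm = TRUE)
  list(log_values = sweep(log_values, 2, d, `-`),
       sample_shift = d, refgene_means = m,
       refgenes_used = refgenes)
}

#' Full count normalization: background, log2, reference-gene shift
#'
#' Composes the three normalization steps in order: (1) subtract the mean
#' negative-control count from the raw counts, (2) log2-transform with
#' masking of undefined (\eqn{\le 0}) values, (3) align samples by the
#' reference-gene shift. Also back-transforms to normalized linear counts
#' (`2^log_values`), which downstream fold-change computation consumes.
#' Positive-control probes are carried in the input but take no part in
#' normalization.
#'
#' @param run A [panel_run()].
#' @param refgenes Reference (housekeeping) gene names to anchor the shift.
#' @param pooled_background Passed to [subtract_background()].
#' @return Object of class `normalization_result`: `log_values`,
#'   `linear_values` (= `2^log_values`), `sample_shift`, `background`,
#'   `refgenes_used`, `refgene_means`, plus the sample annotations of `run`.
#' @export
normalize_counts <- function(run, refgenes, pooled_background = FALSE) {
  bg <- subtract_background(run, pooled = pooled_background)
  logm <- log2_with_na(bg$corrected)
  sh <- refgene_shift(logm, refgenes)
  structure(
    list(log_values = sh$log_values,
         linear_values = 2 ^ sh$log_values,
         sample_shift = sh$sample_shift,
         background = bg$background,
         refgenes_used = sh$refgenes_used,
         refgene_means = sh$refgene_means,
         sample_condition = run$sample_condition,
         cell_line = run$cell_line),
    class = "normalization_result"
  )
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("normalization_result: ", nrow(x$log_values), " probes x ",
      ncol(x$log_values), " samples\n", sep = "")
  cat("  reference genes:", paste(x$refgenes_used, collapse = ", "), "\n")
  cat("  sample shifts (log2):",
      paste(sprintf("%.3f", x$sample_shift), collapse = ", "), "\n")
  invisible(x)
}

#' Write normalized values and per-sample shifts to TSV
#'
#' @param norm A [normalize_counts()] result.
#' @param path Output TSV of normalized log2 values (missing as empty cells).
#' @param shifts_path Optional TSV of per-sample shift and background.
#' @return `norm`, invisibly.
#' @export
write_normalization <- function(norm, path, shifts_path = NULL) {
  tab <- data.frame(gene = rownames(norm$log_values), norm$log_values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(shifts_path))
    utils::write.table(
      data.frame(sample_id = colnames(norm$log_values),
                 shift_log2 = unname(norm$sample_shift),
                 background = unname(norm$background)),
      shifts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(norm)
}
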