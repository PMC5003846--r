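#' Pseudocount-adjusted condition log2 fold-changes per cell line
#'
#' For every gene and cell line, the normalized linear counts are averaged
#' per condition (missing values, which arise from counts at or below
#' background, contribute as zero counts), a pseudocount \eqn{k} is added to
#' both condition means, and the log2 ratio treated/untreated is taken:
#' \deqn{\mathrm{logFC}_g = \log_2\frac{\bar{x}_{treated} + k}
#'                                     {\bar{x}_{untreated} + k}.}
#' The pseudocount damps fold-change blow-up for genes with very low
#' expression in the untreated condition. Adding \eqn{k} before or after
#' averaging is mathematically identical since the constant commutes with the
#' mean.
#'
#' @param x A [normalize_counts()] result, or a linear-scale numeric matrix
#'   (genes x samples) with `conditions` / `cell_lines` supplied.
#' @param treated,untreated Condition labels to contrast.
#' @param pseudocount Positive constant \eqn{k} added to the condition means
#'   (linear-count units); default 10.
#' @param conditions,cell_lines Per-sample labels when `x` is a plain matrix.
#' @return Object of class `fold_change_table`: `logfc` (genes x cell lines),
#'   `mean_logfc` (per-gene mean across cell lines), `pseudocount`,
#'   `n_treated` / `n_untreated` per cell line, and the contrast labels.
#' @export
#'
#' @examples
#' lin <- rbind(g1 = c(30, 30, 10, 10))
#' colnames(lin) <- paste0("s", 1:4)
#' fc <- condition_logfc(lin, "co", "un",
#'                       conditions = c("co", "co", "un", "un"))
#' fc$logfc  # 1.0 = log2(40 / 20)
condition_logfc <- function(x, treated, untreated, pseudocount = 10,
                            conditions = NULL, cell_lines = NULL) {
  if (inherits(x, "normalization_result")) {
    linear <- x$linear_values
    conditions <- x$sample_condition
    cell_lines <- x$cell_line
  } else {
    linear <- as.matrix(x)
    if (is.null(conditions))
      stop("conditions must be supplied for a plain matrix")
    cell_lines <- cell_lines %||% rep("all", ncol(linear))
  }
  k <- pseudocount
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("pseudocount must be a single positive number")
  if (!any(conditions == treated))
    stop("no samples with condition '", treated, "'")
  if (!any(conditions == untreated))
    stop("no samples with condition '", untreated, "'")

  lin0 <- linear
  lin0[is.na(lin0)] <- 0

  lines <- unique(cell_lines[conditions %in% c(treated, untreated)])
  logfc <- matrix(NA_real_, nrow(linear), length(lines),
                  dimnames = list(rownames(linear), lines))
  n_t <- n_u <- stats::setNames(integer(length(lines)), lines)
  for (cl in lines) {
    ti <- which(conditions == treated & cell_lines == cl)
    ui <- which(conditions == untreated & cell_lines == cl)
    if (!length(ti) || !length(ui))
      stop("cell line '", cl, "' lacks samples for one of the conditions")
    mt <- rowMeans(lin0[, ti, drop = FALSE])
    mu <- rowMeans(lin0[, ui, drop = FALSE])
    # difference of logs (identical in value to log2 of the ratio) keeps
    # the label-swap antisymmetry exact to the last bit
    logfc[, cl] <- log2(mt + k) - log2(mu + k)
    n_t[cl] <- length(ti); n_u[cl] <- length(ui)
  }
  fold_change_table(logfc, pseudocount = k, treated = treated,
                    untreated = untreated, n_treated = n_t,
                    n_untreated = n_u)
}

#' Assemble a fold-change table from a logFC matrix
#'
#' Container for per-gene, per-cell-line log2 fold-changes, used both by
#' [condition_logfc()] and when importing fold-changes computed on another
#' platform for concordance analysis.
#'
#' @param logfc Numeric matrix, genes x cell lines.
#' @param pseudocount Pseudocount recorded with the table.
#' @param treated,untreated Contrast labels.
#' @param n_treated,n_untreated Optional per-cell-line group sizes.
#' @return Object of class `fold_change_table`.
#' @export
fold_change_table <- function(logfc, pseudocount = NA_real_,
                              treated = "treated", untreated = "untreated",
                              n_treated = NULL, n_untreated = NULL) {
  logfc <- as.matrix(logfc)
  if (is.null(colnames(logfc)))
    colnames(logfc) <- paste0("line", seq_len(ncol(logfc)))
  structure(
    list(logfc = logfc,
         mean_logfc = rowMeans(logfc, na.rm = TRUE),
         pseudocount = pseudocount,
         treated = treated, untreated = untreated,
         n_treated = n_treated, n_untreated = n_untreated),
    class = "fold_change_table"
  )
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat("fold_change_table: ", nrow(x$logfc), " genes x ", ncol(x$logfc),
      " cell line(s); contrast ", x$treated, " vs ", x$untreated,
      ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Consensus fold-change filter across cell lines
#'
#' Calls a gene up-regulated if its log2 fold-change is at least
#' `log2(fold)` in **every** cell line, and down-regulated if it is at most
#' `-log2(fold)` in every cell line (the conservative consensus reading;
#' the default `fold = 4` is the fourfold filter). Alternative readings are
#' available: `mode = "any"` requires the threshold in at least one cell
#' line; `mode = "average"` applies it to the cross-line mean fold-change.
#'
#' @param fc A [fold_change_table()].
#' @param fold Fold threshold, > 1. Default 4.
#' @param mode `"consensus"` (default), `"any"` or `"average"`.
#' @return List with gene-name vectors `up` and `down` (disjoint by
#'   construction), plus `fold` and `mode`.
#' @export
consensus_fourfold <- function(fc, fold = 4,
                               mode = c("consensus", "any", "average")) {
  stopifnot(inherits(fc, "fold_change_table"))
  mode <- match.arg(mode)
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1)
    stop("fold threshold must be > 1")
  thr <- log2(fold)
  lf <- fc$logfc
  up_mat <- !is.na(lf) & lf >= thr
  dn_mat <- !is.na(lf) & lf <= -thr
  complete <- rowSums(is.na(lf)) == 0
  up <- switch(mode,
    consensus = rownames(lf)[complete & rowSums(up_mat) == ncol(lf)],
    any = rownames(lf)[rowSums(up_mat) >= 1],
    average = names(fc$mean_logfc)[!is.na(fc$mean_logfc) &
                                     fc$mean_logfc >= thr])
  down <- switch(mode,
    consensus = rownames(lf)[complete & rowSums(dn_mat) == ncol(lf)],
    any = rownames(lf)[rowSums(dn_mat) >= 1],
    average = names(fc$mean_logfc)[!is.na(fc$mean_logfc) &
                                     fc$mean_logfc <= -thr])
  list(up = up, down = down, fold = fold, mode = mode)
}

#' Summarise the per-cell-line distribution of log fold-changes
#'
#' Kernel-density summary and deciles of the log2 fold-changes for each cell
#' line, the standard first look at a screen ("distribution of all log
#' fold-changes between the treated and untreated condition").
#'
#' @param fc A [fold_change_table()] with at least 10 genes.
#' @param path Optional TSV to which the decile table is written.
#' @return List with `deciles` (data.frame: cell_line, probs 0..1 by 0.1) and
#'   `density` (per cell line, data.frame of x/y from [stats::density()]).
#' @export
logfc_distribution <- function(fc, path = NULL) {
  stopifnot(inherits(fc, "fold_change_table"))
  if (nrow(fc$logfc) < 10L)
    stop("need at least 10 genes to summarise a fold-change distribution")
  probs <- seq(0, 1, by = 0.1)
  dec <- lapply(colnames(fc$logfc), function(cl) {
    x <- fc$logfc[, cl]
    data.frame(cell_line = cl, prob = probs,
               logfc = unname(stats::quantile(x, probs, na.rm = TRUE)))
  })
  dec <- do.call(rbind, dec)
  dens <- lapply(colnames(fc$logfc), function(cl) {
    d <- stats::density(fc$logfc[, cl], na.rm = TRUE)
    data.frame(x = d$x, y = d$y)
  })
  names(dens) <- colnames(fc$logfc)
  if (!is.null(path))
    utils::write.table(dec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(deciles = dec, density = dens)
}

#' Write a fold-change table to TSV
#'
#' @param fc A [fold_change_table()].
#' @param path Output TSV (gene, one column per cell line, mean_logfc).
#' @return `fc`, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  tab <- data.frame(gene = rownames(fc$logfc), fc$logfc,
                    mean_logfc = unname(fc$mean_logfc),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fc)
}
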