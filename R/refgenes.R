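#' Screen a genome-wide expression matrix for stably expressed genes
#'
#' Computes, for every gene, the standard deviation (denominator n-1) of its
#' log2 expression over all non-missing samples, pooling all conditions and
#' cell lines, and flags genes with SD strictly below the threshold as
#' stable. Genes observed in fewer than 2 samples, or with more than
#' `max_missing` fraction missing, are excluded and listed with a reason.
#'
#' @param expr An [expression_matrix()] (log2 scale).
#' @param threshold Stability threshold \eqn{\tau} in log2 SD units; a gene is
#'   stable iff `sd < threshold` (strict). Default 0.25.
#' @param max_missing Maximum tolerated fraction of missing values per gene.
#' @param per_group Optional: also report per-condition SDs (exploratory; the
#'   stability call itself always pools all samples).
#' @return Object of class `stability_report`: a data.frame with columns
#'   `gene`, `sd`, `mean_expr`, `n_obs`, `stable`, sorted by ascending SD
#'   (ties: descending mean expression, then gene name), with attributes
#'   `threshold` and `excluded` (data.frame gene/reason).
#' @export
#'
#' @examples
#' vals <- rbind(flat = rep(7.3, 4), wobbly = c(6, 7, 6, 7))
#' colnames(vals) <- paste0("s", 1:4)
#' expr <- expression_matrix(vals, rep("untreated", 4))
#' stability_screen(expr)
stability_screen <- function(expr, threshold = 0.25, max_missing = 0.5,
                             per_group = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  vals <- expr$values
  n_obs <- rowSums(!is.na(vals))
  frac_missing <- 1 - n_obs / ncol(vals)

  excl_few <- n_obs < 2L
  excl_miss <- !excl_few & frac_missing > max_missing
  excluded <- data.frame(
    gene = c(rownames(vals)[excl_few], rownames(vals)[excl_miss]),
    reason = c(rep("observed in fewer than 2 samples", sum(excl_few)),
               rep("missing fraction above limit", sum(excl_miss))),
    stringsAsFactors = FALSE)

  keep <- !(excl_few | excl_miss)
  sds <- apply(vals[keep, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  means <- rowMeans(vals[keep, , drop = FALSE], na.rm = TRUE)
  rep_df <- data.frame(gene = rownames(vals)[keep], sd = unname(sds),
                       mean_expr = unname(means),
                       n_obs = unname(n_obs[keep]),
                       stable = unname(sds) < threshold,
                       stringsAsFactors = FALSE)
  ord <- order(rep_df$sd, -rep_df$mean_expr, rep_df$gene)
  rep_df <- rep_df[ord, , drop = FALSE]
  rownames(rep_df) <- NULL

  if (per_group) {
    groups <- unique(expr$sample_condition)
    for (g in groups) {
      cols <- which(expr$sample_condition == g)
      sdg <- apply(vals[keep, cols, drop = FALSE], 1, stats::sd,
                   na.rm = TRUE)
      rep_df[[paste0("sd_", g)]] <- unname(sdg)[ord]
    }
  }

  structure(rep_df, class = c("stability_report", "data.frame"),
            threshold = threshold, excluded = excluded)
}

#' Screen reference-gene candidates for sufficient panel expression
#'
#' A candidate gene is only usable for normalization if it is actually
#' measurable on the count panel: it must be defined (above background) in
#' every sample and its median normalized linear count must reach the floor.
#' By default the floor is twice the pooled mean negative-control count,
#' tying "very low level of expression" to the measured noise floor.
#'
#' @param candidates Character vector of candidate gene names.
#' @param norm A [normalize_counts()] result containing the candidates.
#' @param floor Linear-count threshold; default `2 * mean(norm$background)`.
#' @return List with `usable`, `too_low` (gene-name vectors), the `floor`
#'   applied and `median_counts` per candidate.
#' @export
expression_screen <- function(candidates, norm, floor = NULL) {
  stopifnot(inherits(norm, "normalization_result"))
  candidates <- as.character(candidates)
  absent <- setdiff(candidates, rownames(norm$linear_values))
  if (length(absent))
    stop("candidate(s) absent from panel: ", paste(absent, collapse = ", "))
  floor <- floor %||% (2 * mean(norm$background))
  lin <- norm$linear_values[candidates, , drop = FALSE]
  med <- apply(lin, 1, function(x)
    if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
  any_missing <- rowSums(is.na(lin)) > 0
  too_low <- any_missing | is.na(med) | med < floor
  list(usable = candidates[!too_low], too_low = candidates[too_low],
       floor = floor, median_counts = med)
}

# proportional stratum allocation: every occupied stratum gets one target
# when the budget allows, the rest proportional with remainder to the
# densest strata, capped at stratum size
allocate_strata <- function(sizes, n) {
  k <- length(sizes)
  alloc <- integer(k)
  if (n >= k) {
    alloc <- pmin(sizes, 1L)
    n_left <- n - sum(alloc)
    prop <- floor(n_left * sizes / sum(sizes))
    alloc <- pmin(sizes, alloc + prop)
  }
  ord <- order(sizes, decreasing = TRUE)
  i <- 1L
  while (sum(alloc) < n) {
    s <- ord[(i - 1L) %% k + 1L]
    if (alloc[s] < sizes[s]) alloc[s] <- alloc[s] + 1L
    i <- i + 1L
    if (i > 10L * k * (max(sizes) + 1L)) break  # defensive; cannot trigger when n <= sum(sizes)
  }
  alloc
}

#' Design a measurement panel spanning expression and fold-change space
#'
#' Selects target genes by stratified sampling over the grid of (mean log2
#' expression x mean log2 fold-change) so the panel covers all expression
#' levels and degrees of differential expression, and selects normalization
#' genes from the stable, non-responding candidates (SD below `threshold`
#' and absolute mean log fold-change below `fc_cap`), spreading them across
#' expression quantile bins, highest expression first — i.e. genes spanning a
#' wide range of expression values but without changes between treated and
#' untreated cells.
#'
#' @param expr An [expression_matrix()].
#' @param fc A [fold_change_table()] computed on the same genes.
#' @param n_targets Number of target genes to select.
#' @param n_norm Number of normalization genes to select.
#' @param n_expr_bins,n_fc_bins Grid resolution for target stratification.
#' @param threshold Stability SD threshold for normalization candidates.
#' @param fc_cap Maximum absolute mean log2 fold-change for a normalization
#'   gene. Default 0.25.
#' @return Object of class `panel_design`: data.frame with columns `gene`,
#'   `role` (`"target"` / `"normalization"`), `expr_bin`, `fc_bin`,
#'   `mean_expr`, `mean_logfc`. Warns (and returns a partial design) when
#'   there are not enough stable candidates to fill `n_norm`.
#' @export
design_panel <- function(expr, fc, n_targets, n_norm,
                         n_expr_bins = 5, n_fc_bins = 5,
                         threshold = 0.25, fc_cap = 0.25) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(fc, "fold_change_table"))
  genes <- intersect(rownames(expr$values), names(fc$mean_logfc))
  genes <- genes[!is.na(fc$mean_logfc[genes])]
  if (n_targets + n_norm > length(genes))
    stop("requested ", n_targets + n_norm, " genes but only ",
         length(genes), " available")

  mean_expr <- rowMeans(expr$values[genes, , drop = FALSE], na.rm = TRUE)
  mean_fc <- fc$mean_logfc[genes]

  bin_index <- function(x, nb) {
    if (diff(range(x)) < 1e-12) return(rep(1L, length(x)))
    br <- seq(min(x), max(x), length.out = nb + 1L)
    br[1] <- br[1] - 1e-9; br[nb + 1L] <- br[nb + 1L] + 1e-9
    as.integer(cut(x, br, include.lowest = TRUE))
  }
  eb <- bin_index(mean_expr, n_expr_bins)
  fb <- bin_index(mean_fc, n_fc_bins)
  stratum <- paste(eb, fb, sep = ":")

  # normalization genes first: stable and flat
  stab <- stability_screen(expr, threshold = threshold)
  stable_genes <- stab$gene[stab$stable]
  cand <- intersect(stable_genes, genes[abs(mean_fc) < fc_cap])
  norm_sel <- character(0)
  if (length(cand)) {
    qb <- bin_index(mean_expr[cand], max(n_norm, 1L))
    for (b in sort(unique(qb))) {
      in_bin <- cand[qb == b]
      norm_sel <- c(norm_sel, in_bin[which.max(mean_expr[in_bin])])
      if (length(norm_sel) >= n_norm) break
    }
    if (length(norm_sel) < n_norm) {
      left <- setdiff(cand, norm_sel)
      left <- left[order(mean_expr[left], decreasing = TRUE)]
      norm_sel <- c(norm_sel, utils::head(left, n_norm - length(norm_sel)))
    }
  }
  if (length(norm_sel) < n_norm)
    warning("only ", length(norm_sel), " of ", n_norm,
            " normalization genes could be selected (shortfall ",
            n_norm - length(norm_sel), "): too few stable, flat candidates")

  # stratified target sampling over the remaining genes
  pool <- setdiff(genes, norm_sel)
  strata <- split(pool, stratum[match(pool, genes)])
  sizes <- lengths(strata)
  alloc <- allocate_strata(sizes, min(n_targets, length(pool)))
  target_sel <- unlist(mapply(function(gs, k) {
    if (k >= length(gs)) gs else sample(gs, k)
  }, strata, alloc, SIMPLIFY = FALSE), use.names = FALSE)

  sel <- c(target_sel, norm_sel)
  out <- data.frame(
    gene = sel,
    role = rep(c("target", "normalization"),
               c(length(target_sel), length(norm_sel))),
    expr_bin = eb[match(sel, genes)],
    fc_bin = fb[match(sel, genes)],
    mean_expr = unname(mean_expr[sel]),
    mean_logfc = unname(mean_fc[sel]),
    stringsAsFactors = FALSE)
  structure(out, class = c("panel_design", "data.frame"),
            n_expr_bins = n_expr_bins, n_fc_bins = n_fc_bins,
            fc_cap = fc_cap)
}
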