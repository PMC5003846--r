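#' Construct a PanelRun: raw targeted-panel counts with probe classes
#'
#' A `panel_run` holds the raw integer counts of a hybridization count panel
#' (genes x samples) together with the probe class of every gene and the
#' condition and cell-line annotation of every sample. It is the entry object
#' of the normalization pipeline.
#'
#' @param counts Numeric matrix of non-negative integer counts, genes in rows
#'   (rownames = gene names), samples in columns (colnames = sample ids).
#' @param probe_class Character vector, one of `"endogenous"`, `"negative"`,
#'   `"positive"`, `"housekeeping"` per gene (recycled names from `counts`
#'   rownames if unnamed).
#' @param sample_condition Character vector of condition labels, one per
#'   sample (e.g. `"untreated"`, `"MelanA-CTL"`, `"cytokines"`).
#' @param cell_line Character vector of cell-line labels, one per sample.
#'   Defaults to `"unspecified"`.
#'
#' @return An object of class `panel_run` with elements `counts`,
#'   `probe_class`, `sample_condition`, `cell_line`.
#' @export
#'
#' @examples
#' cnt <- rbind(GUSB = c(250L, 300L), NEG_A = c(4L, 6L))
#' colnames(cnt) <- c("s1", "s2")
#' run <- panel_run(cnt, c("endogenous", "negative"),
#'                  sample_condition = c("untreated", "treated"))
panel_run <- function(counts, probe_class, sample_condition,
                      cell_line = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene names: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("sample ids must be unique")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0))
    stop("counts must be non-negative")
  bad <- !is_whole(counts)
  if (any(bad))
    stop("non-integer count for probe(s): ",
         paste(unique(rownames(counts)[which(bad, arr.ind = TRUE)[, 1]]),
               collapse = ", "))
  storage.mode(counts) <- "double"
  counts <- round(counts)

  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts))
    stop("probe_class must have one entry per gene")
  unknown <- setdiff(unique(probe_class), PROBE_CLASSES)
  if (length(unknown))
    stop("unknown probe class: ", paste(unknown, collapse = ", "))
  names(probe_class) <- rownames(counts)
  if (!any(probe_class == "negative"))
    stop("panel must contain at least one negative-control probe")
  if (!any(probe_class == "endogenous"))
    stop("panel must contain at least one endogenous probe")

  sample_condition <- as.character(sample_condition)
  if (length(sample_condition) != ncol(counts))
    stop("sample_condition must have one label per sample")
  if (anyNA(sample_condition) || any(!nzchar(sample_condition)))
    stop("every sample needs a condition label")
  names(sample_condition) <- colnames(counts)

  cell_line <- as.character(cell_line %||% rep("unspecified", ncol(counts)))
  if (length(cell_line) == 1L) cell_line <- rep(cell_line, ncol(counts))
  if (length(cell_line) != ncol(counts))
    stop("cell_line must have one label per sample")
  names(cell_line) <- colnames(counts)

  structure(
    list(counts = counts, probe_class = probe_class,
         sample_condition = sample_condition, cell_line = cell_line),
    class = "panel_run"
  )
}

#' @export
print.panel_run <- function(x, ...) {
  cls <- table(factor(x$probe_class, levels = PROBE_CLASSES))
  cat("panel_run: ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  probe classes:",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  conditions:",
      paste(unique(x$sample_condition), collapse = ", "), "\n")
  invisible(x)
}

#' Construct an ExpressionMatrix: genome-wide log2 expression with annotations
#'
#' Holds an already-processed expression matrix on log2 scale (e.g. from a
#' whole-genome microarray), genes x samples, with per-sample condition and
#' cell-line labels. Missing entries are allowed (`NA`) and are never imputed.
#'
#' @param values Numeric matrix on log2 scale; `NA` marks missing entries.
#' @param sample_condition,cell_line Per-sample annotation, as in
#'   [panel_run()].
#'
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_condition, cell_line = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (ncol(values) < 2L)
    stop("an expression matrix needs at least 2 samples")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (any(is.infinite(values)))
    stop("values must be finite or missing (NA)")

  sample_condition <- as.character(sample_condition)
  if (length(sample_condition) != ncol(values))
    stop("sample_condition must have one label per sample")
  names(sample_condition) <- colnames(values)
  cell_line <- as.character(cell_line %||% rep("unspecified", ncol(values)))
  if (length(cell_line) == 1L) cell_line <- rep(cell_line, ncol(values))
  names(cell_line) <- colnames(values)

  structure(
    list(values = values, sample_condition = sample_condition,
         cell_line = cell_line),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (log2 scale), ", sum(is.na(x$values)),
      " missing entries\n", sep = "")
  invisible(x)
}
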