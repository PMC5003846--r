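#' Read a single-sample RCC file (nCounter instrument export)
#'
#' Parses the sectioned, comma-separated RCC dialect with sections delimited
#' by `<SectionName>` / `</SectionName>` lines and a `Code_Summary` table with
#' columns `CodeClass,Name,Accession,Count`. CodeClass strings map
#' case-insensitively: `Endogenous` (including suffixed `Endogenous1/2/3`
#' variants used by multi-codeset panels) to `endogenous`, `Negative` to
#' `negative`, `Positive` to `positive`, `Housekeeping` to `housekeeping`;
#' anything else is rejected loudly. Other dialects are rejected rather than
#' guessed at.
#'
#' @param path Path to an RCC file.
#' @return A single-sample fragment of class `rcc_sample`: a list with
#'   `sample_id` (the lane ID from `Lane_Attributes`, falling back to the file
#'   name), named `counts`, `probe_class` and `accession` vectors. Combine
#'   fragments into a [panel_run()] with [merge_runs()].
#' @seealso [merge_runs()], [read_count_table()]
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)

  section <- function(name) {
    open <- match(paste0("<", name, ">"), trimws(lines))
    close <- match(paste0("</", name, ">"), trimws(lines))
    if (is.na(open) || is.na(close) || close <= open) return(NULL)
    lines[(open + 1L):(close - 1L)]
  }

  for (required in c("Header", "Lane_Attributes", "Code_Summary"))
    if (is.null(section(required)))
      stop("RCC format error in ", basename(path), ": missing ",
           required, " section")

  lane <- section("Lane_Attributes")
  lane_kv <- do.call(rbind, strsplit(lane[nzchar(trimws(lane))], ","))
  id_row <- which(tolower(lane_kv[, 1]) == "id")
  sample_id <- if (length(id_row) && ncol(lane_kv) >= 2)
    paste0("lane_", lane_kv[id_row[1], 2])
  else sub("\\.rcc$", "", basename(path), ignore.case = TRUE)

  body <- section("Code_Summary")
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("RCC format error in ", basename(path),
         ": Code_Summary section is empty")
  header <- tolower(trimws(strsplit(body[1], ",")[[1]]))
  if (!identical(header[1:4], c("codeclass", "name", "accession", "count")))
    stop("RCC format error in ", basename(path),
         ": Code_Summary header must be CodeClass,Name,Accession,Count")

  fields <- strsplit(body[-1], ",")
  if (any(lengths(fields) < 4L))
    stop("RCC format error in ", basename(path),
         ": Code_Summary row with fewer than 4 fields")
  fields <- do.call(rbind, lapply(fields, `[`, 1:4))

  cls_raw <- tolower(trimws(fields[, 1]))
  cls <- rep(NA_character_, length(cls_raw))
  cls[grepl("^endogenous", cls_raw)] <- "endogenous"
  cls[cls_raw == "negative"] <- "negative"
  cls[cls_raw == "positive"] <- "positive"
  cls[cls_raw == "housekeeping"] <- "housekeeping"
  if (anyNA(cls))
    stop("RCC format error in ", basename(path), ": unknown CodeClass: ",
         paste(unique(fields[is.na(cls), 1]), collapse = ", "))

  cnt <- suppressWarnings(as.numeric(fields[, 4]))
  if (anyNA(cnt) || any(!is_whole(cnt)))
    stop("RCC format error in ", basename(path), ": non-integer count for ",
         paste(fields[is.na(cnt) | !is_whole(cnt), 2], collapse = ", "))

  genes <- trimws(fields[, 2])
  if (anyDuplicated(genes))
    stop("RCC format error in ", basename(path), ": duplicate probe name: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))

  structure(
    list(sample_id = sample_id,
         counts = stats::setNames(round(cnt), genes),
         probe_class = stats::setNames(cls, genes),
         accession = stats::setNames(trimws(fields[, 3]), genes)),
    class = "rcc_sample"
  )
}

#' Merge single-sample RCC fragments into a PanelRun
#'
#' All fragments must cover exactly the same probe set; a mismatch is an
#' error listing the symmetric difference of the gene lists, so a probe can
#' never be dropped silently.
#'
#' @param fragments List of `rcc_sample` objects from [read_rcc()].
#' @param annotations Optional data.frame with columns `sample_id`,
#'   `condition`, `cell_line`. Samples without annotation get condition
#'   `"unspecified"`.
#' @return A [panel_run()].
#' @export
merge_runs <- function(fragments, annotations = NULL) {
  if (!length(fragments)) stop("no fragments to merge")
  genes <- names(fragments[[1]]$counts)
  for (fr in fragments[-1]) {
    other <- names(fr$counts)
    if (!setequal(genes, other)) {
      diff <- union(setdiff(genes, other), setdiff(other, genes))
      stop("fragments measure different probe sets; symmetric difference: ",
           paste(sort(diff), collapse = ", "))
    }
  }
  ids <- vapply(fragments, `[[`, character(1), "sample_id")
  counts <- vapply(fragments, function(fr) fr$counts[genes], numeric(length(genes)))
  counts <- matrix(counts, nrow = length(genes),
                   dimnames = list(genes, ids))
  cond <- rep("unspecified", length(ids))
  cl <- rep("unspecified", length(ids))
  if (!is.null(annotations)) {
    idx <- match(ids, annotations$sample_id)
    cond[!is.na(idx)] <- annotations$condition[idx[!is.na(idx)]]
    cl[!is.na(idx)] <- annotations$cell_line[idx[!is.na(idx)]]
  }
  panel_run(counts, fragments[[1]]$probe_class[genes], cond, cl)
}

read_annotations <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "condition", "cell_line")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  ann
}

#' Read a plain count table plus sample annotations into a PanelRun
#'
#' The count table is a TSV with a `gene` column, a `probe_class` column and
#' one integer column per sample; the annotation file is a TSV with columns
#' `sample_id`, `condition`, `cell_line`. Row order is preserved.
#'
#' @param path Count table TSV.
#' @param annotations Annotation TSV path or a data.frame.
#' @return A [panel_run()].
#' @export
read_count_table <- function(path, annotations) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("gene", "probe_class") %in% names(tab)))
    stop("count table needs 'gene' and 'probe_class' columns")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene names: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  sample_cols <- setdiff(names(tab), c("gene", "probe_class"))
  if (!length(sample_cols)) stop("count table has no sample columns")
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(counts) <- tab$gene
  if (!is.numeric(counts) || anyNA(counts) || any(!is_whole(counts)))
    stop("non-integer count in table")

  ann <- if (is.data.frame(annotations)) annotations
         else read_annotations(annotations)
  idx <- match(sample_cols, ann$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from annotations: ",
         paste(sample_cols[is.na(idx)], collapse = ", "))
  panel_run(counts, tab$probe_class,
            ann$condition[idx], ann$cell_line[idx])
}

#' Write a PanelRun as a count table (and optionally its annotations)
#'
#' @param run A [panel_run()].
#' @param path Output TSV for the counts.
#' @param annotation_path Optional output TSV for the sample annotations.
#' @return `run`, invisibly.
#' @export
write_count_table <- function(run, path, annotation_path = NULL) {
  tab <- data.frame(gene = rownames(run$counts),
                    probe_class = unname(run$probe_class),
                    run$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(
      data.frame(sample_id = colnames(run$counts),
                 condition = unname(run$sample_condition),
                 cell_line = unname(run$cell_line)),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(run)
}

#' Read a processed log2 expression matrix with sample annotations
#'
#' TSV with a `gene` column and one column per sample; empty cells are read
#' as missing (`NA`) and are never imputed.
#'
#' @param path Expression TSV (log2 scale).
#' @param annotations Annotation TSV path or data.frame (`sample_id`,
#'   `condition`, `cell_line`); if `NULL`, labels default to `"unspecified"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotations = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!"gene" %in% names(tab))
    stop("expression table needs a 'gene' column")
  sample_cols <- setdiff(names(tab), "gene")
  if (length(sample_cols) < 2L)
    stop("an expression matrix needs at least 2 samples")
  values <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(values) <- tab$gene
  cond <- rep("unspecified", length(sample_cols))
  cl <- rep("unspecified", length(sample_cols))
  if (!is.null(annotations)) {
    ann <- if (is.data.frame(annotations)) annotations
           else read_annotations(annotations)
    idx <- match(sample_cols, ann$sample_id)
    if (anyNA(idx))
      stop("sample(s) missing from annotations: ",
           paste(sample_cols[is.na(idx)], collapse = ", "))
    cond <- ann$condition[idx]
    cl <- ann$cell_line[idx]
  }
  expression_matrix(values, cond, cl)
}

#' Write an ExpressionMatrix as TSV (missing entries as empty cells)
#'
#' @param expr An [expression_matrix()].
#' @param path Output TSV.
#' @param annotation_path Optional output TSV for sample annotations.
#' @return `expr`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, annotation_path = NULL) {
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(annotation_path))
    utils::write.table(
      data.frame(sample_id = colnames(expr$values),
                 condition = unname(expr$sample_condition),
                 cell_line = unname(expr$cell_line)),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}
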