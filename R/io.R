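#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' The expected layout is a header row of sample identifiers followed by one
#' row per gene, the first field being the gene identifier. Values are log2
#' intensities unless `log2_transform = TRUE`, in which case linear-scale
#' values are floored at 1 and log2-transformed on read.
#'
#' @param path Path to a TSV file.
#' @param log2_transform Logical; declare the file to be on linear scale and
#'   convert to log2 after flooring at 1. Default `FALSE` (values already log2).
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names, in file order.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene-id column and at least one sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene row %d, sample column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], sample_ids[bad[1L, 2L]]))
  }
  if (anyNA(num) || any(!is.finite(num))) stop("expression values must all be finite")
  dimnames(num) <- list(gene_ids, sample_ids)
  if (log2_transform) num <- log2(pmax(num, 1))
  num
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column,
#' sample ids in the header.
#'
#' @param x Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  check_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared invariant checks for the genes x samples matrix.
check_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in matrix")
  if (any(!is.finite(x))) stop("expression values must all be finite")
  invisible(x)
}

#' Read a sample-annotation table
#'
#' Expects tab-separated columns `sample_id`, `cell_line`, `condition`.
#' Condition tokens are matched case-insensitively onto the three design
#' levels `WT` (wild type), `VECTOR` (empty-vector control) and `OVEREXPR`
#' (overexpressing). When `matrix` is supplied the sample sets must agree
#' exactly.
#'
#' @param path Path to a TSV file.
#' @param matrix Optional expression matrix whose column names the annotation
#'   must match.
#' @return A data.frame with columns `sample_id`, `cell_line` and `condition`
#'   (factor with levels `WT`, `VECTOR`, `OVEREXPR`).
#' @export
read_sample_annotation <- function(path, matrix = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  ann <- df[, need]
  ann$condition <- normalize_condition(ann$condition)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample id(s) in annotation")
  if (!is.null(matrix)) check_annotation(matrix, ann)
  ann
}

condition_levels <- c("WT", "VECTOR", "OVEREXPR")

normalize_condition <- function(x) {
  up <- toupper(trimws(as.character(x)))
  bad <- setdiff(unique(up), condition_levels)
  if (length(bad)) {
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         "; accepted (case-insensitive): ", paste(condition_levels, collapse = ", "))
  }
  factor(up, levels = condition_levels)
}

# Annotation sample ids must match matrix sample ids exactly.
check_annotation <- function(x, ann) {
  a <- setdiff(colnames(x), ann$sample_id)
  b <- setdiff(ann$sample_id, colnames(x))
  if (length(a) || length(b)) {
    stop("sample sets differ between matrix and annotation; only in matrix: {",
         paste(a, collapse = ", "), "}; only in annotation: {",
         paste(b, collapse = ", "), "}")
  }
  invisible(TRUE)
}

#' Write a sample-annotation table
#' @param ann Annotation data.frame as returned by [read_sample_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann[, c("sample_id", "cell_line", "condition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of
#'   member gene ids, with a `description` attribute (named character vector)
#'   holding the per-set description fields. File order is preserved.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields (name, description, members...)")
  }
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set after parsing")
  names(sets) <- names_
  descr <- vapply(parts, `[[`, "", 2L)
  names(descr) <- names_
  structure(sets, description = descr, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param collection A `gene_set_collection` (or named list of character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descr <- attr(collection, "description")
  if (is.null(descr)) descr <- setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descr[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets;",
      "sizes", min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Write an over-representation result table
#'
#' Tab-separated with the fixed column order `rank`, `pathway`, `n_pathway`,
#' `n_overlap`, `p_value`, `adj_p` (plus the remaining diagnostic columns),
#' mirroring the usual ranked-pathway report layout.
#'
#' @param ora An `ora_result` from [run_ora()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(ora, path) {
  lead <- c("rank", "pathway", "n_pathway", "n_overlap", "p_value", "adj_p")
  df <- as.data.frame(ora)[, c(lead, setdiff(colnames(ora), lead))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene signature table
#'
#' Columns: `gene_id`, `loading`, `abs_loading`, `threshold`, `source_pc`.
#'
#' @param signature A `gene_signature` from [select_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  df <- as.data.frame(signature)
  df$threshold <- attr(signature, "threshold")
  df$source_pc <- attr(signature, "pc")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
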