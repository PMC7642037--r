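#' Read a gene x sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and a first column
#' of gene identifiers; the body is numeric FPKM (non-negative). Genes whose
#' expression is constant across samples are retained but recorded in the
#' `"zero_variance"` attribute of the result, so downstream correlation code
#' can exclude them explicitly.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes in rows, samples in columns) with an
#'   attribute `zero_variance` holding the ids of constant genes.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_expression_tsv(m, tf)
#' em <- read_expression_tsv(tf)
read_expression_tsv <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort("expression file not found: %s", path)
  if (file.size(path) == 0L) abort("expression file is empty: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort("expression file must have a gene-id column and at least one sample: %s", path)
  }
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) abort("duplicate gene id(s) in %s: %s", path, paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample id(s) in %s: %s", path,
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !(df[[j + 1L]] %in% c("NA", "")))
    bad <- c(bad, which(df[[j + 1L]] %in% c("NA", "")))
    if (length(bad)) {
      abort("non-numeric value at row %d (gene '%s'), column '%s' in %s",
            bad[1L] + 1L, gene_ids[bad[1L]], sample_ids[j], path)
    }
    vals[, j] <- v
  }
  validate_expression_matrix(vals)
}

#' Write an expression matrix to TSV
#'
#' @param em Numeric gene x sample matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  em <- validate_expression_matrix(em)
  out <- data.frame(gene_id = rownames(em),
                    apply(em, 2L, format_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(em))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks unique gene/sample ids and finite non-negative values, and tags
#' constant genes in the `zero_variance` attribute.
#'
#' @param em Numeric matrix, genes in rows.
#' @return The validated matrix.
#' @export
validate_expression_matrix <- function(em) {
  if (!is.matrix(em) || !is.numeric(em)) abort("expression matrix must be a numeric matrix")
  if (is.null(rownames(em)) || is.null(colnames(em))) {
    abort("expression matrix must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(em))) {
    abort("duplicate gene id(s): %s",
          paste(unique(rownames(em)[duplicated(rownames(em))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(em))) {
    abort("duplicate sample id(s): %s",
          paste(unique(colnames(em)[duplicated(colnames(em))]), collapse = ", "))
  }
  if (any(!is.finite(em))) abort("expression values must all be finite")
  if (any(em < 0)) abort("expression values must be non-negative (FPKM)")
  rv <- apply(em, 1L, function(x) max(x) - min(x)) == 0
  attr(em, "zero_variance") <- rownames(em)[rv]
  em
}
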