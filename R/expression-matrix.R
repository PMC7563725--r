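#' Expression matrix with sample annotations
#'
#' Container for a genes x samples expression matrix (log2 scale) together
#' with the per-sample batch label and 0/1 phenotype (0 = normal, 1 = cancer).
#' Gene symbols are carried as row names and sample ids as column names.
#'
#' @param values numeric matrix, genes in rows (row names = gene symbols),
#'   samples in columns (column names = sample ids).
#' @param batch character vector of per-sample batch labels, length
#'   `ncol(values)`.
#' @param phenotype integer vector of per-sample phenotypes in `{0, 1}`,
#'   length `ncol(values)`.
#' @return An object of class `expr_mat`: a list with elements `values`,
#'   `batch`, `phenotype`.
#' @export
expression_matrix <- function(values, batch, phenotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique gene symbols as row names")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique sample ids as column names")
  batch <- as.character(batch)
  if (length(batch) != ncol(values) || any(!nzchar(batch)) || anyNA(batch))
    stop("`batch` must be a non-empty label for every sample")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != ncol(values) || anyNA(phenotype) ||
      !all(phenotype %in% c(0L, 1L)))
    stop("`phenotype` must be 0 (normal) or 1 (cancer) for every sample")
  if (anyNA(values)) stop("`values` must not contain missing values")
  structure(list(values = values, batch = batch, phenotype = phenotype),
            class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d genes x %d samples, %d batches (%s), %d/%d normal/cancer\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              paste(unique(x$batch), collapse = ", "),
              sum(x$phenotype == 0L), sum(x$phenotype == 1L)))
  invisible(x)
}

#' Gene and sample accessors
#' @param x an `expr_mat`.
#' @return `gene_ids()`: character vector of gene symbols;
#'   `sample_ids()`: character vector of sample ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by samples or genes
#'
#' @param x an `expr_mat`.
#' @param samples sample indices, logical mask, or sample ids.
#' @param genes gene indices, logical mask, or gene symbols.
#' @return A new `expr_mat` restricted to the requested rows/columns.
#' @export
subset_samples <- function(x, samples) {
  expression_matrix(x$values[, samples, drop = FALSE],
                    x$batch[if (is.character(samples))
                      match(samples, sample_ids(x)) else samples],
                    x$phenotype[if (is.character(samples))
                      match(samples, sample_ids(x)) else samples])
}

#' @rdname subset_samples
#' @export
subset_genes <- function(x, genes) {
  expression_matrix(x$values[genes, , drop = FALSE], x$batch, x$phenotype)
}
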