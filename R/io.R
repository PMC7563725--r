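#' Read an expression matrix and its sample metadata from text files
#'
#' The expression file is tab- or comma-separated (auto-detected from the
#' header line) with gene symbols in the first column and one column per
#' sample. The metadata file has columns `sample`, `batch`, `phenotype`
#' (0 = normal, 1 = cancer).
#'
#' @param path path to the expression table.
#' @param meta_path path to the sample-metadata table.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, meta_path) {
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs a gene column and >=1 sample")
  genes <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable expression value at row %d, column '%s'",
                 bad[1], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))

  meta <- utils::read.table(meta_path, header = TRUE, sep = .detect_sep(meta_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "batch", "phenotype")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns sample, batch, phenotype")
  missing <- setdiff(colnames(num), meta$sample)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(num), meta$sample), ]
  expression_matrix(num, meta$batch, meta$phenotype)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an expression matrix and metadata as TSV files
#'
#' @param x an [expression_matrix()].
#' @param path output path for the expression TSV (first column `gene`).
#' @param meta_path output path for the metadata TSV.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(x, path, meta_path) {
  tab <- data.frame(gene = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = sample_ids(x), batch = x$batch,
                     phenotype = x$phenotype)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Simulate a study and write it to disk
#'
#' Generates a synthetic study from a [synthetic_spec()] and writes the
#' expression TSV, metadata TSV and a ground-truth JSON sidecar into `dir`,
#' in the formats accepted by [read_expression()] and [run_pipeline()].
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_expression(spec)
  expr_path <- file.path(dir, "expression.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "ground_truth.json")
  write_expression(sim$expr, expr_path, meta_path)
  truth <- sim$truth
  truth$batch_params <- lapply(truth$batch_params, function(m)
    as.data.frame(m, check.names = FALSE))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(expression = expr_path, metadata = meta_path,
              ground_truth = truth_path))
}
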