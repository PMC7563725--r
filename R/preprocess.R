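#' Merge expression datasets on shared gene symbols
#'
#' Within each dataset, rows sharing a gene symbol (duplicate probes) are
#' collapsed to their per-sample median; the merged matrix keeps the
#' intersection of symbols across datasets and concatenates all samples,
#' preserving batch and phenotype labels.
#'
#' @param matrices list of [expression_matrix()] objects, or plain lists
#'   with elements `values`, `batch`, `phenotype` when the input still
#'   carries duplicate gene symbols (collapsed by median here). Duplicate
#'   sample ids across inputs are an error.
#' @return A merged [expression_matrix()].
#' @export
merge_datasets <- function(matrices) {
  if (!length(matrices)) stop("need at least one dataset")
  collapsed <- lapply(matrices, .collapse_duplicates)
  common <- Reduce(intersect, lapply(collapsed, function(x) gene_ids(x)))
  if (!length(common)) stop("empty gene intersection across datasets")
  ids <- unlist(lapply(collapsed, sample_ids))
  if (anyDuplicated(ids))
    stop("duplicate sample ids across datasets: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- do.call(cbind, lapply(collapsed, function(x)
    x$values[common, , drop = FALSE]))
  expression_matrix(vals,
                    unlist(lapply(collapsed, function(x) x$batch)),
                    unlist(lapply(collapsed, function(x) x$phenotype)))
}

.collapse_duplicates <- function(x) {
  ids <- rownames(x$values)
  if (!anyDuplicated(ids))
    return(expression_matrix(x$values, x$batch, x$phenotype))
  groups <- split(seq_along(ids), ids)
  vals <- t(vapply(groups, function(r)
    apply(x$values[r, , drop = FALSE], 2, stats::median),
    numeric(ncol(x$values))))
  vals <- vals[unique(ids), , drop = FALSE]  # keep first-appearance order
  expression_matrix(vals, x$batch, x$phenotype)
}

#' Log2-transform datasets still on a linear scale
#'
#' Each batch is inspected separately: a batch whose maximum value exceeds
#' `threshold` is treated as linear-scale and replaced by `log2(x + 1)`;
#' batches already on a log scale pass through unchanged. The decision is
#' recorded per batch in the `"log2_applied"` attribute.
#'
#' @param x an [expression_matrix()].
#' @param threshold maximum value above which a batch is deemed linear-scale.
#' @return The transformed [expression_matrix()] with a named logical
#'   attribute `log2_applied`.
#' @export
log2_if_needed <- function(x, threshold = 50) {
  applied <- logical(0)
  for (b in unique(x$batch)) {
    cols <- x$batch == b
    linear <- max(x$values[, cols]) > threshold
    applied[b] <- linear
    if (linear) {
      if (min(x$values[, cols]) < 0)
        stop(sprintf("batch '%s' flagged linear-scale but has negative values", b))
      x$values[, cols] <- log2(x$values[, cols] + 1)
    }
  }
  attr(x, "log2_applied") <- applied
  x
}

#' Standardize each gene to mean 0, sd 1
#'
#' Uses the sample (n-1) standard deviation. Constant genes are dropped with
#' a warning; an all-constant matrix is an error.
#'
#' @param x an [expression_matrix()].
#' @return A standardized [expression_matrix()] (possibly with fewer genes).
#' @export
standardize <- function(x) {
  m <- rowMeans(x$values)
  s <- apply(x$values, 1, stats::sd)
  keep <- s > 0
  if (!any(keep)) stop("all genes are constant; nothing to standardize")
  if (!all(keep))
    warning(sprintf("dropping %d constant gene(s): %s", sum(!keep),
                    paste(utils::head(gene_ids(x)[!keep], 5), collapse = ", ")))
  vals <- (x$values[keep, , drop = FALSE] - m[keep]) / s[keep]
  expression_matrix(vals, x$batch, x$phenotype)
}

#' Remove batch effects with a parametric empirical-Bayes location/scale model
#'
#' Implements the parametric location/scale adjustment of the
#' empirical-Bayes framework for microarray batch correction: genes are
#' standardized against a batch-free model that protects the phenotype
#' covariate, per-gene per-batch location and scale are estimated on the
#' standardized residuals, shrunk toward pooled priors (normal prior on
#' locations, inverse-gamma on scales, method-of-moments hyperparameters,
#' iterative posterior solution), removed, and the data rescaled to the
#' original per-gene mean and variance model.
#'
#' @param x an [expression_matrix()] with >= 2 batches, each with >= 2
#'   samples.
#' @param eb if `FALSE`, shrinkage is disabled and the raw per-batch
#'   location/scale estimates are removed exactly (useful for small exact
#'   tests).
#' @param mean_only adjust batch locations only, leaving scales untouched
#'   (the right model for pure location shifts, which it then removes
#'   exactly).
#' @param allow_single if `TRUE`, a single-batch input is returned unchanged
#'   instead of raising an error.
#' @return The corrected [expression_matrix()]. Genes with zero variance
#'   within any batch are dropped first (with a message).
#' @export
correct_batch <- function(x, eb = TRUE, mean_only = FALSE,
                          allow_single = FALSE) {
  batches <- unique(x$batch)
  if (length(batches) < 2) {
    if (allow_single) return(x)
    stop("batch correction needs >= 2 batches")
  }
  nb <- table(x$batch)
  if (any(nb < 2))
    stop("batch with a single sample: ",
         paste(names(nb)[nb < 2], collapse = ", "))

  # drop genes constant within any batch (scale undefined there)
  ok <- rep(TRUE, nrow(x$values))
  for (b in batches) {
    v <- apply(x$values[, x$batch == b, drop = FALSE], 1, stats::var)
    ok <- ok & v > 0
  }
  if (!all(ok)) {
    message(sprintf("correct_batch: dropping %d gene(s) with zero within-batch variance",
                    sum(!ok)))
    x <- subset_genes(x, ok)
  }

  dat <- x$values
  n <- ncol(dat)
  batchmod <- stats::model.matrix(~ 0 + factor(x$batch, levels = batches))
  colnames(batchmod) <- batches
  design <- cbind(batchmod, phenotype = x$phenotype)
  if (qr(design)$rank < ncol(design))
    stop("phenotype is confounded with batch; cannot protect it")

  n_batch <- length(batches)
  n_per <- colSums(batchmod)
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))   # coef x genes
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- ((dat - t(design %*% B_hat))^2) %*% rep(1 / n, n)

  stand_mean <- t(grand_mean) %*% t(rep(1, n))
  tmp <- design
  tmp[, seq_len(n_batch)] <- 0
  stand_mean <- stand_mean + t(tmp %*% B_hat)
  s_data <- (dat - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n)))

  gamma_hat <- t(solve(crossprod(batchmod), t(batchmod) %*% t(s_data)))
  delta_hat <- if (mean_only)
    matrix(1, nrow(s_data), n_batch, dimnames = list(rownames(s_data), batches))
  else sapply(batches, function(b)
    apply(s_data[, x$batch == b, drop = FALSE], 1, stats::var))

  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (j in seq_len(n_batch)) {
      g <- gamma_hat[, j]; d <- delta_hat[, j]
      g_bar <- mean(g); t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      nj <- n_per[j]
      sd_b <- s_data[, x$batch == batches[j], drop = FALSE]
      g_new <- g; d_new <- d
      change <- 1
      while (change > 1e-4) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * nj * g + d_old * g_bar) / (t2 * nj + d_old)
        if (!mean_only) {
          sum2 <- rowSums((sd_b - g_new %*% t(rep(1, nj)))^2)
          d_new <- (0.5 * sum2 + b_prior) / (nj / 2 + a_prior - 1)
        }
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d_new - d_old) / d_old)
      }
      gamma_star[, j] <- g_new
      delta_star[, j] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  bayes <- s_data
  for (j in seq_len(n_batch)) {
    cols <- x$batch == batches[j]
    bayes[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  corrected <- bayes * (sqrt(var_pooled) %*% t(rep(1, n))) + stand_mean
  out <- expression_matrix(corrected, x$batch, x$phenotype)
  attr(out, "batch_model") <- list(
    grand_mean = as.numeric(grand_mean), var_pooled = as.numeric(var_pooled),
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    prior = if (eb) "parametric-eb" else "none")
  out
}

#' Fold a held-out batch onto a corrected training reference
#'
#' Aligns each gene of the held-out batch to the corrected training data by a
#' per-gene location/scale map: test values are standardized by their own
#' batch mean/sd and rescaled to the training per-gene mean/sd. Keeps the
#' trained model independent of held-out samples.
#'
#' @param train corrected training [expression_matrix()].
#' @param test held-out [expression_matrix()] with the same genes.
#' @return The aligned test [expression_matrix()].
#' @export
align_holdout_batch <- function(train, test) {
  common <- gene_ids(train)
  if (!all(common %in% gene_ids(test)))
    stop("held-out batch is missing genes present in the training reference")
  tv <- test$values[common, , drop = FALSE]
  mt <- rowMeans(tv); st <- apply(tv, 1, stats::sd)
  if (any(st == 0)) st[st == 0] <- 1
  mr <- rowMeans(train$values); sr <- apply(train$values, 1, stats::sd)
  vals <- (tv - mt) / st * sr + mr
  expression_matrix(vals, test$batch, test$phenotype)
}

#' PCA quality control of batch structure
#'
#' Projects samples onto the top principal components of the gene-centered
#' expression matrix; intended for before/after batch-correction inspection.
#'
#' @param x an [expression_matrix()].
#' @param n_components number of components (`<= min(genes, samples)`).
#' @return A data.frame with columns `sample`, `batch`, `phenotype` and
#'   `PC1..PCk` scores; the per-component explained-variance fractions are in
#'   the `"explained_variance"` attribute.
#' @export
pca_qc <- function(x, n_components = 2) {
  if (n_components > min(dim(x$values)))
    stop("n_components exceeds min(genes, samples)")
  if (all(apply(x$values, 1, stats::sd) == 0))
    stop("degenerate matrix: all genes constant")
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  out <- cbind(data.frame(sample = sample_ids(x), batch = x$batch,
                          phenotype = x$phenotype), scores)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  rownames(out) <- NULL
  out
}
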