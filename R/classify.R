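#' Split samples by held-out batch
#'
#' @param x an [expression_matrix()].
#' @param test_batch batch id held out as the test set.
#' @return A list with `train`/`test` sample indices and a `counts` table of
#'   class counts per split. Warns if the test split has one class only.
#' @export
split_by_batch <- function(x, test_batch) {
  if (!test_batch %in% x$batch)
    stop(sprintf("batch '%s' not present", test_batch))
  test <- which(x$batch == test_batch)
  train <- which(x$batch != test_batch)
  counts <- rbind(train = c(normal = sum(x$phenotype[train] == 0),
                            cancer = sum(x$phenotype[train] == 1)),
                  test = c(normal = sum(x$phenotype[test] == 0),
                           cancer = sum(x$phenotype[test] == 1)))
  if (any(counts["test", ] == 0))
    warning("held-out batch contains a single class; AUC will be undefined")
  list(train = train, test = test, counts = counts)
}

#' Fuse hub-gene expression and latent features
#'
#' Columns are the hub genes' expression (samples in rows) followed by the
#' latent dimensions, z-scaled feature-wise using training-split statistics
#' only.
#'
#' @param x an [expression_matrix()] (source of hub-gene expression).
#' @param hub_genes character vector of hub gene symbols (may be empty for a
#'   latents-only ablation).
#' @param latents samples x latent matrix from [encode_samples()] (or `NULL`
#'   for a hubs-only ablation), rows aligned with `sample_ids(x)`.
#' @param train sample indices whose mean/sd define the scaling.
#' @return samples x features numeric matrix with attributes `center` and
#'   `scale` (training statistics).
#' @export
build_features <- function(x, hub_genes, latents = NULL, train) {
  missing <- setdiff(hub_genes, gene_ids(x))
  if (length(missing))
    stop("hub gene(s) missing from matrix: ", paste(missing, collapse = ", "))
  feats <- NULL
  if (length(hub_genes))
    feats <- t(x$values[hub_genes, , drop = FALSE])
  if (!is.null(latents)) {
    if (nrow(latents) != ncol(x$values))
      stop("latents are not aligned with the samples")
    feats <- if (is.null(feats)) latents else cbind(feats, latents)
  }
  if (is.null(feats)) stop("no features requested")
  ctr <- colMeans(feats[train, , drop = FALSE])
  scl <- apply(feats[train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  out <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Train a support vector machine
#'
#' Soft-margin SVM (libsvm dual solver via e1071) with decision scores
#' oriented so that larger values favor the positive class.
#'
#' @param features samples x features matrix (training rows only).
#' @param labels 0/1 vector; both classes required.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param C soft-margin cost (default 1).
#' @return A `coexfuse_svm` wrapper holding the fitted model and score
#'   orientation.
#' @export
train_svm <- function(features, labels, kernel = "linear", C = 1) {
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  fit <- e1071::svm(x = features, y = factor(labels, levels = c(0, 1)),
                    kernel = kernel, cost = C, scale = FALSE)
  sc <- .svm_scores(fit, features)
  flip <- mean(sc[labels == 1]) < mean(sc[labels == 0])
  structure(list(fit = fit, flip = flip, kernel = kernel, C = C),
            class = "coexfuse_svm")
}

.svm_scores <- function(fit, features) {
  pr <- stats::predict(fit, features, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

#' Decision scores of a trained SVM
#' @param model a [train_svm()] model.
#' @param features samples x features matrix.
#' @return Numeric scores, larger = more cancer-like.
#' @export
decision_scores <- function(model, features) {
  sc <- .svm_scores(model$fit, features)
  if (model$flip) -sc else sc
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with ties averaged: the probability that a
#' random positive outscores a random negative.
#'
#' @param scores numeric decision scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a test set
#'
#' @param model a [train_svm()] model.
#' @param features test samples x features matrix.
#' @param labels 0/1 test labels.
#' @return A `classifier_report` list: `accuracy`, `auc` (`NA` when only one
#'   class is present), `confusion` (2x2 table, truth in rows), `scores`,
#'   `predictions`, `n`.
#' @export
evaluate_classifier <- function(model, features, labels) {
  if (!nrow(features)) stop("empty test set")
  pred <- as.integer(as.character(stats::predict(model$fit, features)))
  sc <- decision_scores(model, features)
  confusion <- table(truth = factor(labels, levels = c(0, 1)),
                     predicted = factor(pred, levels = c(0, 1)))
  structure(list(accuracy = mean(pred == labels),
                 auc = auc_score(sc, labels),
                 confusion = confusion, scores = sc, predictions = pred,
                 n = length(labels)), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, AUC %s on %d test samples\n", x$accuracy,
              ifelse(is.na(x$auc), "undefined", sprintf("%.4f", x$auc)), x$n))
  print(x$confusion)
  invisible(x)
}
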