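# Small expression matrices and independent oracles shared across tests.

# Plain expr_mat from a numeric matrix, single batch / balanced phenotype by
# default.
toy_expr <- function(values, batch = NULL, phenotype = NULL) {
  n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%03d", seq_len(n))
  if (is.null(batch)) batch <- rep("b1", n)
  if (is.null(phenotype)) phenotype <- rep(c(0L, 1L), length.out = n)
  expression_matrix(values, batch, phenotype)
}

# Desk-scale study small enough for per-module tests (<1 s to generate).
small_spec <- function(seed = 1, trait_effect = 4) {
  synthetic_spec(
    n_genes = 400,
    batches = list(list(id = "b1", n_normal = 12, n_cancer = 14),
                   list(id = "b2", n_normal = 12, n_cancer = 14),
                   list(id = "b3", n_normal = 12, n_cancer = 14),
                   list(id = "b4", n_normal = 11, n_cancer = 11)),
    modules = list(module_spec(60, trait_effect = trait_effect, n_hubs = 5),
                   module_spec(40)),
    de_frac_background = 0.05, seed = seed)
}

# --- independent oracles -----------------------------------------------------

# Benjamini-Hochberg step-up, spelled out.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Topological overlap by triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# Intramodular connectivity by explicit sums.
kin_oracle <- function(a, labels) {
  genes <- rownames(a)
  out <- setNames(rep(NA_real_, length(genes)), genes)
  for (i in seq_along(genes)) {
    if (labels[genes[i]] == "grey") next
    s <- 0
    for (j in seq_along(genes))
      if (j != i && labels[genes[j]] == labels[genes[i]]) s <- s + a[i, j]
    out[genes[i]] <- s
  }
  out
}

# AUC by all-pairs comparison.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Fraction of genes whose one-way batch ANOVA F-test is significant.
batch_f_frac <- function(x, alpha = 0.05) {
  f <- factor(x$batch)
  k <- nlevels(f); n <- ncol(x$values)
  gm <- rowMeans(x$values)
  ssb <- 0; ssw <- 0
  for (lev in levels(f)) {
    cols <- f == lev
    bm <- rowMeans(x$values[, cols, drop = FALSE])
    ssb <- ssb + sum(cols) * (bm - gm)^2
    ssw <- ssw + rowSums((x$values[, cols, drop = FALSE] - bm)^2)
  }
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  mean(p < alpha)
}
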