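#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector (unit-norm
#' sample scores) of the gene-standardized module submatrix, sign-oriented
#' so that it correlates non-negatively with the module's average
#' standardized expression profile.
#'
#' @param x an [expression_matrix()].
#' @param labels named module labels per gene (`"grey"` = unassigned).
#' @return A list with `eigengenes` (module x sample matrix, rows named
#'   `ME<label>`) and `var_explained` (named fraction of module variance
#'   captured, in `(0, 1]`).
#' @export
module_eigengenes <- function(x, labels) {
  labels <- labels[gene_ids(x)]
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules")
  me <- matrix(NA_real_, length(mods), ncol(x$values),
               dimnames = list(paste0("ME", mods), sample_ids(x)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (i in seq_along(mods)) {
    sub <- x$values[labels == mods[i], , drop = FALSE]
    if (nrow(sub) < 2)
      stop(sprintf("module '%s' has fewer than 2 genes", mods[i]))
    s <- apply(sub, 1, stats::sd)
    if (any(s == 0))
      stop(sprintf("degenerate module '%s': zero-variance gene", mods[i]))
    std <- (sub - rowMeans(sub)) / s
    sv <- svd(std)
    scores <- sv$v[, 1]
    if (stats::cor(scores, colMeans(std)) < 0) scores <- -scores
    me[i, ] <- scores
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge highly correlated modules
#'
#' While any pair of module eigengenes has Pearson correlation above
#' `threshold`, the most correlated pair is merged (the smaller module takes
#' the larger module's label) and eigengenes are recomputed. Terminates with
#' every pairwise eigengene correlation `<= threshold`; final labels are
#' re-colored by descending module size.
#'
#' @param x an [expression_matrix()].
#' @param labels named module labels per gene.
#' @param threshold correlation above which modules merge (default 0.8).
#' @return Named character vector of merged module labels.
#' @export
merge_modules <- function(x, labels, threshold = 0.8) {
  labels <- labels[gene_ids(x)]
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(x, labels)$eigengenes
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    if (max(cc) <= threshold) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    a <- sub("^ME", "", rownames(me)[ij[1]])
    b <- sub("^ME", "", rownames(me)[ij[2]])
    # smaller module absorbed into the larger (ties: keep the first label)
    if (sum(labels == a) < sum(labels == b)) { from <- a; to <- b }
    else { from <- b; to <- a }
    labels[labels == from] <- to
  }
  .relabel_by_size(labels)
}

.relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), 0L)
  first <- vapply(mods, function(m) which(labels == m)[1], 0L)
  ord <- mods[order(-sizes, first)]
  cols <- c(.module_colors,
            paste0("module", seq_len(max(0, length(ord) - length(.module_colors)))))
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- cols[i]
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with the 0/1 phenotype;
#' two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees
#' of freedom.
#'
#' @param me module x sample eigengene matrix (rows `ME<label>`).
#' @param phenotype 0/1 vector aligned with the eigengene columns; both
#'   classes must be present.
#' @return A data.frame with columns `module`, `PCC`, `p.value`, `n`.
#' @export
module_trait_correlation <- function(me, phenotype) {
  if (length(unique(phenotype)) < 2)
    stop("phenotype must contain both classes")
  n <- ncol(me)
  if (any(apply(me, 1, stats::sd) == 0)) stop("constant module eigengene")
  r <- as.numeric(stats::cor(t(me), phenotype))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(module = sub("^ME", "", rownames(me)), PCC = r, p.value = p,
             n = n, row.names = NULL)
}

#' Select the key (most trait-correlated) module
#'
#' @param trait_cor result of [module_trait_correlation()].
#' @param sizes optional named module sizes for tie-breaking.
#' @return The label of the module with maximum `|PCC|` (ties broken by
#'   smaller p-value, then larger size).
#' @export
select_key_module <- function(trait_cor, sizes = NULL) {
  if (!nrow(trait_cor)) stop("no modules to select from")
  sz <- if (is.null(sizes)) rep(0, nrow(trait_cor))
        else as.numeric(sizes[trait_cor$module])
  ord <- order(-abs(trait_cor$PCC), trait_cor$p.value, -sz)
  trait_cor$module[ord[1]]
}
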