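#' Gene significance
#'
#' `GS_i = |PCC(x_i, phenotype)|` — the magnitude of each gene's correlation
#' with the binary trait.
#'
#' @param x an [expression_matrix()]; both phenotype classes must be present.
#' @return Named numeric vector of GS values in `[0, 1]`. Constant genes get
#'   GS 0 with a warning.
#' @export
gene_significance <- function(x) {
  if (length(unique(x$phenotype)) < 2)
    stop("phenotype must contain both classes")
  s <- apply(x$values, 1, stats::sd)
  gs <- stats::setNames(rep(0, nrow(x$values)), gene_ids(x))
  if (any(s == 0))
    warning(sprintf("%d constant gene(s) assigned GS = 0", sum(s == 0)))
  ok <- s > 0
  gs[ok] <- abs(as.numeric(stats::cor(t(x$values[ok, , drop = FALSE]),
                                      x$phenotype)))
  gs
}

#' Signed module membership (kME)
#'
#' `MM_i = PCC(x_i, ME of gene i's module)` — signed, so anti-correlated
#' members are negative. Grey (unassigned) genes get `NA`.
#'
#' @param x an [expression_matrix()].
#' @param me eigengene matrix from [module_eigengenes()].
#' @param labels named module labels per gene.
#' @return Named numeric vector of MM values in `[-1, 1]` (`NA` for grey).
#' @export
signed_kme <- function(x, me, labels) {
  labels <- labels[gene_ids(x)]
  mm <- stats::setNames(rep(NA_real_, nrow(x$values)), gene_ids(x))
  for (mod in setdiff(unique(labels), "grey")) {
    rows <- which(labels == mod)
    ev <- me[paste0("ME", mod), ]
    mm[rows] <- as.numeric(stats::cor(t(x$values[rows, , drop = FALSE]), ev))
  }
  mm
}

#' Intramodular connectivity
#'
#' `K.in_i = sum_{j in module(i), j != i} a_ij`.
#'
#' @param adjacency adjacency matrix with unit diagonal, dimnames = genes.
#' @param labels named module labels aligned with the adjacency.
#' @return Named numeric vector (`NA` for grey genes).
#' @export
intramodular_connectivity <- function(adjacency, labels) {
  genes <- rownames(adjacency)
  labels <- labels[genes]
  kin <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (mod in setdiff(unique(labels), "grey")) {
    rows <- which(labels == mod)
    sub <- adjacency[rows, rows, drop = FALSE]
    kin[rows] <- rowSums(sub) - diag(sub)
  }
  kin
}

#' Assemble the per-gene hub statistics table for one module
#'
#' @param x an [expression_matrix()] used for GS/MM.
#' @param adjacency network adjacency.
#' @param me eigengene matrix.
#' @param labels module labels.
#' @param module the module of interest.
#' @param de result of [moderated_t_test()] supplying `logFC`/`adj.P.Val`.
#' @return A data.frame (one row per module gene) with columns `gene`,
#'   `logFC`, `adj.P.Val`, `GS`, `MM`, `K.in`.
#' @export
hub_gene_table <- function(x, adjacency, me, labels, module, de) {
  labels <- labels[gene_ids(x)]
  genes <- names(labels)[labels == module]
  if (!length(genes)) stop(sprintf("module '%s' has no genes", module))
  gs <- gene_significance(x)[genes]
  mm <- signed_kme(x, me, labels)[genes]
  kin <- intramodular_connectivity(adjacency, labels)[genes]
  idx <- match(genes, de$gene)
  data.frame(gene = genes,
             logFC = de$logFC[idx], adj.P.Val = de$adj.P.Val[idx],
             GS = unname(gs), MM = unname(mm), K.in = unname(kin),
             row.names = NULL)
}

#' Screen hub genes
#'
#' Keeps genes with `GS > gs_min`, `|MM| > mm_min` and membership in the
#' differentially-expressed set, sorts by `K.in` descending (ties broken by
#' GS descending, then gene id) and returns the top `top_n`.
#'
#' @param table a [hub_gene_table()] restricted to the key module.
#' @param de_genes character vector of screened DE genes.
#' @param gs_min GS threshold (default 0.5, strict).
#' @param mm_min absolute MM threshold (default 0.8, strict).
#' @param top_n number of hub genes to return (default 10).
#' @return The hub rows of `table` (possibly fewer than `top_n`, with a
#'   warning). Candidate counts before/after the DE screen are attached as
#'   attributes `n_gs_mm` and `n_candidates`.
#' @export
screen_hubs <- function(table, de_genes, gs_min = 0.5, mm_min = 0.8,
                        top_n = 10) {
  pass <- table$GS > gs_min & abs(table$MM) > mm_min
  n_gs_mm <- sum(pass, na.rm = TRUE)
  pass <- pass & table$gene %in% de_genes
  cand <- table[which(pass), , drop = FALSE]
  message(sprintf("hub screen: %d genes pass GS/MM, %d also differentially expressed",
                  n_gs_mm, nrow(cand)))
  cand <- cand[order(-cand$K.in, -cand$GS, cand$gene), , drop = FALSE]
  if (nrow(cand) < top_n)
    warning(sprintf("only %d genes survive the hub screen (requested %d)",
                    nrow(cand), top_n))
  out <- utils::head(cand, top_n)
  rownames(out) <- NULL
  attr(out, "n_gs_mm") <- n_gs_mm
  attr(out, "n_candidates") <- nrow(cand)
  out
}
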