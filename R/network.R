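#' Weighted network adjacency from expression
#'
#' Unsigned adjacency `a_ij = |cor_ij|^beta` (signed option:
#' `((1 + cor)/2)^beta`), with unit diagonal.
#'
#' @param cormat gene x gene Pearson correlation matrix (e.g.
#'   `cor(t(x$values))`).
#' @param beta soft-threshold power.
#' @param signed use the signed transformation instead of `|cor|`.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
compute_adjacency <- function(cormat, beta, signed = FALSE) {
  a <- if (signed) ((1 + cormat) / 2)^beta else abs(cormat)^beta
  diag(a) <- 1
  a
}

#' Whole-network connectivity
#'
#' `k_i = sum_{j != i} a_ij`.
#'
#' @param adjacency adjacency matrix with unit diagonal.
#' @return Numeric vector of connectivities.
#' @export
connectivity <- function(adjacency) rowSums(adjacency) - diag(adjacency)

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `nbins` equal-width bins, computes the
#' per-bin relative frequency `p(k)` and mean connectivity, drops empty bins,
#' and regresses `log10 p(k)` on `log10 k`. The truncated model adds a linear
#' `k` term (truncated exponential correction).
#'
#' @param k connectivity vector.
#' @param nbins number of bins (default 10).
#' @return List with `r_squared`, `slope`, `truncated_r_squared` (each `NA`
#'   if fewer than 3 usable bins).
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2)
    return(list(r_squared = NA_real_, slope = NA_real_,
                truncated_r_squared = NA_real_))
  breaks <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  dk <- dk[keep]; pk <- pk[keep]
  if (length(dk) < 3)
    return(list(r_squared = NA_real_, slope = NA_real_,
                truncated_r_squared = NA_real_))
  log_dk <- log10(dk); log_pk <- log10(pk)
  fit <- stats::lm(log_pk ~ log_dk)
  tfit <- stats::lm(log_pk ~ log_dk + dk)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       truncated_r_squared = summary(tfit)$r.squared)
}

#' Scan candidate soft-threshold powers
#'
#' For each candidate power the adjacency is formed, the connectivity vector
#' computed, and the scale-free fit measured as in [scale_free_fit()].
#'
#' @param x an [expression_matrix()] (>= 3 genes, >= 4 samples).
#' @param powers candidate powers (default 1:20).
#' @param nbins histogram bins for the fit.
#' @param signed signed network option.
#' @return A data.frame with columns `Power`, `SFT.R.sq`, `slope`,
#'   `truncated.R.sq`, `mean.k`, `median.k`, `max.k`.
#' @export
scan_soft_thresholds <- function(x, powers = 1:20, nbins = 10, signed = FALSE) {
  if (nrow(x$values) < 3 || ncol(x$values) < 4)
    stop("need >= 3 genes and >= 4 samples")
  cormat <- stats::cor(t(x$values))
  rows <- lapply(powers, function(beta) {
    a <- compute_adjacency(cormat, beta, signed = signed)
    k <- connectivity(a)
    f <- scale_free_fit(k, nbins = nbins)
    data.frame(Power = beta, SFT.R.sq = f$r_squared, slope = f$slope,
               truncated.R.sq = f$truncated_r_squared,
               mean.k = mean(k), median.k = stats::median(k), max.k = max(k))
  })
  do.call(rbind, rows)
}

#' Select the soft-threshold power
#'
#' Smallest power whose scale-free fit exceeds `r2_min` with a negative
#' slope; if none qualifies, the power maximizing the fit is returned with a
#' warning.
#'
#' @param scan result of [scan_soft_thresholds()].
#' @param r2_min required fit (default 0.85).
#' @return The selected power (integer scalar).
#' @export
select_power <- function(scan, r2_min = 0.85) {
  if (!nrow(scan)) stop("empty soft-threshold scan")
  ok <- !is.na(scan$SFT.R.sq) & scan$SFT.R.sq > r2_min &
    !is.na(scan$slope) & scan$slope < 0
  if (any(ok)) return(scan$Power[which(ok)[1]])
  warning("no power reaches the scale-free fit threshold; using the best fit")
  scan$Power[which.max(scan$SFT.R.sq)]
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k` excludes the diagonal; the
#' diagonal is 1.
#'
#' @param adjacency symmetric adjacency matrix in `[0, 1]` with unit
#'   diagonal.
#' @return The TOM (symmetric, values in `[0, 1]`, unit diagonal).
#' @export
compute_tom <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12)
    stop("adjacency values must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # removes the u = i and u = j terms (diag 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at `cut_frac`
#' of the maximum merge height (the static-cut convention: unconnected
#' background genes agglomerate in a flat band at the maximum
#' dissimilarity, and cutting just below that band isolates the tight
#' branches). Every resulting cluster's internal merge height is below the
#' cut by construction, so no re-cutting is required. Clusters smaller than
#' `min_size` are assigned to `"grey"`; surviving modules are named by
#' descending size with the conventional module colors (turquoise, blue,
#' brown, ...).
#'
#' @param dissimilarity square matrix in `[0, 1]` (typically `1 - TOM`).
#' @param min_size minimum module size (default 30).
#' @param cut_frac fraction of the maximum merge height at which the tree
#'   is cut (default 0.99).
#' @return Named character vector of module labels per gene.
#' @export
detect_modules <- function(dissimilarity, min_size = 30, cut_frac = 0.99) {
  n <- nrow(dissimilarity)
  if (min_size >= n) {
    warning("min_size >= number of genes; all genes assigned to grey")
    return(stats::setNames(rep("grey", n), rownames(dissimilarity)))
  }
  h <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  cut_h <- cut_frac * max(h$height)
  cl <- stats::cutree(h, h = cut_h)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_size])
  cl[cl %in% small] <- 0L
  .label_modules(cl, rownames(dissimilarity))
}

.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

# 0 = unassigned -> grey; remaining clusters colored by descending size,
# ties broken by first gene index for determinism.
.label_modules <- function(cl, genes) {
  out <- rep("grey", length(cl))
  ids <- setdiff(unique(cl), 0L)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(cl == i), 0L)
    first <- vapply(ids, function(i) which(cl == i)[1], 0L)
    ord <- ids[order(-sizes, first)]
    cols <- c(.module_colors,
              paste0("module", seq_len(max(0, length(ord) - length(.module_colors)))))
    for (i in seq_along(ord)) out[cl == ord[i]] <- cols[i]
  }
  stats::setNames(out, genes)
}
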