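#' Moderated t-test between phenotype groups
#'
#' Per-gene two-group contrast (cancer minus normal, so positive log2FC =
#' upregulated in cancer) with empirical-Bayes variance moderation: the
#' posterior residual variance is `s2_post = (d0*s0^2 + df*s2)/(d0 + df)`
#' with hyperparameters `d0`, `s0^2` fitted by moment matching on the
#' distribution of `log(s2)` (trigamma-inverse solution), and the moderated t
#' is referred to a t distribution on `d0 + df` degrees of freedom.
#'
#' @param x an [expression_matrix()]; both phenotype groups need >= 2
#'   samples.
#' @param moderated if `FALSE`, an ordinary pooled-variance t-test is used
#'   instead (comparison mode).
#' @param d0_override optional forced prior degrees of freedom (`Inf` gives
#'   the fully shrunken limit where every gene uses `s0^2`).
#' @return A data.frame with columns `gene`, `logFC`, `t`, `P.Value`,
#'   `adj.P.Val` (Benjamini-Hochberg) and `direction` (`"up"`/`"down"`/
#'   `"none"` by the sign of `logFC`), plus attributes `d0` and `s0_2`.
#' @export
moderated_t_test <- function(x, moderated = TRUE, d0_override = NULL) {
  g0 <- x$phenotype == 0L
  g1 <- x$phenotype == 1L
  n0 <- sum(g0); n1 <- sum(g1)
  if (n0 < 2 || n1 < 2)
    stop(sprintf("each phenotype group needs >= 2 samples (have %d/%d)", n0, n1))
  v <- x$values
  m0 <- rowMeans(v[, g0, drop = FALSE])
  m1 <- rowMeans(v[, g1, drop = FALSE])
  logfc <- m1 - m0
  s2 <- (rowSums((v[, g0, drop = FALSE] - m0)^2) +
         rowSums((v[, g1, drop = FALSE] - m1)^2)) / (n0 + n1 - 2)
  df <- n0 + n1 - 2
  se_unscaled <- sqrt(1 / n0 + 1 / n1)

  if (moderated) {
    ok <- s2 > 0                      # hyperparameters from informative genes
    if (!any(ok)) stop("all genes have zero residual variance")
    fit <- .fit_f_dist(s2[ok], df)
    d0 <- if (is.null(d0_override)) fit$d0 else d0_override
    s0_2 <- fit$s0_2
    s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
               else (d0 * s0_2 + df * s2) / (d0 + df)
    tdf <- df + d0
  } else {
    d0 <- 0; s0_2 <- NA_real_
    s2_post <- s2
    tdf <- df
  }
  tstat <- logfc / (sqrt(s2_post) * se_unscaled)
  tstat[s2_post == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = tdf)
  out <- data.frame(gene = gene_ids(x), logFC = logfc, t = tstat,
                    P.Value = p, adj.P.Val = bh_adjust(p),
                    direction = ifelse(logfc > 0, "up",
                                       ifelse(logfc < 0, "down", "none")),
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# Moment fit of the scaled-F model for gene-wise sample variances:
# s2 ~ s0^2 * F(df, d0). Works on z = log(s2); E z and Var z are digamma /
# trigamma expressions, inverted with Newton's method.
.fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s0_2 = exp(emean)))
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    delta <- (trigamma(y) - x) / psigamma(y, deriv = 2)
    y <- y - delta
    if (abs(delta / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in rank, clipped to 1).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen differentially expressed genes
#'
#' Keeps genes with `adj.P.Val < alpha` and `|logFC| > lfc` (both strict).
#'
#' @param de a result of [moderated_t_test()].
#' @param alpha FDR threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @return A list with `genes` (character), `up`/`down` counts, and `table`
#'   (the retained rows, ordered by adjusted p).
#' @export
screen_de <- function(de, alpha = 0.05, lfc = 1) {
  if (alpha <= 0 || lfc <= 0) stop("thresholds must be > 0")
  keep <- de$adj.P.Val < alpha & abs(de$logFC) > lfc
  tab <- de[keep, , drop = FALSE]
  tab <- tab[order(tab$adj.P.Val, tab$P.Value), , drop = FALSE]
  list(genes = tab$gene,
       up = sum(tab$logFC > 0),
       down = sum(tab$logFC < 0),
       table = tab)
}
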