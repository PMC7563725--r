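#' Variational autoencoder configuration
#'
#' Mirror-symmetric architecture `input - h1 - h2 - latent - h2 - h1 -
#' input` with ReLU hidden activations and linear output (Gaussian
#' likelihood, squared-error reconstruction). The reference widths are
#' 584/100 hidden units and a 10-dimensional latent for an 1159-gene input;
#' other input sizes scale the hidden widths proportionally.
#'
#' @param input_dim number of input genes.
#' @param hidden_dims two encoder widths; default scales `c(584, 100)` by
#'   `input_dim / 1159` (floored at `latent_dim`).
#' @param latent_dim latent dimension (default 10).
#' @param learning_rate Adam step size (default 0.0005).
#' @param batch_size minibatch size (default 20).
#' @param epochs training epochs (default 6).
#' @param seed RNG seed for initialization, shuffling and sampling.
#' @param kl_weight weight of the KL term (default 1).
#' @return A `vae_config` list.
#' @export
vae_config <- function(input_dim, hidden_dims = NULL, latent_dim = 10,
                       learning_rate = 5e-4, batch_size = 20, epochs = 6,
                       seed = 1, kl_weight = 1) {
  if (is.null(hidden_dims))
    hidden_dims <- pmax(round(input_dim * c(584, 100) / 1159), latent_dim)
  stopifnot(input_dim >= 1, length(hidden_dims) == 2, all(hidden_dims >= 1),
            latent_dim >= 1, epochs >= 1, batch_size >= 1, learning_rate > 0,
            kl_weight >= 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed), kl_weight = kl_weight),
            class = "vae_config")
}

.addb <- function(m, b) sweep(m, 2, b, "+")

.vae_init <- function(cfg) {
  d <- cfg$input_dim; h1 <- cfg$hidden_dims[1]; h2 <- cfg$hidden_dims[2]
  L <- cfg$latent_dim
  he <- function(fin, fout) matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)),
                                   fin, fout)
  lin <- function(fin, fout) matrix(stats::rnorm(fin * fout, 0, sqrt(1 / fin)),
                                    fin, fout)
  list(W1 = he(d, h1), b1 = numeric(h1),
       W2 = he(h1, h2), b2 = numeric(h2),
       Wm = lin(h2, L), bm = numeric(L),
       Wv = lin(h2, L), bv = numeric(L),
       W3 = he(L, h2), b3 = numeric(h2),
       W4 = he(h2, h1), b4 = numeric(h1),
       W5 = lin(h1, d), b5 = numeric(d))
}

# Forward pass + loss + analytic gradients for one minibatch.
# X: samples x genes; eps: samples x latent (fixed noise for the
# reparameterized draw z = mu + sigma * eps). Reconstruction is the
# per-sample sum of squared errors averaged over the batch (Gaussian ELBO
# convention); KL is summed over latent dims, averaged over the batch.
.vae_loss_grad <- function(p, X, eps, kl_weight) {
  B <- nrow(X)
  H1p <- .addb(X %*% p$W1, p$b1);  H1 <- H1p * (H1p > 0)
  H2p <- .addb(H1 %*% p$W2, p$b2); H2 <- H2p * (H2p > 0)
  MU <- .addb(H2 %*% p$Wm, p$bm)
  LV <- .addb(H2 %*% p$Wv, p$bv)
  S <- exp(0.5 * LV)
  Z <- MU + S * eps
  D1p <- .addb(Z %*% p$W3, p$b3);  D1 <- D1p * (D1p > 0)
  D2p <- .addb(D1 %*% p$W4, p$b4); D2 <- D2p * (D2p > 0)
  XH <- .addb(D2 %*% p$W5, p$b5)

  recon <- sum((XH - X)^2) / B
  kl <- sum(-0.5 * (1 + LV - MU^2 - exp(LV))) / B
  loss <- recon + kl_weight * kl

  dXH <- 2 * (XH - X) / B
  dW5 <- crossprod(D2, dXH); db5 <- colSums(dXH)
  dD2p <- (dXH %*% t(p$W5)) * (D2p > 0)
  dW4 <- crossprod(D1, dD2p); db4 <- colSums(dD2p)
  dD1p <- (dD2p %*% t(p$W4)) * (D1p > 0)
  dW3 <- crossprod(Z, dD1p); db3 <- colSums(dD1p)
  dZ <- dD1p %*% t(p$W3)
  dMU <- dZ + kl_weight * MU / B
  dLV <- dZ * eps * 0.5 * S + kl_weight * 0.5 * (exp(LV) - 1) / B
  dWm <- crossprod(H2, dMU); dbm <- colSums(dMU)
  dWv <- crossprod(H2, dLV); dbv <- colSums(dLV)
  dH2p <- (dMU %*% t(p$Wm) + dLV %*% t(p$Wv)) * (H2p > 0)
  dW2 <- crossprod(H1, dH2p); db2 <- colSums(dH2p)
  dH1p <- (dH2p %*% t(p$W2)) * (H1p > 0)
  dW1 <- crossprod(X, dH1p); db1 <- colSums(dH1p)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wm = dWm, bm = dbm, Wv = dWv, bv = dbv,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4,
                    W5 = dW5, b5 = db5))
}

.vae_encode_mu <- function(p, X) {
  H1p <- .addb(X %*% p$W1, p$b1); H1 <- H1p * (H1p > 0)
  H2p <- .addb(H1 %*% p$W2, p$b2); H2 <- H2p * (H2p > 0)
  .addb(H2 %*% p$Wm, p$bm)
}

.vae_decode <- function(p, Z) {
  D1p <- .addb(Z %*% p$W3, p$b3); D1 <- D1p * (D1p > 0)
  D2p <- .addb(D1 %*% p$W4, p$b4); D2 <- D2p * (D2p > 0)
  .addb(D2 %*% p$W5, p$b5)
}

#' Train a variational autoencoder on expression data
#'
#' Minimizes the per-sample summed squared reconstruction error plus
#' `kl_weight` times the KL divergence of the latent Gaussian from N(0, 1)
#' by Adam, with the reparameterized draw `z = mu + sigma * eps` during
#' training. Batches are reshuffled every epoch from the run seed, so a
#' fixed seed gives a bit-identical training history.
#'
#' @param x an [expression_matrix()] restricted to the genes of interest
#'   (per-gene standardized input is expected).
#' @param config a [vae_config()]; `input_dim` must equal `nrow(x$values)`.
#' @return A `vae_model` list with `params`, `config`, `history` (per-epoch
#'   `recon`, `kl`, `total`) and the training `genes`.
#' @export
train_vae <- function(x, config) {
  X <- t(x$values)
  if (ncol(X) != config$input_dim)
    stop(sprintf("config input_dim (%d) != number of genes (%d)",
                 config$input_dim, ncol(X)))
  n <- nrow(X)
  if (n < config$batch_size)
    stop("need at least batch_size samples to train")
  set.seed(config$seed)
  p <- .vae_init(config)
  adam_m <- lapply(p, function(w) w * 0)
  adam_v <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsg <- 1e-8; t <- 0
  L <- config$latent_dim
  hist <- data.frame(epoch = seq_len(config$epochs), recon = NA_real_,
                     kl = NA_real_, total = NA_real_)
  for (ep in seq_len(config$epochs)) {
    perm <- sample(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_recon <- 0; ep_kl <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * L), length(idx), L)
      r <- .vae_loss_grad(p, Xb, eps, config$kl_weight)
      if (!is.finite(r$loss))
        stop(sprintf("non-finite loss at epoch %d, batch starting %d", ep, s))
      t <- t + 1
      for (nm in names(p)) {
        g <- r$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        mhat <- adam_m[[nm]] / (1 - b1^t)
        vhat <- adam_v[[nm]] / (1 - b2^t)
        p[[nm]] <- p[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + epsg)
      }
      ep_recon <- ep_recon + r$recon * length(idx)
      ep_kl <- ep_kl + r$kl * length(idx)
    }
    hist$recon[ep] <- ep_recon / n
    hist$kl[ep] <- ep_kl / n
    hist$total[ep] <- hist$recon[ep] + config$kl_weight * hist$kl[ep]
  }
  structure(list(params = p, config = config, history = hist,
                 genes = gene_ids(x)), class = "vae_model")
}

#' Encode samples to their latent means
#'
#' Deterministic at inference: returns the posterior means `mu` without
#' sampling.
#'
#' @param model a trained [train_vae()] model.
#' @param x an [expression_matrix()] over the same gene set as training
#'   (reordered to the training order if necessary).
#' @return samples x latent_dim matrix of latent means (rows = sample ids).
#' @export
encode_samples <- function(model, x) {
  missing <- setdiff(model$genes, gene_ids(x))
  extra <- setdiff(gene_ids(x), model$genes)
  if (length(missing) || length(extra))
    stop(sprintf("gene set mismatch; missing: %s; extra: %s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 paste(utils::head(extra, 5), collapse = ", ")))
  X <- t(x$values[model$genes, , drop = FALSE])
  mu <- .vae_encode_mu(model$params, X)
  rownames(mu) <- sample_ids(x)
  colnames(mu) <- paste0("latent", seq_len(ncol(mu)))
  mu
}

#' Reconstruction error of a VAE on a dataset
#'
#' Decodes from the latent means (no sampling) and reports the mean squared
#' error per sample and overall.
#'
#' @inheritParams encode_samples
#' @return A list with `per_sample` (named numeric) and `overall`.
#' @export
reconstruction_error <- function(model, x) {
  X <- t(x$values[model$genes, , drop = FALSE])
  mu <- .vae_encode_mu(model$params, X)
  XH <- .vae_decode(model$params, mu)
  per <- rowMeans((XH - X)^2)
  names(per) <- sample_ids(x)
  list(per_sample = per, overall = mean(per))
}
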