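#' Pipeline configuration
#'
#' Collects every tunable threshold of the two-step feature-extraction
#' pipeline in one place. The defaults are the reference analysis settings:
#' DE screen at adjusted p < 0.05 and |log2FC| > 1, scale-free fit
#' requirement 0.85 over candidate powers 1-20, minimum module size 30,
#' eigengene merge correlation 0.8, hub screen GS > 0.5 and |MM| > 0.8 with
#' the top 10 genes by intramodular connectivity, a 10-dimensional VAE
#' (learning rate 0.0005, batch size 20, 6 epochs) and a linear SVM with
#' C = 1 evaluated on one held-out batch.
#'
#' @param test_batch batch id held out as the test set.
#' @param de_alpha,de_lfc DE screen thresholds.
#' @param r2_min scale-free fit requirement.
#' @param powers candidate soft-threshold powers.
#' @param min_module_size,merge_cor,cut_frac module detection settings.
#' @param gs_min,mm_min,top_n_hubs hub screen settings.
#' @param latent_dim,vae_epochs,vae_batch_size,vae_learning_rate,kl_weight
#'   VAE settings.
#' @param svm_kernel,svm_C classifier settings.
#' @param eb use empirical-Bayes shrinkage in batch correction.
#' @param paper_mode if `TRUE`, batch correction, DE screening and network
#'   construction use all samples (the study-style transductive procedure);
#'   the default `FALSE` estimates everything from the training split only.
#' @param seed root seed; every stochastic stage derives its seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(test_batch,
                            de_alpha = 0.05, de_lfc = 1,
                            r2_min = 0.85, powers = 1:20,
                            min_module_size = 30, merge_cor = 0.8,
                            cut_frac = 0.99,
                            gs_min = 0.5, mm_min = 0.8, top_n_hubs = 10,
                            latent_dim = 10, vae_epochs = 6,
                            vae_batch_size = 20, vae_learning_rate = 5e-4,
                            kl_weight = 1,
                            svm_kernel = "linear", svm_C = 1,
                            eb = TRUE, paper_mode = FALSE, seed = 1) {
  stopifnot(de_alpha > 0, de_alpha < 1, de_lfc > 0, r2_min > 0, r2_min < 1,
            min_module_size >= 2, merge_cor > 0, merge_cor <= 1,
            gs_min >= 0, gs_min <= 1, mm_min >= 0, mm_min <= 1,
            top_n_hubs >= 1, latent_dim >= 1, vae_epochs >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full two-step feature-extraction and classification pipeline
#'
#' Stages: log-scale check, held-out split, batch correction, PCA QC, DE
#' screen, co-expression network (soft threshold, TOM, module detection,
#' eigengene merging, module-trait correlation, key module), hub-gene
#' screen, VAE latent features, feature fusion, SVM training and held-out
#' evaluation (with hubs-only and latents-only ablations).
#'
#' In the default strict mode every model-fitting stage (DE, network, hubs,
#' VAE, feature scaling, SVM) sees training samples only; the held-out batch
#' is aligned to the corrected training reference by a per-gene
#' location/scale map and only ever touches test-side features.
#'
#' @param x an [expression_matrix()] (e.g. from [generate_expression()] or
#'   [read_expression()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for stage artifacts (TSV tables and a
#'   metrics JSON).
#' @return A list with elements `beta`, `scan`, `de`, `labels`, `me`,
#'   `trait_cor`, `key_module`, `hubs`, `vae`, `report`, `ablations`,
#'   `counts`, `pca_before`, `pca_after`, `config`.
#' @export
run_pipeline <- function(x, config, out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(what) message(sprintf("[%5.1fs] %s",
    as.numeric(difftime(Sys.time(), t0, units = "secs")), what))

  x <- log2_if_needed(x)
  split <- split_by_batch(x, config$test_batch)
  stage(sprintf("split: %d train / %d test samples (test batch '%s')",
                length(split$train), length(split$test), config$test_batch))

  ## ---- batch correction -------------------------------------------------
  if (config$paper_mode) {
    xc <- correct_batch(x, eb = config$eb)
    xtr <- subset_samples(xc, split$train)
    xte <- subset_samples(xc, split$test)
  } else {
    xtr <- correct_batch(subset_samples(x, split$train), eb = config$eb,
                         allow_single = TRUE)
    xte <- align_holdout_batch(xtr, subset_samples(x, split$test))
    xc <- .cbind_expr(xtr, xte, sample_ids(x))
  }
  stage(sprintf("batch correction done (%d genes retained, eb=%s, paper_mode=%s)",
                nrow(xc$values), config$eb, config$paper_mode))
  pca_before <- pca_qc(x, 2)
  pca_after <- pca_qc(xc, 2)

  fit_x <- if (config$paper_mode) xc else xtr

  ## ---- differential expression -----------------------------------------
  de <- moderated_t_test(fit_x)
  de_screen <- screen_de(de, alpha = config$de_alpha, lfc = config$de_lfc)
  stage(sprintf("DE screen (adj.p < %g, |log2FC| > %g): %d genes (%d up, %d down)",
                config$de_alpha, config$de_lfc, length(de_screen$genes),
                de_screen$up, de_screen$down))
  if (length(de_screen$genes) < 2)
    stop("pipeline stage 'diffexpr' failed: fewer than 2 DE genes")

  ## ---- co-expression network -------------------------------------------
  scan <- scan_soft_thresholds(fit_x, powers = config$powers)
  beta <- select_power(scan, r2_min = config$r2_min)
  stage(sprintf("soft threshold: beta = %d (fit R^2 = %.3f)", beta,
                scan$SFT.R.sq[scan$Power == beta]))
  adj <- compute_adjacency(stats::cor(t(fit_x$values)), beta)
  tom <- compute_tom(adj)
  labels0 <- detect_modules(1 - tom, min_size = config$min_module_size,
                            cut_frac = config$cut_frac)
  labels <- merge_modules(fit_x, labels0, threshold = config$merge_cor)
  n_mod <- length(setdiff(unique(labels), "grey"))
  stage(sprintf("modules: %d detected, %d after merging at cor > %g",
                length(setdiff(unique(labels0), "grey")), n_mod,
                config$merge_cor))
  if (n_mod == 0)
    stop("pipeline stage 'coexpnet' failed: no modules detected")
  me <- module_eigengenes(fit_x, labels)
  trait_cor <- module_trait_correlation(me$eigengenes, fit_x$phenotype)
  sizes <- table(labels[labels != "grey"])
  key <- select_key_module(trait_cor, sizes = sizes)
  stage(sprintf("key module '%s' (PCC %.4f)", key,
                trait_cor$PCC[trait_cor$module == key]))

  ## ---- hub genes --------------------------------------------------------
  hub_tab <- hub_gene_table(fit_x, adj, me$eigengenes, labels, key, de)
  hubs <- screen_hubs(hub_tab, de_screen$genes, gs_min = config$gs_min,
                      mm_min = config$mm_min, top_n = config$top_n_hubs)
  stage(sprintf("hub screen: %d hubs returned", nrow(hubs)))

  ## ---- VAE latent features ----------------------------------------------
  de_tr <- subset_genes(xtr, de_screen$genes)
  ctr <- rowMeans(de_tr$values)
  scl <- apply(de_tr$values, 1, stats::sd)
  scl[scl == 0] <- 1
  de_tr$values <- (de_tr$values - ctr) / scl
  vcfg <- vae_config(input_dim = length(de_screen$genes),
                     latent_dim = config$latent_dim,
                     learning_rate = config$vae_learning_rate,
                     batch_size = config$vae_batch_size,
                     epochs = config$vae_epochs,
                     kl_weight = config$kl_weight,
                     seed = config$seed + 101L)
  vae <- train_vae(de_tr, vcfg)
  de_te <- subset_genes(xte, de_screen$genes)
  de_te$values <- (de_te$values - ctr) / scl
  lat_tr <- encode_samples(vae, de_tr)
  lat_te <- encode_samples(vae, de_te)
  stage(sprintf("VAE trained: %d -> %d dims, final loss %.3f",
                vcfg$input_dim, vcfg$latent_dim,
                vae$history$total[vcfg$epochs]))

  ## ---- fused features + SVM ---------------------------------------------
  lat_all <- rbind(lat_tr, lat_te)[sample_ids(xc), , drop = FALSE]
  feats <- build_features(xc, hubs$gene, lat_all, train = split$train)
  labels01 <- xc$phenotype
  model <- train_svm(feats[split$train, , drop = FALSE],
                     labels01[split$train],
                     kernel = config$svm_kernel, C = config$svm_C)
  report <- evaluate_classifier(model, feats[split$test, , drop = FALSE],
                                labels01[split$test])
  ablations <- list()
  for (ab in c("hubs_only", "latents_only")) {
    f <- if (ab == "hubs_only")
      build_features(xc, hubs$gene, NULL, train = split$train)
    else build_features(xc, character(0), lat_all, train = split$train)
    m <- train_svm(f[split$train, , drop = FALSE], labels01[split$train],
                   kernel = config$svm_kernel, C = config$svm_C)
    ablations[[ab]] <- evaluate_classifier(m, f[split$test, , drop = FALSE],
                                           labels01[split$test])
  }
  stage(sprintf("SVM: accuracy %.4f, AUC %.4f (hubs-only %.4f, latents-only %.4f)",
                report$accuracy, report$auc,
                ablations$hubs_only$accuracy, ablations$latents_only$accuracy))

  out <- list(beta = beta, scan = scan, de = de, de_screen = de_screen,
              labels = labels, labels_premerge = labels0, me = me,
              trait_cor = trait_cor, key_module = key, hub_table = hub_tab,
              hubs = hubs, vae = vae, model = model, features = feats,
              report = report, ablations = ablations,
              counts = split$counts, pca_before = pca_before,
              pca_after = pca_after, config = config)
  if (!is.null(out_dir)) .write_artifacts(out, xc, out_dir)
  out
}

.cbind_expr <- function(a, b, order_ids) {
  common <- intersect(gene_ids(a), gene_ids(b))
  vals <- cbind(a$values[common, , drop = FALSE],
                b$values[common, , drop = FALSE])
  batch <- c(a$batch, b$batch)
  phen <- c(a$phenotype, b$phenotype)
  ord <- match(intersect(order_ids, colnames(vals)), colnames(vals))
  expression_matrix(vals[, ord, drop = FALSE], batch[ord], phen[ord])
}

.write_artifacts <- function(out, xc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(out$scan, "soft_threshold_scan.tsv")
  wt(out$de, "de_table.tsv")
  wt(data.frame(gene = names(out$labels), module = out$labels),
     "module_assignment.tsv")
  wt(data.frame(module = rownames(out$me$eigengenes), out$me$eigengenes,
                check.names = FALSE), "module_eigengenes.tsv")
  wt(out$trait_cor, "module_trait.tsv")
  wt(out$hubs, "hub_genes.tsv")
  metrics <- list(
    beta = out$beta,
    n_genes = nrow(xc$values),
    n_de = length(out$de_screen$genes),
    de_up = out$de_screen$up, de_down = out$de_screen$down,
    n_modules = length(setdiff(unique(out$labels), "grey")),
    key_module = out$key_module,
    hubs = out$hubs$gene,
    accuracy = out$report$accuracy, auc = out$report$auc,
    confusion = as.integer(out$report$confusion),
    split = list(counts = as.data.frame(out$counts)),
    ablations = list(
      hubs_only = list(accuracy = out$ablations$hubs_only$accuracy,
                       auc = out$ablations$hubs_only$auc),
      latents_only = list(accuracy = out$ablations$latents_only$accuracy,
                          auc = out$ablations$latents_only$auc)),
    seed = out$config$seed)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
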