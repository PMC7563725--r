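# coexfuse

Two-step feature extraction and classification for case/control gene
expression studies, for bioinformaticians analysing merged multi-cohort
microarray (or microarray-like) data.

High-dimensional expression matrices with small sample sizes overwhelm
classifiers with redundant genes. `coexfuse` reduces them to a compact,
interpretable feature set in two complementary ways and fuses the results:

1. **Hub genes from a weighted co-expression network.** Genes are connected
   by the soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β`, with β
   chosen as the smallest power whose connectivity distribution fits a
   scale-free law with R² > 0.85. Modules are detected by average-linkage
   clustering of the topological-overlap dissimilarity
   `1 − TOM`, `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   merged while module eigengenes (first principal components) correlate
   above 0.8, and the module most correlated with the phenotype is mined
   for hub genes: gene significance `GS = |cor(x_i, phenotype)| > 0.5`,
   module membership `|MM| = |cor(x_i, ME)| > 0.8`, differential
   expression, and finally the top 10 by intramodular connectivity
   `K.in_i = Σ_{j∈module} a_ij`.
2. **A variational-autoencoder latent representation.** The genes passing
   the differential-expression screen (moderated t with empirical-Bayes
   variance shrinkage, Benjamini–Hochberg `adj.p < 0.05`, `|log2FC| > 1`)
   are compressed to 10 latent dimensions by a VAE (mirror architecture
   with two hidden layers, ReLU activations, Adam, lr 0.0005, batch 20,
   6 epochs, reparameterization trick).

The fused 20-feature matrix (10 hub expressions + 10 latent means) feeds a
linear SVM evaluated on a fully held-out batch. Upstream, multi-batch
input is merged on shared gene symbols (duplicate probes collapsed by
median) and batch-corrected with a parametric empirical-Bayes
location/scale model; PCA-based QC verifies the correction. A
synthetic-data generator with planted modules, hub genes, differential
expression and batch effects makes the whole pipeline testable against
known ground truth.

## Worked example

```r
library(coexfuse)

sim <- generate_expression(synthetic_spec(seed = 7))  # reference study
cfg <- pipeline_config(test_batch = "b4", seed = 7)
res <- run_pipeline(sim$expr, cfg)
```

The run log reports every stage on the reference synthetic study
(2,000 genes, 180 samples in 4 batches, 3 planted modules):

```
[  0.0s] split: 138 train / 42 test samples (test batch 'b4')
[  0.3s] batch correction done (2000 genes retained, eb=TRUE, paper_mode=FALSE)
[  0.6s] DE screen (adj.p < 0.05, |log2FC| > 1): 172 genes (165 up, 7 down)
[  4.7s] soft threshold: beta = 7 (fit R^2 = 0.873)
[  7.2s] modules: 3 detected, 3 after merging at cor > 0.8
[  7.2s] key module 'turquoise' (PCC 0.7253)
[  7.3s] hub screen: 10 hubs returned
[  7.3s] VAE trained: 172 -> 10 dims, final loss 250.470
[  7.4s] SVM: accuracy 0.8810, AUC 0.9727 (hubs-only 0.8333, latents-only 0.8810)
```

The module–trait table shows one trait-associated module — the planted
one — and the hub table carries the screening statistics:

```r
res$trait_cor
#>      module      PCC   p.value   n
#> 1 turquoise 0.725322 8.284e-24 138
#> 2      blue 0.002543 9.764e-01 138
#> 3     brown 0.054354 5.266e-01 138

head(res$hubs, 5)
#>     gene logFC adj.P.Val     GS     MM  K.in
#> 1 g00009 3.595 1.043e-17 0.6574 0.9761 71.84
#> 2 g00003 3.558 1.903e-18 0.6695 0.9763 71.30
#> 3 g00005 3.533 4.283e-18 0.6638 0.9746 70.76
#> 4 g00010 3.666 7.969e-19 0.6748 0.9747 70.36
#> 5 g00006 3.593 1.191e-17 0.6563 0.9718 69.36
```

All ten returned hubs are the ten planted hub genes (`g00001`–`g00010`).
`res$report` holds the held-out evaluation: accuracy 0.8810, AUC 0.9727
here — the default study's trait effect leaves irreducible factor noise, so
held-out accuracy saturates near pnorm(1) ≈ 0.84 for module-derived
features. On the stronger-signal variant (`strong_signal_spec(seed = 106)`)
the same pipeline reaches accuracy 0.9762 with AUC 1.0 on the 42 held-out
samples.

The `vignettes/methods.Rmd` vignette documents the models, the parameter
defaults, the leakage policy (training-only estimation by default,
`paper_mode = TRUE` for the transductive variant), and the generator's
assumptions and limitations.

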