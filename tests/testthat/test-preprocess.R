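test_that("duplicate probes collapse to their per-sample median", {
  v <- matrix(c(2, 10, 4, 20, 6, 30,    # three probes of the same symbol
                1, 1), 4, 2, byrow = TRUE,
              dimnames = list(c("gA", "gA", "gA", "gB"), c("s1", "s2")))
  x <- list(values = v, batch = rep("b1", 2), phenotype = c(0L, 1L))
  m <- merge_datasets(list(x))
  expect_equal(m$values["gA", ], c(s1 = 4, s2 = 20))
  expect_equal(m$values["gB", ], c(s1 = 1, s2 = 1))
})

test_that("merging is identity for one clean dataset and errors sensibly", {
  x <- toy_expr(matrix(stats::rnorm(20), 4, 5))
  expect_equal(merge_datasets(list(x))$values, x$values)
  y <- toy_expr(matrix(stats::rnorm(20), 4, 5))
  rownames(y$values) <- paste0("other", 1:4)
  expect_error(merge_datasets(list(x, y)), "empty gene intersection")
  z <- toy_expr(matrix(stats::rnorm(20), 4, 5))  # same sample ids as x
  expect_error(merge_datasets(list(x, z)), "duplicate sample ids")
})

test_that("merged matrices intersect genes and concatenate samples", {
  a <- toy_expr(matrix(1:12, 4, 3,
                       dimnames = list(paste0("g", 1:4), paste0("a", 1:3))),
                batch = rep("b1", 3))
  b <- toy_expr(matrix(1:9, 3, 3,
                       dimnames = list(paste0("g", 2:4), paste0("b", 1:3))),
                batch = rep("b2", 3))
  m <- merge_datasets(list(a, b))
  expect_identical(gene_ids(m), paste0("g", 2:4))
  expect_identical(sample_ids(m), c(paste0("a", 1:3), paste0("b", 1:3)))
  expect_identical(unique(m$batch), c("b1", "b2"))
})

test_that("linear-scale batches are detected and log2-transformed", {
  v <- cbind(matrix(10, 3, 2), matrix(c(1023, 20000, 3, 15, 1, 7), 3, 2))
  dimnames(v) <- list(paste0("g", 1:3), paste0("s", 1:4))
  x <- expression_matrix(v, rep(c("log", "lin"), each = 2), c(0L, 1L, 0L, 1L))
  y <- log2_if_needed(x)
  expect_equal(unname(attr(y, "log2_applied")), c(FALSE, TRUE))
  expect_equal(y$values["g1", "s3"], 10)          # log2(1023 + 1)
  expect_equal(y$values["g1", "s1"], 10)          # untouched log-scale batch
  # max 15.8 -> heuristic says already log scale
  z <- toy_expr(matrix(15.8, 2, 4))
  expect_equal(log2_if_needed(z)$values, z$values)
  neg <- toy_expr(matrix(c(-1, 100, 3, 4, 5, 6, 7, 8), 2, 4))
  expect_error(log2_if_needed(neg), "negative")
})

test_that("standardization yields exact zero-mean unit-sd rows", {
  x <- toy_expr(rbind(c(1, 2, 3), c(5, 5, 5), c(0, 10, 20)))
  expect_warning(s <- standardize(x), "constant")
  expect_equal(nrow(s$values), 2L)
  expect_equal(unname(s$values[1, ]), c(-1, 0, 1))   # sample-sd convention
  expect_lt(max(abs(rowMeans(s$values))), 1e-12)
  expect_lt(max(abs(apply(s$values, 1, stats::sd) - 1)), 1e-12)
  expect_error(standardize(toy_expr(matrix(3, 2, 3))), "constant")
})

test_that("a pure location shift is removed exactly without shrinkage", {
  set.seed(42)
  G <- 50; n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  phen <- rep(c(0L, 1L), n / 2)
  # residuals exactly centered/scaled within each batch so the location
  # model is exact
  base <- matrix(0, G, n, dimnames = list(sprintf("g%02d", 1:G),
                                          sprintf("s%02d", 1:n)))
  for (b in unique(batch)) {
    cols <- batch == b
    r <- matrix(stats::rnorm(G * sum(cols)), G)
    r <- (r - rowMeans(r)) / apply(r, 1, stats::sd)
    base[, cols] <- r
  }
  shift <- stats::rnorm(G, 0, 2)
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + shift
  x <- expression_matrix(shifted, batch, phen)
  cx <- correct_batch(x, eb = FALSE)
  # batch means agree under the full location/scale adjustment
  for (g in 1:G) {
    m1 <- mean(cx$values[g, batch == "b1"])
    m2 <- mean(cx$values[g, batch == "b2"])
    expect_lt(abs(m1 - m2), 1e-8)
  }
  # the location-only model removes a pure location shift exactly
  cl <- correct_batch(x, eb = FALSE, mean_only = TRUE)
  recovered <- cl$values - rowMeans(cl$values)
  expect_lt(max(abs(recovered - base)), 1e-6)
})

test_that("batch correction rejects degenerate designs", {
  x <- toy_expr(matrix(stats::rnorm(40), 4, 10))
  expect_error(correct_batch(x), ">= 2 batches")
  expect_identical(correct_batch(x, allow_single = TRUE), x)
  y <- toy_expr(matrix(stats::rnorm(40), 4, 10),
                batch = c(rep("b1", 9), "lonely"))
  expect_error(correct_batch(y), "lonely")
})

test_that("batch structure is removed from synthetic data", {
  sim <- generate_expression(synthetic_spec(seed = 13))
  before <- batch_f_frac(sim$expr)
  expect_gt(before, 0.5)
  cx <- correct_batch(sim$expr)
  after <- batch_f_frac(cx)
  expect_lt(after, 0.12)
  # shape and per-gene moments preserved by the rescaling step
  expect_equal(dim(cx$values), dim(sim$expr$values))
  expect_equal(rowMeans(cx$values), rowMeans(sim$expr$values),
               tolerance = 0.05)
})

test_that("the EB adjustment matches the reference ComBat implementation", {
  sim <- generate_expression(small_spec(seed = 21))
  ours <- correct_batch(sim$expr, eb = TRUE)
  ref <- sva::ComBat(dat = sim$expr$values, batch = sim$expr$batch,
                     mod = stats::model.matrix(~ sim$expr$phenotype))
  expect_equal(ours$values, ref, tolerance = 1e-6)
})

test_that("PCA QC exposes and then loses batch separability", {
  sim <- generate_expression(synthetic_spec(seed = 17))
  qc1 <- pca_qc(sim$expr, 2)
  ev <- attr(qc1, "explained_variance")
  expect_true(all(diff(ev) <= 0) && sum(ev) <= 1)
  nearest_centroid_acc <- function(qc) {
    sc <- as.matrix(qc[, c("PC1", "PC2")])
    cents <- apply(sc, 2, function(cl) tapply(cl, qc$batch, mean))
    d <- as.matrix(stats::dist(rbind(cents, sc)))[-(1:nrow(cents)), 1:nrow(cents)]
    mean(rownames(cents)[apply(d, 1, which.min)] == qc$batch)
  }
  acc_before <- nearest_centroid_acc(qc1)
  qc2 <- pca_qc(correct_batch(sim$expr), 2)
  acc_after <- nearest_centroid_acc(qc2)
  expect_gt(acc_before, 0.5)
  expect_lt(acc_after, 0.45)     # 4 batches: chance is 0.25
  # duplicated samples get identical scores
  v <- matrix(stats::rnorm(40), 8, 5)
  v <- cbind(v, v[, 1])
  colnames(v) <- paste0("s", 1:6); rownames(v) <- paste0("g", 1:8)
  qc <- pca_qc(expression_matrix(v, rep("b1", 6), rep(0:1, 3)), 2)
  expect_equal(unlist(qc[6, c("PC1", "PC2")]), unlist(qc[1, c("PC1", "PC2")]),
               tolerance = 1e-10)
})

test_that("holdout alignment maps the test batch onto the train reference", {
  sim <- generate_expression(small_spec(seed = 31))
  sp <- split_by_batch(sim$expr, "b4")
  tr <- correct_batch(subset_samples(sim$expr, sp$train))
  te <- align_holdout_batch(tr, subset_samples(sim$expr, sp$test))
  expect_equal(rowMeans(te$values), rowMeans(tr$values), tolerance = 1e-10)
  expect_identical(sample_ids(te), sample_ids(sim$expr)[sp$test])
})
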