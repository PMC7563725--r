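test_that("TOM matches a brute-force oracle on random adjacencies", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(3:8, 1)
    a <- matrix(stats::runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(compute_tom(a), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("TOM boundary cases: complete and empty graphs", {
  ones <- matrix(1, 5, 5)
  expect_true(all(compute_tom(ones) == 1))
  empty <- diag(5)
  t2 <- compute_tom(empty)
  expect_true(all(t2[upper.tri(t2)] == 0))
  expect_true(all(diag(t2) == 1))
  bad <- matrix(stats::runif(16), 4, 4)
  expect_error(compute_tom(bad), "symmetric")
})

test_that("adjacency respects the power transform and monotonicity", {
  set.seed(3)
  x <- toy_expr(matrix(stats::rnorm(200), 20, 10))
  cc <- stats::cor(t(x$values))
  a1 <- compute_adjacency(cc, 1)
  expect_equal(a1[upper.tri(a1)], abs(cc)[upper.tri(cc)])
  a2 <- compute_adjacency(cc, 2)
  expect_true(all(a2[upper.tri(a2)] <= a1[upper.tri(a1)] + 1e-15))
  scan <- scan_soft_thresholds(x, powers = 1:6)
  expect_true(all(diff(scan$mean.k) <= 0))
  expect_true(all(scan$max.k >= scan$median.k))
})

test_that("an exact discrete power law yields a near-perfect fit", {
  gamma <- 2.2
  ks <- 1:10
  counts <- round(1e5 * ks^(-gamma))
  k <- rep(ks, counts)
  f <- scale_free_fit(k, nbins = 10)
  expect_gt(f$r_squared, 0.999)
  expect_equal(f$slope, -gamma, tolerance = 0.05)
})

test_that("power selection follows the smallest-qualifying rule", {
  scan <- data.frame(Power = 1:8,
                     SFT.R.sq = c(0.2, 0.5, 0.7, 0.84, 0.88, 0.9, 0.95, 0.96),
                     slope = rep(-1, 8))
  expect_equal(select_power(scan, 0.85), 5)
  scan$SFT.R.sq <- scan$SFT.R.sq / 2
  expect_warning(b <- select_power(scan, 0.85), "threshold")
  expect_equal(b, 8)
  # positive-slope fits never qualify
  scan2 <- data.frame(Power = 1:2, SFT.R.sq = c(0.99, 0.9), slope = c(1, -1))
  expect_equal(select_power(scan2, 0.85), 2)
})

test_that("block-structured dissimilarity yields exactly the planted modules", {
  n <- 100
  d <- matrix(1, n, n)
  d[1:50, 1:50] <- 0
  d[51:100, 51:100] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("g%03d", 1:n)
  lab <- detect_modules(d, min_size = 30)
  expect_setequal(unique(lab), c("turquoise", "blue"))
  expect_equal(unname(table(lab)), c(50L, 50L), ignore_attr = TRUE)
  expect_true(all(lab[1:50] == lab[1]) && all(lab[51:100] == lab[51]))
  # raising the minimum size greys everything out
  lab2 <- detect_modules(d, min_size = 60)
  expect_true(all(lab2 == "grey"))
  expect_warning(detect_modules(d, min_size = 200), "grey")
})

test_that("eigengenes equal the SVD oracle and are orientation-fixed", {
  set.seed(5)
  for (r in 1:5) {
    v <- matrix(stats::rnorm(200), 20, 10)
    x <- toy_expr(v)
    lab <- stats::setNames(rep(c("turquoise", "blue"), each = 10), gene_ids(x))
    me <- module_eigengenes(x, lab)
    for (mod in c("turquoise", "blue")) {
      sub <- v[lab == mod, ]
      std <- t(scale(t(sub)))
      pc <- stats::prcomp(t(std), center = FALSE)
      oracle <- pc$x[, 1] / sqrt(sum(pc$x[, 1]^2))
      got <- me$eigengenes[paste0("ME", mod), ]
      expect_equal(abs(unname(got)), abs(unname(oracle)), tolerance = 1e-10)
      expect_gte(stats::cor(got, colMeans(std)), 0)
      expect_equal(unname(me$var_explained[mod]),
                   pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-10)
    }
  }
})

test_that("a module of identical genes is summarized losslessly", {
  row <- stats::rnorm(12)
  v <- rbind(row, row, row, row + 1)
  rownames(v) <- paste0("g", 1:4); colnames(v) <- paste0("s", 1:12)
  x <- toy_expr(v)
  lab <- stats::setNames(rep("turquoise", 4), gene_ids(x))
  me <- module_eigengenes(x, lab)
  expect_equal(unname(me$var_explained["turquoise"]), 1, tolerance = 1e-12)
  expect_gt(abs(stats::cor(me$eigengenes[1, ], row)), 1 - 1e-12)
  # degenerate module is refused by name
  v[1, ] <- 3
  expect_error(module_eigengenes(toy_expr(v), lab), "turquoise")
})

test_that("modules from one latent factor merge; distinct ones do not", {
  set.seed(9)
  n <- 40
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  mk <- function(f, g) t(sapply(seq_len(g), function(i)
    stats::runif(1, 0.8, 1.2) * f + stats::rnorm(n, 0, 0.3)))
  v <- rbind(mk(f1, 15), mk(f1, 12), mk(f2, 15))
  rownames(v) <- sprintf("g%03d", 1:42); colnames(v) <- sprintf("s%03d", 1:n)
  x <- toy_expr(v)
  lab <- stats::setNames(rep(c("turquoise", "blue", "brown"), c(15, 12, 15)),
                         gene_ids(x))
  merged <- merge_modules(x, lab, threshold = 0.8)
  mods <- setdiff(unique(merged), "grey")
  expect_length(mods, 2)
  expect_length(unique(merged[1:27]), 1)           # same factor -> merged
  expect_false(merged[1] == merged[28])            # distinct factor survives
  me <- module_eigengenes(x, merged)$eigengenes
  cc <- stats::cor(t(me)); diag(cc) <- 0
  expect_lte(max(cc), 0.8)
  # labels below the threshold stay untouched
  merged2 <- merge_modules(x, merged, threshold = 0.8)
  expect_identical(merged2, merged)
})

test_that("module-trait correlation matches its closed form", {
  set.seed(2)
  phen <- rep(c(0L, 1L), each = 10)
  me <- rbind(MEturquoise = as.numeric(phen),
              MEblue = rep(c(1, -1), 10))
  me[1, ] <- me[1, ] + stats::rnorm(20, 0, 1e-9)
  tc <- module_trait_correlation(me, phen)
  expect_equal(tc$PCC[1], 1, tolerance = 1e-6)
  expect_lt(tc$p.value[1], 1e-12)
  expect_equal(tc$PCC[2], 0, tolerance = 1e-9)
  expect_gt(tc$p.value[2], 0.99)
  # r exactly 0.5 at n = 20: closed form gives p = 0.0247697
  n <- 20
  phen2 <- rep(c(0L, 1L), each = n / 2)
  phc <- scale(phen2)[, 1]
  set.seed(8)
  w <- stats::rnorm(n)
  w <- stats::residuals(stats::lm(w ~ phc))        # orthogonal to the trait
  w <- w / stats::sd(w)
  v <- phc + sqrt(3) * w                            # cor(v, phen2) = 0.5
  me2 <- rbind(MEturquoise = v)
  tc2 <- module_trait_correlation(me2, phen2)
  expect_equal(tc2$PCC, 0.5, tolerance = 1e-10)
  expect_equal(tc2$p.value,
               2 * stats::pt(-0.5 * sqrt(n - 2) / sqrt(0.75), n - 2),
               tolerance = 1e-10)
  expect_equal(tc2$p.value, 0.0247697, tolerance = 1e-5)
})

test_that("the key module maximizes |PCC| with deterministic tie-breaks", {
  tc <- data.frame(
    module = c("tan", "brown", "turquoise", "blue", "green", "purple"),
    PCC = c(-0.1285, -0.3052, -0.9251, -0.7075, -0.2017, 0.3457),
    p.value = c(0.0920, 0, 0, 0, 0.0078, 0))
  expect_equal(select_key_module(tc), "turquoise")
  expect_equal(select_key_module(tc[1, , drop = FALSE]), "tan")
  tie <- data.frame(module = c("a", "b"), PCC = c(0.9, -0.9),
                    p.value = c(0.01, 0.001))
  expect_equal(select_key_module(tie), "b")
  sz <- c(a = 10, b = 50)
  tie2 <- data.frame(module = c("a", "b"), PCC = c(0.9, -0.9),
                     p.value = c(0.01, 0.01))
  expect_equal(select_key_module(tie2, sizes = sz), "b")
})
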