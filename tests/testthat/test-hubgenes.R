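test_that("gene significance is the absolute trait correlation", {
  phen <- rep(c(0L, 1L), each = 6)
  v <- rbind(as.numeric(phen), -as.numeric(phen), stats::rnorm(12), rep(2, 12))
  rownames(v) <- paste0("g", 1:4); colnames(v) <- paste0("s", 1:12)
  x <- expression_matrix(v, rep("b1", 12), phen)
  expect_warning(gs <- gene_significance(x), "constant")
  expect_equal(unname(gs[1:2]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(gs["g4"]), 0)
  expect_true(all(gs >= 0 & gs <= 1))
})

test_that("max GS over independent null genes matches a permutation null", {
  set.seed(31)
  phen <- rep(c(0L, 1L), each = 15)
  n_rep <- 100
  got <- oracle <- numeric(n_rep)
  for (r in 1:n_rep) {
    v <- matrix(stats::rnorm(500 * 30), 500, 30)
    rownames(v) <- sprintf("g%03d", 1:500); colnames(v) <- sprintf("s%02d", 1:30)
    got[r] <- max(gene_significance(expression_matrix(v, rep("b1", 30), phen)))
    # independent oracle: same construction with a permuted trait
    oracle[r] <- max(abs(stats::cor(t(matrix(stats::rnorm(500 * 30), 500, 30)),
                                    sample(phen))))
  }
  expect_gt(suppressWarnings(stats::ks.test(got, oracle))$p.value, 0.01)
})

test_that("signed module membership keeps its sign", {
  set.seed(4)
  f <- stats::rnorm(15)
  v <- rbind(2 * f, -3 * f, stats::rnorm(15))
  rownames(v) <- paste0("g", 1:3); colnames(v) <- paste0("s", 1:15)
  x <- toy_expr(v)
  lab <- stats::setNames(c("turquoise", "turquoise", "grey"), gene_ids(x))
  me <- rbind(MEturquoise = f / sqrt(sum(f^2)))
  colnames(me) <- sample_ids(x)
  mm <- signed_kme(x, me, lab)
  expect_equal(unname(mm[1]), 1, tolerance = 1e-10)
  expect_equal(unname(mm[2]), -1, tolerance = 1e-10)
  expect_true(is.na(mm[3]))
})

test_that("intramodular connectivity matches the brute-force oracle", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    a <- matrix(stats::runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 1
    rownames(a) <- colnames(a) <- sprintf("g%02d", 1:n)
    lab <- stats::setNames(sample(c("turquoise", "blue", "grey"), n, TRUE),
                           rownames(a))
    got <- intramodular_connectivity(a, lab)
    expect_equal(got, kin_oracle(a, lab), tolerance = 1e-12)
    # K.in never exceeds whole-network connectivity
    k <- connectivity(a)
    ok <- !is.na(got)
    expect_true(all(got[ok] <= k[ok] + 1e-12))
  }
  # complete module: m - 1 each; disconnected module: 0
  m <- 6
  a1 <- matrix(1, m, m); rownames(a1) <- colnames(a1) <- paste0("g", 1:m)
  lab1 <- stats::setNames(rep("turquoise", m), rownames(a1))
  expect_true(all(intramodular_connectivity(a1, lab1) == m - 1))
  a0 <- diag(m); dimnames(a0) <- dimnames(a1)
  expect_true(all(intramodular_connectivity(a0, lab1) == 0))
})

test_that("the hub screen enforces thresholds, ordering, and determinism", {
  tab <- data.frame(
    gene = c("CDK4x", "CDH3x", "weakGS", "weakMM", "notDE", "negMM"),
    logFC = c(1.3, 6.4, 2, 2, 2, -6.4),
    adj.P.Val = rep(1e-20, 6),
    GS = c(0.81, 0.94, 0.45, 0.9, 0.8, 0.87),
    MM = c(-0.91, -0.92, 0.95, 0.7, 0.9, 0.91),
    K.in = c(933.8, 922.2, 999, 998, 997, 895.3))
  de <- setdiff(tab$gene, "notDE")
  hubs <- suppressMessages(screen_hubs(tab, de, top_n = 10))
  expect_warning(suppressMessages(screen_hubs(tab, de, top_n = 10)), "survive")
  expect_equal(hubs$gene, c("CDK4x", "CDH3x", "negMM"))  # by K.in, |MM| kept
  expect_true(all(hubs$GS > 0.5 & abs(hubs$MM) > 0.8))
  # row order of the input does not matter
  perm <- tab[c(4, 6, 1, 3, 5, 2), ]
  hubs2 <- suppressWarnings(suppressMessages(screen_hubs(perm, de, top_n = 10)))
  expect_equal(hubs2$gene, hubs$gene)
  # K.in ties broken by GS, then gene id
  tie <- data.frame(gene = c("b", "a", "c"), logFC = 2, adj.P.Val = 1e-9,
                    GS = c(0.7, 0.7, 0.9), MM = 0.95, K.in = 5)
  h3 <- suppressMessages(screen_hubs(tie, tie$gene, top_n = 3))
  expect_equal(h3$gene, c("c", "a", "b"))
})

test_that("GS and MM are invariant to per-gene affine rescaling", {
  sim <- generate_expression(small_spec(seed = 23))
  x <- correct_batch(sim$expr)
  lab <- stats::setNames(
    sim$truth$module_assignment[gene_ids(x)], gene_ids(x))
  lab[lab == "none"] <- "grey"
  lab[lab == "module1"] <- "turquoise"; lab[lab == "module2"] <- "blue"
  me <- module_eigengenes(x, lab)
  y <- x
  sc <- stats::runif(nrow(y$values), 0.5, 3)
  y$values <- y$values * sc + stats::rnorm(nrow(y$values))
  expect_equal(gene_significance(x), gene_significance(y), tolerance = 1e-10)
  me_y <- module_eigengenes(y, lab)
  expect_equal(signed_kme(x, me$eigengenes, lab),
               signed_kme(y, me_y$eigengenes, lab), tolerance = 1e-8)
})

test_that("planted hubs rank first by intramodular connectivity", {
  sim <- generate_expression(small_spec(seed = 29))
  x <- correct_batch(sim$expr)
  de <- moderated_t_test(x)
  scr <- screen_de(de)
  beta <- select_power(scan_soft_thresholds(x))
  adj <- compute_adjacency(stats::cor(t(x$values)), beta)
  tom <- compute_tom(adj)
  lab <- merge_modules(x, detect_modules(1 - tom))
  me <- module_eigengenes(x, lab)
  tc <- module_trait_correlation(me$eigengenes, x$phenotype)
  key <- select_key_module(tc, table(lab[lab != "grey"]))
  tab <- hub_gene_table(x, adj, me$eigengenes, lab, key, de)
  hubs <- suppressMessages(screen_hubs(tab, scr$genes, top_n = 5))
  expect_gte(sum(hubs$gene %in% sim$truth$hub_genes$module1), 4)
})
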