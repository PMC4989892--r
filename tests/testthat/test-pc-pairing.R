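test_that("loading standardization z-scores with the population divisor", {
  expect_equal(unname(standardize_loadings(matrix(c(1, -1), 2, 1))[, 1]),
               c(1, -1))
  expect_equal(unname(standardize_loadings(matrix(c(2, 0), 2, 1))[, 1]),
               c(1, -1))
  expect_error(standardize_loadings(matrix(c(3, 3), 2, 1)), "degenerate")
  # every column: mean 0, population sd 1
  set.seed(5)
  z <- standardize_loadings(matrix(rnorm(60), 12, 5))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(colMeans(z^2) - 1)), 1e-10)
})

test_that("loading correlations match the textbook Pearson correlation", {
  set.seed(8)
  e <- make_design_omics(matrix(rnorm(24 * 40), 40, 24))
  m <- make_design_omics(matrix(rnorm(24 * 40), 40, 24), "methylation")
  de <- embed_features(e, 5)
  dm <- embed_features(m, 5)
  lc <- loading_correlation(de, dm, 5)
  expect_equal(dim(lc$rho), c(10L, 10L))
  expect_lt(max(abs(lc$rho - t(lc$rho))), 1e-12)
  expect_equal(unname(diag(lc$rho)), rep(1, 10))
  expect_lte(max(abs(lc$rho)), 1 + 1e-12)
  both <- cbind(de$loadings, dm$loadings)
  expect_lt(max(abs(lc$rho - unname(cor(both)))), 1e-10)
  # identical columns correlate at exactly 1
  lc_self <- loading_correlation(de, de, 5,
                                 labelsB = paste0("PC", 1:5, "b"))
  expect_equal(unname(lc_self$rho[cbind(1:5, 6:10)]), rep(1, 5))
  # orthogonal loading columns of one decomposition correlate near 0 only
  # after standardization removes the mean -- check the defining formula
  zA <- standardize_loadings(de$loadings[, 1:5])
  expect_equal(unname(lc$rho[1:5, 1:5]), unname(crossprod(zA) / 24),
               tolerance = 1e-12)
})

test_that("rho is invariant to loading sign flips when used as |rho|", {
  set.seed(9)
  e <- make_design_omics(matrix(rnorm(24 * 30), 30, 24))
  m <- make_design_omics(matrix(rnorm(24 * 30), 30, 24), "methylation")
  de <- embed_features(e, 3)
  dm <- embed_features(m, 3)
  lc1 <- loading_correlation(de, dm, 3)
  de$loadings[, 2] <- -de$loadings[, 2]
  lc2 <- loading_correlation(de, dm, 3)
  expect_equal(abs(lc1$rho), abs(lc2$rho), tolerance = 1e-12)
})

test_that("UPGMA reproduces the hand-worked three-leaf tree", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- -0.9
  d["A", "C"] <- d["C", "A"] <- -0.2
  d["B", "C"] <- d["C", "B"] <- -0.1
  tree <- upgma(d)
  expect_equal(tree$height, c(-0.9, -0.15))
  sib <- sibling_leaf_pairs(tree)
  expect_equal(sort(c(sib$label1, sib$label2)), c("A", "B"))

  two <- matrix(c(0, -0.4, -0.4, 0), 2, 2,
                dimnames = list(c("X", "Y"), c("X", "Y")))
  t2 <- upgma(two)
  expect_equal(t2$height, -0.4)

  asym <- d; asym["A", "B"] <- -0.5
  expect_error(upgma(asym), "symmetric")
})

test_that("UPGMA equals the brute-force oracle and heights are monotone", {
  set.seed(13)
  for (trial in 1:20) {
    n <- sample(3:6, 1)
    r <- matrix(runif(n * n), n)
    d <- -(abs(r + t(r)) / 2)
    diag(d) <- 0
    labs <- paste0("L", seq_len(n))
    dimnames(d) <- list(labs, labs)
    tree <- upgma(d)
    expect_true(all(diff(tree$height) >= -1e-12))
    coph <- as.matrix(stats::cophenetic(tree))[labs, labs]
    expect_equal(coph, upgma_cophenetic_oracle(d), tolerance = 1e-12)
  }
})

test_that("coincident pairs are cross-modality siblings ordered by |rho|", {
  labs <- c("PC1", "PC2", "PC1M", "PC2M")
  rho <- diag(4)
  dimnames(rho) <- list(labs, labs)
  rho["PC1", "PC1M"] <- rho["PC1M", "PC1"] <- 0.95
  rho["PC2", "PC2M"] <- rho["PC2M", "PC2"] <- -0.6
  rho["PC1", "PC2"] <- rho["PC2", "PC1"] <- 0.1
  lc <- structure(list(rho = rho, labels = labs,
                       modality = c("expression", "expression",
                                    "methylation", "methylation"),
                       K = 2, J = 24),
                  class = "loading_correlation")
  pairs <- find_coincident_pairs(upgma(-abs(rho)), lc)
  expect_equal(pairs$expression_pc, c("PC1", "PC2"))
  expect_equal(pairs$methylation_pc, c("PC1M", "PC2M"))
  expect_equal(pairs$rho, c(0.95, -0.6))

  # same-modality sibling pairs are excluded
  rho2 <- diag(4)
  dimnames(rho2) <- list(labs, labs)
  rho2["PC1", "PC2"] <- rho2["PC2", "PC1"] <- 0.99
  lc2 <- lc; lc2$rho <- rho2
  pairs2 <- find_coincident_pairs(upgma(-abs(rho2)), lc2)
  expect_false(any(pairs2$expression_pc == "PC1" &
                     pairs2$methylation_pc == "PC2"))

  # mutual nearest neighbour variant agrees on the clear-cut pairing
  mn <- find_coincident_pairs(upgma(-abs(rho)), lc, method = "mutual_nn")
  expect_true(all(c("PC1", "PC2") %in% mn$expression_pc))
})

test_that("the top cross-modality sibling pair is the planted one", {
  hits <- 0
  for (seed in 1:20) {
    syn <- generate_paired_omics(synthetic_config(
      seed = seed, I = 1000, n_planted = 30))
    if (isTRUE(planted_recovery(syn)$pair_is_shared)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("greedy relabeling is a bijection onto the full-sample labels", {
  set.seed(17)
  for (trial in 1:10) {
    K <- sample(3:6, 1)
    a <- standardize_loadings(matrix(rnorm(23 * K), 23, K))
    b <- standardize_loadings(matrix(rnorm(23 * K), 23, K))
    labs <- paste0("PC", seq_len(K))
    out <- pcafe:::greedy_relabel(a, b, labs)
    expect_setequal(out, labs)
  }
})

test_that("leave-one-out conservation is perfect without noise and vacuous without targets", {
  syn <- generate_paired_omics(synthetic_config(
    seed = 2, I = 800, n_planted = 30, noise_sd = 0,
    category_effect_sd = 0))
  de <- embed_features(syn$expression, 5)
  dm <- embed_features(syn$methylation, 5)
  lc <- loading_correlation(de, dm, 5)
  pairs <- find_coincident_pairs(upgma(cor_distance(lc)), lc)
  st <- loo_stability(syn$expression, syn$methylation, 5, head(pairs, 1))
  expect_equal(st$count, 24L)

  empty <- pairs[0, ]
  st0 <- loo_stability(syn$expression, syn$methylation, 5, empty)
  expect_equal(st0$count, 24L)
  expect_error(loo_stability(syn$expression, syn$methylation, K = 24,
                             head(pairs, 1)),
               "parameter error")
})

test_that("conservation stays high under the default noise level", {
  counts <- vapply(1:10, function(seed) {
    syn <- generate_paired_omics(synthetic_config(seed = seed, I = 2000))
    de <- embed_features(syn$expression, 5)
    dm <- embed_features(syn$methylation, 5)
    lc <- loading_correlation(de, dm, 5)
    pairs <- find_coincident_pairs(upgma(cor_distance(lc)), lc)
    loo_stability(syn$expression, syn$methylation, 5,
                  head(pairs, 1))$count
  }, numeric(1))
  expect_gte(median(counts), 20)
})
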