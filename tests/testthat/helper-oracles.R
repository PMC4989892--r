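# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check: the PCA oracle
# uses an eigendecomposition of the sample-space Gram matrix (the
# implementation uses svd of the data matrix), and the UPGMA oracle
# re-averages original leaf distances at every step (the implementation
# uses the running size-weighted update).

make_omics <- function(values, categories = NULL, replicates = NULL,
                       modality = "expression") {
  I <- nrow(values); J <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(I))
  if (is.null(categories)) categories <- paste0("C", seq_len(J))
  if (is.null(replicates)) replicates <- as.integer(ave(seq_len(J),
                                                        categories,
                                                        FUN = seq_along))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(categories, "_r", replicates)
  omics_matrix(values, data.frame(
    sample_id = colnames(values), category = categories,
    replicate = replicates, modality = modality,
    stringsAsFactors = FALSE))
}

# balanced 8x3 design matching the study layout
make_design_omics <- function(values, modality = "expression") {
  J <- ncol(values)
  stopifnot(J %% 3 == 0)
  categories <- rep(paste0("cat", seq_len(J / 3)), each = 3)
  make_omics(values, categories, rep(1:3, J / 3), modality)
}

# Eigendecomposition oracle for the feature-embedding PCA: sample-space
# axes are eigenvectors of crossprod(centered), scores are projections.
pca_oracle <- function(values, K) {
  cx <- sweep(values, 2, colMeans(values))
  eig <- eigen(crossprod(cx), symmetric = TRUE)
  V <- eig$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    i0 <- which.max(abs(V[, k]))
    if (V[i0, k] < 0) V[, k] <- -V[, k]
  }
  list(loadings = V, scores = cx %*% V,
       eigenvalues = eig$values[seq_len(K)])
}

# Brute-force UPGMA oracle: returns the cophenetic distance matrix, with
# cluster-average distances recomputed from the original matrix at every
# step and the same smallest-representative-pair tie-break.
upgma_cophenetic_oracle <- function(d, labels = rownames(d)) {
  n <- nrow(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      key <- paste(sort(c(min(labels[clusters[[i]]]),
                          min(labels[clusters[[j]]]))), collapse = "\r")
      if (dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 && key < best_key)) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# pair of vectors whose sample Pearson correlation is exactly r
make_cor_pair <- function(r, J, seed = 1) {
  set.seed(seed)
  x <- rnorm(J)
  z <- rnorm(J)
  xc <- x - mean(x)
  zc <- z - mean(z)
  zc <- zc - sum(zc * xc) / sum(xc^2) * xc
  y <- r * xc / sqrt(sum(xc^2)) + sqrt(1 - r^2) * zc / sqrt(sum(zc^2))
  list(x = x, y = y)
}

# minimal decomposition wrapper so ranking operations can be driven with
# hand-chosen scores
fake_dec <- function(scores, J = 4) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- matrix(0, J, ncol(scores),
                     dimnames = list(paste0("s", seq_len(J)),
                                     colnames(scores)))
  structure(list(loadings = loadings, scores = scores),
            class = "omics_pca")
}

# vectorized permutation p-values for the one-way F test, shared
# permutation draws across probes
perm_pvalues <- function(x, categories, B, seed) {
  set.seed(seed)
  J <- ncol(x)
  M <- stats::model.matrix(~ 0 + factor(categories))
  n_l <- colSums(M)
  L <- ncol(M)
  df1 <- L - 1; df2 <- J - L
  perm <- t(replicate(B, sample.int(J)))
  vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    grand <- sum(v)
    SST <- sum(v^2) - grand^2 / J
    gs <- as.vector(v %*% M)
    SSB <- sum(gs^2 / n_l) - grand^2 / J
    Fobs <- (SSB / df1) / ((SST - SSB) / df2)
    TS <- matrix(v[perm], B, J) %*% M
    SSBp <- rowSums(sweep(TS^2, 2, n_l, "/")) - grand^2 / J
    Fp <- (SSBp / df1) / ((SST - SSBp) / df2)
    mean(Fp >= Fobs)
  }, numeric(1))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# recovery of the planted probes through the full pair-then-select path
planted_recovery <- function(syn, n = NULL, K = 5) {
  cfg <- syn$truth$config
  if (is.null(n)) n <- 2 * cfg$n_planted
  de <- embed_features(syn$expression, K)
  dm <- embed_features(syn$methylation, K)
  lc <- loading_correlation(de, dm, K)
  pairs <- find_coincident_pairs(upgma(cor_distance(lc)), lc)
  if (nrow(pairs) == 0) return(list(jaccard = 0, pairs = pairs))
  sel <- intersect_directional(de, dm, pairs$expression_pc[1],
                               pairs$methylation_pc[1], n = n)
  # does the selected pair carry the true shared factor?  The planted
  # component of a modality is the one whose loadings correlate most with
  # the true shared sample scores.
  s <- syn$truth$shared_scores
  true_e <- colnames(de$loadings)[which.max(abs(cor(de$loadings, s)))]
  true_m <- colnames(dm$loadings)[which.max(abs(cor(dm$loadings, s)))]
  list(jaccard = jaccard(sel, syn$truth$planted), pairs = pairs,
       pair_is_shared =
         sub("M$", "", pairs$expression_pc[1]) == true_e &&
         sub("M$", "", pairs$methylation_pc[1]) == true_m)
}
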