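# Identification of the coincident expression-methylation component pair.
#
# Sample loadings of each component are z-scored over samples,
#   dc_jk = (c_jk - <c_jk>_j) / <(c_jk - <c_jk>_j)^2>_j^{1/2}
# (population standard deviation, divisor J; correlations are invariant to
# the divisor choice), the correlation rho_kk' = <dc_jk dc_jk'>_j is taken
# over every pair of components of either modality, and -|rho| is used as
# the distance for UPGMA clustering.  Component pairs that appear as
# sibling leaves with one member per modality are the candidate
# biologically coincident pairs, ordered by merge distance.

#' Standardize sample loadings
#'
#' Z-scores each loading column over samples with the population (divisor
#' J) standard deviation, so each column has mean 0 and population sd 1.
#'
#' @param x An `omics_pca` or a numeric loadings matrix (samples x
#'   components).
#' @return Matrix of standardized loadings.
#' @export
standardize_loadings <- function(x) {
  if (inherits(x, "omics_pca")) x <- x$loadings
  x <- as.matrix(x)
  J <- nrow(x)
  if (J < 2) stop("need at least 2 samples")
  mu <- colMeans(x)
  cx <- sweep(x, 2, mu)
  sd_pop <- sqrt(colMeans(cx^2))
  if (any(sd_pop < 1e-12))
    stop("degenerate input: constant loading column ",
         which(sd_pop < 1e-12)[1])
  sweep(cx, 2, sd_pop, "/")
}

#' Correlation matrix of component loadings across modalities
#'
#' Computes rho over the joint label set of the first `K` components of
#' each modality.  Methylation components are tagged with an `M` suffix
#' (`PC3M`), expression components keep plain labels (`PC3`).
#'
#' @param decA Expression decomposition (`omics_pca`).
#' @param decB Methylation decomposition over the same ordered samples.
#' @param K Number of components per modality entering the comparison.
#' @param labelsA,labelsB Optional label overrides (length `K`), used by
#'   the leave-one-out relabeling.
#' @return A `loading_correlation`: list with `rho` (2K x 2K, symmetric,
#'   unit diagonal), `labels`, `modality` per label, and `J`.
#' @export
loading_correlation <- function(decA, decB, K = 5, labelsA = NULL,
                                labelsB = NULL) {
  stopifnot(inherits(decA, "omics_pca"), inherits(decB, "omics_pca"))
  if (!identical(rownames(decA$loadings), rownames(decB$loadings)))
    stop("alignment error: decompositions must share the same ordered ",
         "samples")
  if (K > ncol(decA$loadings) || K > ncol(decB$loadings))
    stop("parameter error: K exceeds the number of components available")
  zA <- standardize_loadings(decA$loadings[, seq_len(K), drop = FALSE])
  zB <- standardize_loadings(decB$loadings[, seq_len(K), drop = FALSE])
  if (is.null(labelsA)) labelsA <- paste0("PC", seq_len(K))
  if (is.null(labelsB)) labelsB <- paste0("PC", seq_len(K), "M")
  labels <- c(labelsA, labelsB)
  if (anyDuplicated(labels)) stop("component labels must be unique")
  Z <- cbind(zA, zB)
  J <- nrow(Z)
  rho <- crossprod(Z) / J
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(labels, labels)
  structure(list(rho = rho, labels = labels,
                 modality = rep(c("expression", "methylation"), each = K),
                 K = K, J = J),
            class = "loading_correlation")
}

#' Correlation distance for clustering
#'
#' @param lc A `loading_correlation`.
#' @return The matrix `-|rho|`, the distance used for UPGMA.
#' @export
cor_distance <- function(lc) {
  stopifnot(inherits(lc, "loading_correlation"))
  -abs(lc$rho)
}

#' UPGMA agglomerative clustering
#'
#' Unweighted pair-group method with arithmetic mean: repeatedly merges
#' the two clusters at minimum average pairwise distance, where the
#' average is the unweighted mean over all original leaf pairs
#' (maintained by the size-weighted update).  Ties are broken by the
#' lexicographically smallest pair of cluster representatives (a cluster
#' is represented by its smallest member label), making the tree
#' deterministic.
#'
#' @param d Symmetric distance matrix (here typically `-|rho|`, entries in
#'   `[-1, 0]`; any symmetric matrix is accepted).
#' @param labels Leaf labels; defaults to `rownames(d)`.
#' @return An object of classes `upgma_tree` and `hclust` (plottable and
#'   convertible with the standard tools), with `merge`, `height`,
#'   `order`, and `labels`.
#' @export
upgma <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves")
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-9)
    stop("input error: distance matrix must be symmetric")
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  active <- seq_len(n)              # positions into dmat
  code <- -seq_len(n)               # hclust codes: -leaf or +merge row
  size <- rep(1L, n)
  rep_label <- labels
  dmat <- d
  diag(dmat) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    sub <- dmat[active, active, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    cand <- which(sub <= mn + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (sorted) representative label pair
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_label[active[ij[1]]], rep_label[active[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    best <- cand[order(keys)[1], ]
    i <- active[best[1]]; j <- active[best[2]]
    height[step] <- dmat[i, j]
    ci <- code[i]; cj <- code[j]
    both_leaf <- ci < 0 && cj < 0
    merge[step, ] <- if (both_leaf || (ci < 0) == (cj < 0))
      sort(c(ci, cj)) else c(min(ci, cj), max(ci, cj))
    # size-weighted average update == unweighted mean over original pairs
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      newd <- (size[i] * dmat[i, others] + size[j] * dmat[j, others]) /
        (size[i] + size[j])
      dmat[i, others] <- newd
      dmat[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    code[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active <- setdiff(active, j)
  }
  tree <- structure(list(merge = merge, height = height,
                         order = tree_order(merge),
                         labels = labels,
                         method = "average",
                         dist.method = "-|rho|",
                         call = match.call()),
                    class = c("upgma_tree", "hclust"))
  tree
}

# left-to-right leaf order implied by the merge matrix
tree_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Export a cluster tree in Newick format
#'
#' Branch lengths derive from merge heights; since the clustering distance
#' `-|rho|` is negative, heights are shifted so the root sits at zero
#' before conversion.
#'
#' @param tree An `upgma_tree`.
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly if written to `path`).
#' @export
upgma_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  shifted <- tree
  shifted$height <- tree$height - min(tree$height) + 1e-8
  phy <- ape::as.phylo(shifted)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Sibling leaf pairs of a cluster tree
#'
#' @param tree An `upgma_tree`/`hclust`.
#' @return Data frame with `label1`, `label2`, `height` for every merge of
#'   two leaves.
#' @export
sibling_leaf_pairs <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  rows <- which(tree$merge[, 1] < 0 & tree$merge[, 2] < 0)
  data.frame(label1 = tree$labels[-tree$merge[rows, 1]],
             label2 = tree$labels[-tree$merge[rows, 2]],
             height = tree$height[rows],
             stringsAsFactors = FALSE)
}

#' Find coincident cross-modality component pairs
#'
#' Returns every sibling leaf pair of the tree whose members come from
#' different modalities, ordered by merge height (smallest distance, i.e.
#' largest |rho|, first).  Optionally, mutual nearest neighbours by |rho|
#' can be used instead of tree siblings as a sensitivity check.
#'
#' @param tree UPGMA tree over the joint component label set.
#' @param lc The `loading_correlation` the tree was built from.
#' @param method `"sibling"` (default) or `"mutual_nn"`.
#' @return Data frame of class `pc_pairs` with columns `expression_pc`,
#'   `methylation_pc`, `rho`, `abs_rho`, `height`; zero rows if no
#'   cross-modality pair exists.
#' @export
find_coincident_pairs <- function(tree, lc,
                                  method = c("sibling", "mutual_nn")) {
  stopifnot(inherits(lc, "loading_correlation"))
  method <- match.arg(method)
  mod <- stats::setNames(lc$modality, lc$labels)
  if (method == "sibling") {
    sib <- sibling_leaf_pairs(tree)
    keep <- mod[sib$label1] != mod[sib$label2]
    sib <- sib[keep, , drop = FALSE]
    expr_first <- mod[sib$label1] == "expression"
    pairs <- data.frame(
      expression_pc = ifelse(expr_first, sib$label1, sib$label2),
      methylation_pc = ifelse(expr_first, sib$label2, sib$label1),
      height = sib$height, stringsAsFactors = FALSE)
  } else {
    e_lab <- lc$labels[lc$modality == "expression"]
    m_lab <- lc$labels[lc$modality == "methylation"]
    a <- abs(lc$rho[e_lab, m_lab, drop = FALSE])
    pairs <- data.frame(expression_pc = character(0),
                        methylation_pc = character(0),
                        height = numeric(0), stringsAsFactors = FALSE)
    for (e in e_lab) {
      m <- m_lab[which.max(a[e, ])]
      if (e_lab[which.max(a[, m])] == e)
        pairs <- rbind(pairs, data.frame(
          expression_pc = e, methylation_pc = m, height = -a[e, m],
          stringsAsFactors = FALSE))
    }
  }
  if (nrow(pairs) > 0) {
    pairs$rho <- lc$rho[cbind(pairs$expression_pc, pairs$methylation_pc)]
    pairs$abs_rho <- abs(pairs$rho)
    pairs <- pairs[order(pairs$height,
                         pairs$expression_pc), , drop = FALSE]
    pairs <- pairs[, c("expression_pc", "methylation_pc", "rho",
                       "abs_rho", "height")]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(expression_pc = character(0),
                        methylation_pc = character(0), rho = numeric(0),
                        abs_rho = numeric(0), height = numeric(0),
                        stringsAsFactors = FALSE)
  }
  class(pairs) <- c("pc_pairs", "data.frame")
  pairs
}

# Greedy bijective assignment between reduced-sample components and
# full-sample component labels by maximum |correlation|.
greedy_relabel <- function(reduced_z, full_z, full_labels) {
  a <- abs(crossprod(reduced_z, full_z)) / nrow(reduced_z)
  K <- ncol(a)
  assignment <- character(K)
  for (step in seq_len(K)) {
    idx <- which(a == max(a), arr.ind = TRUE)[1, ]
    assignment[idx[1]] <- full_labels[idx[2]]
    a[idx[1], ] <- -Inf
    a[, idx[2]] <- -Inf
  }
  assignment
}

#' Leave-one-out stability of a component pairing
#'
#' For each of the J samples, drops that sample from both modalities,
#' recomputes the decompositions, relabels each of the first `K`
#' reduced-sample components with the full-sample component label whose
#' loadings (restricted to the shared J-1 samples, both standardized) have
#' maximum absolute correlation (greedy, highest first, each label used
#' once), rebuilds the UPGMA tree, and counts the subsets in which the
#' target pair(s) reappear as cross-modality sibling pairs.
#'
#' @param expr,meth Aligned `omics_matrix` objects.
#' @param K Components per modality entering the clustering (default 5).
#' @param target_pairs A `pc_pairs` data frame (rows of
#'   [find_coincident_pairs()] output) naming the pairings to track; with
#'   zero rows the criterion is vacuous and every subset counts as
#'   conserved.
#' @param require_all If `TRUE` (default) a subset is conserved only when
#'   every target pair is recovered; otherwise any one suffices.
#' @return List with `count` (0..J), `per_sample` (named logical), and
#'   `pairs_by_subset` (list of recovered `pc_pairs`).
#' @export
loo_stability <- function(expr, meth, K = 5, target_pairs,
                          require_all = TRUE) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(meth, "omics_matrix"))
  J <- ncol(expr$values)
  if (ncol(meth$values) != J ||
      !identical(paste(expr$samples$category, expr$samples$replicate),
                 paste(meth$samples$category, meth$samples$replicate)))
    stop("alignment error: modalities must be aligned (see ",
         "align_modalities)")
  if (K > J - 1) stop("parameter error: K must be at most J - 1")
  full_e <- embed_features(expr, K)
  full_m <- embed_features(meth, K)
  lab_e <- paste0("PC", seq_len(K))
  lab_m <- paste0("PC", seq_len(K), "M")
  conserved <- logical(J)
  pairs_by_subset <- vector("list", J)
  for (j in seq_len(J)) {
    red_e <- embed_features(subset_samples(expr, -j), K)
    red_m <- embed_features(subset_samples(meth, -j), K)
    zfe <- standardize_loadings(full_e$loadings[-j, , drop = FALSE])
    zfm <- standardize_loadings(full_m$loadings[-j, , drop = FALSE])
    new_e <- greedy_relabel(standardize_loadings(red_e), zfe, lab_e)
    new_m <- greedy_relabel(standardize_loadings(red_m), zfm, lab_m)
    lc <- loading_correlation(red_e, red_m, K, labelsA = new_e,
                              labelsB = new_m)
    pairs <- find_coincident_pairs(upgma(cor_distance(lc)), lc)
    pairs_by_subset[[j]] <- pairs
    found <- paste(pairs$expression_pc, pairs$methylation_pc)
    want <- paste(target_pairs$expression_pc, target_pairs$methylation_pc)
    conserved[j] <- if (length(want) == 0) TRUE
      else if (require_all) all(want %in% found)
      else any(want %in% found)
  }
  names(conserved) <- expr$samples$sample_id
  list(count = sum(conserved), per_sample = conserved,
       pairs_by_subset = pairs_by_subset)
}
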