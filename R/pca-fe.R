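# Feature-embedding PCA and directional outlier selection.
#
# In contrast to the usual convention, probes (features), not samples, are
# embedded into the low-dimensional space: the orthonormal axes live in
# sample space (the loadings c_jk) and each probe i receives the score
#   x_ik = sum_j c_jk (x_ij - <x_i'j>_i'),
# i.e. the projection of its per-sample-centered profile onto axis k.

#' Feature-embedding principal component decomposition
#'
#' Each sample column is centered by its mean over probes (no per-probe
#' centering and no variance scaling), and the orthonormal sample-space
#' axes of the centered matrix are computed by singular value
#' decomposition, ordered by decreasing explained variance.  The sign of
#' each loading column is fixed so that its element of largest magnitude
#' is positive; probe scores are the projections onto the (sign-fixed)
#' axes.
#'
#' @param m An [omics_matrix()] with at least 2 probes and 2 samples.
#' @param K Number of components to retain; defaults to `min(I, J)`.
#' @return An object of class `omics_pca`: list with `loadings` (J x K,
#'   columns orthonormal), `scores` (I x K), `d` (singular values),
#'   `var_explained`, `sample_means` (the per-sample means subtracted),
#'   and the sample metadata.
#' @export
embed_features <- function(m, K = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values
  I <- nrow(x); J <- ncol(x)
  if (I < 2 || J < 2)
    stop("need at least 2 probes and 2 samples")
  if (is.null(K)) K <- min(I, J)
  if (K < 1 || K > min(I, J))
    stop("parameter error: K must be in 1..min(I, J) = ", min(I, J))
  mu <- colMeans(x)
  cx <- sweep(x, 2, mu)
  if (max(abs(cx)) < 1e-12)
    stop("degenerate input: centered matrix is identically zero")
  sv <- svd(cx, nu = 0, nv = K)
  V <- sv$v
  for (k in seq_len(K)) {
    i0 <- which.max(abs(V[, k]))
    if (V[i0, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- m$samples$sample_id
  colnames(V) <- paste0("PC", seq_len(K))
  scores <- cx %*% V
  dimnames(scores) <- list(rownames(x), colnames(V))
  structure(list(loadings = V, scores = scores, d = sv$d[seq_len(K)],
                 var_explained = sv$d[seq_len(K)]^2 / sum(sv$d^2),
                 sample_means = mu, samples = m$samples),
            class = "omics_pca")
}

#' @export
print.omics_pca <- function(x, ...) {
  cat("omics_pca: ", nrow(x$scores), " probes, ", nrow(x$loadings),
      " samples, ", ncol(x$loadings), " components\n", sep = "")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

resolve_pc <- function(dec, pc) {
  K <- ncol(dec$loadings)
  if (is.character(pc)) {
    hit <- match(pc, colnames(dec$loadings))
    # accept modality-tagged labels such as "PC3M" from the pairing stage
    if (is.na(hit)) hit <- match(sub("M$", "", pc),
                                 colnames(dec$loadings))
    pc <- hit
  }
  pc <- suppressWarnings(as.integer(pc))
  if (is.na(pc) || pc < 1 || pc > K)
    stop("parameter error: component must be one of PC1..PC", K)
  pc
}

#' Rank probes as directional outliers along one component
#'
#' Probes are ordered by their score on the chosen component: descending
#' for `direction = "larger"`, ascending for `"smaller"`.  Ties are broken
#' by probe identifier, so the ranking is deterministic.
#'
#' @param dec An `omics_pca`.
#' @param pc Component label (`"PC3"`) or index.
#' @param direction `"larger"` or `"smaller"`.
#' @return A `directional_ranking`: list with `pc`, `direction`, `probes`
#'   (rank order) and `scores` along the component.
#' @export
rank_outliers <- function(dec, pc, direction = c("larger", "smaller")) {
  stopifnot(inherits(dec, "omics_pca"))
  direction <- match.arg(direction)
  pc <- resolve_pc(dec, pc)
  s <- dec$scores[, pc]
  ids <- rownames(dec$scores)
  ord <- if (direction == "larger") order(-s, ids) else order(s, ids)
  structure(list(pc = colnames(dec$scores)[pc], direction = direction,
                 probes = ids[ord], scores = unname(s[ord])),
            class = "directional_ranking")
}

#' Take the top N probes of a directional ranking
#'
#' @param r A `directional_ranking`.
#' @param n Number of probes (default 300, the study-scale convention).
#' @return Character vector of the `n` highest-ranked probe identifiers.
#' @export
select_top <- function(r, n = 300) {
  stopifnot(inherits(r, "directional_ranking"))
  if (n < 1 || n > length(r$probes))
    stop("parameter error: n must be in 1..", length(r$probes))
  r$probes[seq_len(n)]
}

#' Cross-modality directional intersection
#'
#' For the chosen expression and methylation components, takes the top-`n`
#' probes in each direction of each modality and returns the union over
#' the four (expression direction x methylation direction) combinations of
#' pairwise intersections.  This equals the intersection of the two
#' modality-wise unions of larger/smaller top-`n` sets, an identity that
#' is exercised in the test suite.
#'
#' @param expr_dec,meth_dec `omics_pca` decompositions over the same probe
#'   universe.
#' @param expr_pc,meth_pc Component label or index per modality.
#' @param n Top-`n` per direction (default 300).
#' @return Character vector of selected probes (sorted); the per-combination
#'   intersections are attached as attribute `"combinations"`.
#' @export
intersect_directional <- function(expr_dec, meth_dec, expr_pc, meth_pc,
                                  n = 300) {
  stopifnot(inherits(expr_dec, "omics_pca"), inherits(meth_dec, "omics_pca"))
  if (!setequal(rownames(expr_dec$scores), rownames(meth_dec$scores)))
    stop("alignment error: probe universes differ between modalities")
  tops <- function(dec, pc)
    list(larger = select_top(rank_outliers(dec, pc, "larger"), n),
         smaller = select_top(rank_outliers(dec, pc, "smaller"), n))
  te <- tops(expr_dec, expr_pc)
  tm <- tops(meth_dec, meth_pc)
  combos <- list(
    larger_larger   = intersect(te$larger,  tm$larger),
    larger_smaller  = intersect(te$larger,  tm$smaller),
    smaller_larger  = intersect(te$smaller, tm$larger),
    smaller_smaller = intersect(te$smaller, tm$smaller))
  out <- sort(unique(unlist(combos, use.names = FALSE)))
  attr(out, "combinations") <- combos
  out
}
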