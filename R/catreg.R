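# Categorical-regression feature extraction.
#
# Per probe, the model x_ij = a_i0 + sum_l a_il d_jl is fitted by least
# squares, where d_jl indicates membership of sample j in cell-line
# category l.  The reported P-value is the overall model F-test (between-
# category over within-category mean square, df L-1 and J-L), identical to
# a one-way ANOVA; the computation is vectorized over probes and checked
# against per-probe linear-model fits in the test suite.

#' Fit the categorical (cell-line) model to every probe
#'
#' @param m An [omics_matrix()] whose samples carry category labels; every
#'   category must have at least one sample and `J > L` so residual
#'   degrees of freedom remain.
#' @return A `catreg_result` data frame with columns `probe`, `F`, `df1`,
#'   `df2`, `p`, `rank` (smallest P = rank 1, ties broken by probe id) and
#'   `flag` (`"ok"`, `"constant"` or `"perfect_separation"`).  The fitted
#'   parameterization (grand mean `a0`, sum-to-zero category `effects`) is
#'   attached as attribute `"coefficients"`.
#' @export
fit_categorical <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$samples$category))
    stop("sample categories required; apply a sample map first")
  cat_f <- factor(m$samples$category)
  J <- ncol(m$values)
  L <- nlevels(cat_f)
  if (L < 2) stop("need at least 2 categories")
  if (J <= L)
    stop("insufficient residual degrees of freedom: J = ", J,
         " samples but L = ", L, " categories")
  x <- m$values
  M <- stats::model.matrix(~ 0 + cat_f)
  n_l <- colSums(M)
  group_sum <- x %*% M
  group_mean <- sweep(group_sum, 2, n_l, "/")
  grand <- rowSums(x) / J
  SST <- rowSums(x^2) - J * grand^2
  SSB <- rowSums(sweep(group_mean^2, 2, n_l, "*")) - J * grand^2
  SSB <- pmin(pmax(SSB, 0), pmax(SST, 0))
  SSW <- pmax(SST - SSB, 0)
  df1 <- L - 1
  df2 <- J - L
  tol <- 1e-10 * pmax(SST, 1)
  flag <- rep("ok", nrow(x))
  Fstat <- (SSB / df1) / (SSW / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  const <- SST <= tol
  sep <- !const & SSW <= tol
  if (any(const)) {
    # totally constant probe: no signal at all, P = 1 by convention
    Fstat[const] <- NA_real_
    p[const] <- 1
    flag[const] <- "constant"
  }
  if (any(sep)) {
    warning(sum(sep), " probe(s) with zero within-category variance ",
            "(perfect separation); P reported as 0")
    Fstat[sep] <- Inf
    p[sep] <- 0
    flag[sep] <- "perfect_separation"
  }
  ids <- rownames(x)
  ord <- order(p, ids)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  res <- data.frame(probe = ids, F = Fstat, df1 = df1, df2 = df2, p = p,
                    rank = rk, flag = flag, stringsAsFactors = FALSE,
                    row.names = NULL)
  effects <- sweep(group_mean, 1, grand)
  colnames(effects) <- levels(cat_f)
  attr(res, "coefficients") <- list(a0 = stats::setNames(grand, ids),
                                    effects = effects)
  attr(res, "categories") <- levels(cat_f)
  class(res) <- c("catreg_result", "data.frame")
  res
}

#' Select the top N probes by categorical-regression P-value
#'
#' @param res A `catreg_result`.
#' @param n Number of probes (default 300); ties broken by probe id.
#' @return Character vector of selected probe identifiers.
#' @export
select_top_p <- function(res, n = 300) {
  stopifnot(inherits(res, "catreg_result"))
  if (n < 1 || n > nrow(res))
    stop("parameter error: n must be in 1..", nrow(res))
  res$probe[order(res$p, res$probe)][seq_len(n)]
}

#' Intersect probe selections across modalities
#'
#' @param expr_sel,meth_sel Probe sets from a shared universe.
#' @return Their intersection (sorted).
#' @export
intersect_modalities <- function(expr_sel, meth_sel) {
  sort(intersect(expr_sel, meth_sel))
}
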