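# Final candidate-gene report: union of the feature-extraction methods'
# gene sets plus per-gene expression-methylation correlation flags.

#' Correlation between expression and methylation of one gene
#'
#' Pearson correlation across the J paired samples, with the two-sided
#' P-value from the exact t transform t = r sqrt(J-2) / sqrt(1-r^2) on
#' J-2 degrees of freedom.  The flag marks significant negative
#' correlations (r < 0 and P < 0.05, raw P, no adjustment).
#'
#' @param expr_values,meth_values Numeric vectors over the same samples,
#'   length at least 3, neither constant.
#' @return List with `r`, `p`, and `negative_significant`.
#' @export
per_gene_correlation <- function(expr_values, meth_values) {
  if (length(expr_values) != length(meth_values))
    stop("vectors must have equal length")
  if (length(expr_values) < 3) stop("need at least 3 samples")
  if (stats::sd(expr_values) < 1e-12 || stats::sd(meth_values) < 1e-12)
    stop("degenerate input: constant vector")
  ct <- stats::cor.test(expr_values, meth_values, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(r = r, p = p, negative_significant = (r < 0 && p < 0.05))
}

#' Combine gene selections from the feature-extraction methods
#'
#' @param pca_genes_per_pc Named list of gene-symbol vectors, one per
#'   component used for PCA-based selection (names like `"PC3"`, `"PC4"`);
#'   method labels become `pca_fe_pc3` etc.
#' @param catreg_genes Gene symbols selected by categorical regression.
#' @return A `gene_report`: list with `table` (gene, comma-separated
#'   methods, n_methods), `n_unique`, and `n_multi_method`.
#' @export
combine_methods <- function(pca_genes_per_pc, catreg_genes) {
  sets <- c(stats::setNames(pca_genes_per_pc,
                            paste0("pca_fe_", tolower(names(pca_genes_per_pc)))),
            list(catreg = catreg_genes))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  n_methods <- rowSums(membership)
  methods <- apply(membership, 1, function(z)
    paste(names(sets)[z], collapse = ","))
  structure(list(
    table = data.frame(gene = genes, methods = methods,
                       n_methods = n_methods, stringsAsFactors = FALSE,
                       row.names = NULL),
    n_unique = length(genes),
    n_multi_method = sum(n_methods > 1)),
    class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat("gene_report: ", x$n_unique, " unique genes, ", x$n_multi_method,
      " selected by more than one method\n", sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Per-gene expression-methylation correlation table
#'
#' For each gene, pairs its expression probes with its methylation probes
#' and reports the correlation of the most significant pair
#' (`reduce = "best_probe"`, smallest P; the default) or of the per-gene
#' probe means (`reduce = "mean"`).  The two probe universes may differ;
#' genes with no annotated probe in either modality get `NA` rows.
#'
#' @param genes Gene symbols to report.
#' @param expr,meth Aligned `omics_matrix` objects.
#' @param expr_ann,meth_ann `probe_annotation` tables for each platform
#'   (may be the same object).
#' @param reduce Probe-to-gene reduction rule.
#' @return Data frame: `gene`, `expr_probe`, `meth_probe`, `r`, `p`,
#'   `negative_significant`.
#' @export
gene_correlation_table <- function(genes, expr, meth, expr_ann, meth_ann,
                                   reduce = c("best_probe", "mean")) {
  reduce <- match.arg(reduce)
  rows <- lapply(genes, function(g) {
    pe <- intersect(expr_ann$probe_id[expr_ann$symbol == g],
                    rownames(expr$values))
    pm <- intersect(meth_ann$probe_id[meth_ann$symbol == g],
                    rownames(meth$values))
    na_row <- data.frame(gene = g, expr_probe = NA_character_,
                         meth_probe = NA_character_, r = NA_real_,
                         p = NA_real_, negative_significant = NA,
                         stringsAsFactors = FALSE)
    if (length(pe) == 0 || length(pm) == 0) return(na_row)
    if (reduce == "mean") {
      ev <- colMeans(expr$values[pe, , drop = FALSE])
      mv <- colMeans(meth$values[pm, , drop = FALSE])
      if (stats::sd(ev) < 1e-12 || stats::sd(mv) < 1e-12) return(na_row)
      pg <- per_gene_correlation(ev, mv)
      return(data.frame(gene = g, expr_probe = "(mean)",
                        meth_probe = "(mean)", r = pg$r, p = pg$p,
                        negative_significant = pg$negative_significant,
                        stringsAsFactors = FALSE))
    }
    best <- na_row
    for (a in pe) for (b in pm) {
      ev <- expr$values[a, ]; mv <- meth$values[b, ]
      if (stats::sd(ev) < 1e-12 || stats::sd(mv) < 1e-12) next
      pg <- per_gene_correlation(ev, mv)
      if (is.na(best$p) || pg$p < best$p)
        best <- data.frame(gene = g, expr_probe = a, meth_probe = b,
                           r = pg$r, p = pg$p,
                           negative_significant = pg$negative_significant,
                           stringsAsFactors = FALSE)
    }
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
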