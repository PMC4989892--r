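# Two-group comparison of per-gene values (e.g. HDAC-inhibitor resistant
# versus non-resistant cell-line panels, or histone acetylation at 0 h
# versus 2 h of treatment).

#' Compare one gene's values between two sample groups
#'
#' Arithmetic group means plus a two-sided two-sample t-test.  The default
#' flavor is Welch (unequal variances); the pooled-variance test is
#' provided because published comparisons do not always name the variance
#' assumption.  When both groups are constant the test statistic is
#' undefined: P is 1 by convention if the means agree, 0 otherwise, and
#' the result is flagged.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @param labels Group labels for reporting.
#' @return A `group_comparison`: list with `means`, `direction` (`">"`,
#'   `"<"` or `"="` between the printed means), `p`, `t`, `df`, `flavor`,
#'   `degenerate`.
#' @export
compare_groups <- function(a, b, flavor = c("welch", "pooled"),
                           labels = c("group1", "group2")) {
  flavor <- match.arg(flavor)
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs at least 2 values")
  ma <- mean(a); mb <- mean(b)
  degenerate <- stats::var(a) < 1e-24 && stats::var(b) < 1e-24
  if (degenerate) {
    p <- if (isTRUE(all.equal(ma, mb))) 1 else 0
    tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = p)
  } else {
    tt <- stats::t.test(a, b, var.equal = (flavor == "pooled"))
  }
  structure(list(
    labels = labels,
    means = stats::setNames(c(ma, mb), labels),
    direction = if (isTRUE(all.equal(ma, mb))) "=" else
      if (ma > mb) ">" else "<",
    p = tt$p.value, t = unname(tt$statistic), df = unname(tt$parameter),
    flavor = flavor, degenerate = degenerate),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g %s %.4g   P = %.3g (%s t-test)\n",
              paste(x$labels, collapse = " vs "),
              x$means[1], x$direction, x$means[2], x$p, x$flavor))
  invisible(x)
}

#' Group comparison table over a matrix
#'
#' Runs [compare_groups()] per probe for the listed genes.  For genes with
#' several probes the minimum-P probe is reported and flagged, mirroring
#' the best-probe reduction used by the gene report.
#'
#' @param m An `omics_matrix`.
#' @param group_map Data frame with `sample_id` and `group` (exactly two
#'   groups); samples absent from the map are ignored.
#' @param genes Genes to report; requires `ann`.  If `NULL`, every probe
#'   is reported individually.
#' @param ann Optional `probe_annotation`.
#' @param flavor Passed to [compare_groups()].
#' @return Data frame: `gene`, `probe`, group means, `direction`, `p`,
#'   `multi_probe` flag.
#' @export
compare_table <- function(m, group_map, genes = NULL, ann = NULL,
                          flavor = c("welch", "pooled")) {
  stopifnot(inherits(m, "omics_matrix"))
  flavor <- match.arg(flavor)
  group_map <- as.data.frame(group_map, stringsAsFactors = FALSE)
  idx <- match(group_map$sample_id, m$samples$sample_id)
  if (anyNA(idx))
    stop("group map names sample(s) absent from the matrix: ",
         paste(group_map$sample_id[is.na(idx)][1:3], collapse = ", "))
  groups <- unique(group_map$group)
  if (length(groups) != 2) stop("exactly two groups required")
  ja <- idx[group_map$group == groups[1]]
  jb <- idx[group_map$group == groups[2]]
  one <- function(probe, gene, multi) {
    gc <- compare_groups(m$values[probe, ja], m$values[probe, jb],
                         flavor = flavor, labels = groups)
    data.frame(gene = gene, probe = probe,
               mean1 = unname(gc$means[1]), mean2 = unname(gc$means[2]),
               direction = gc$direction, p = gc$p, multi_probe = multi,
               stringsAsFactors = FALSE)
  }
  if (is.null(genes)) {
    out <- do.call(rbind, lapply(rownames(m$values), function(p)
      one(p, NA_character_, FALSE)))
  } else {
    if (is.null(ann)) stop("'ann' is required when 'genes' is given")
    out <- do.call(rbind, lapply(genes, function(g) {
      probes <- intersect(ann$probe_id[ann$symbol == g],
                          rownames(m$values))
      if (length(probes) == 0)
        return(data.frame(gene = g, probe = NA_character_,
                          mean1 = NA_real_, mean2 = NA_real_,
                          direction = NA_character_, p = NA_real_,
                          multi_probe = FALSE, stringsAsFactors = FALSE))
      rows <- do.call(rbind, lapply(probes, function(p)
        one(p, g, length(probes) > 1)))
      rows[which.min(rows$p), , drop = FALSE]
    }))
  }
  names(out)[names(out) == "mean1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean2"] <- paste0("mean_", groups[2])
  rownames(out) <- NULL
  out
}
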