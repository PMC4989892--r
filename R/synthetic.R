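# Synthetic paired expression/methylation generator with a planted shared
# latent factor.  The generative model per modality m is
#   x^(m)_ij = mu^(m)_{i,c(j)} + sum_f w^(m)_if s^(m)_fj
#              + w^(m)_{i,shared} s_{shared,j} + eps^(m)_ij
# with Gaussian factor scores and noise.  The shared factor's sample
# scores are identical across modalities; nuisance factor scores are
# drawn independently per modality.  Because the nuisance score variances
# exceed the shared factor's variance, the shared structure deliberately
# does not dominate: with the default two nuisance factors it surfaces
# near PC3 of each modality, so that identifying it requires the
# cross-modality loading-correlation machinery rather than simply taking
# PC1.

#' Configuration for the synthetic paired-omics generator
#'
#' Defaults emulate the study-scale design: 8 cell-line categories x 3
#' replicates (J = 24 samples per modality), thousands of probes, two
#' modality-private nuisance factors stronger than the shared factor, and
#' 50 planted probes loading strongly on the shared factor in both
#' modalities.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param I Probes per modality.
#' @param categories Cell-line category labels (L = 8 by default).
#' @param replicates Replicates per category (J = L * replicates).
#' @param nuisance_var Decreasing variances of the modality-private factor
#'   scores; its length is the number of nuisance factors.
#' @param shared_factor_variance Variance of the shared factor's sample
#'   scores; must be below `min(nuisance_var)` so the shared factor is not
#'   a leading component.
#' @param n_planted Number of planted outlier probes.
#' @param planted_loading Magnitude of the planted probes' loading on the
#'   shared factor (array units per unit factor score).
#' @param planted_sign_mix Fraction of planted probes whose shared-factor
#'   loading has opposite signs in the two modalities, exercising all four
#'   directional selection combinations.
#' @param background_loading_sd Standard deviation of non-planted probes'
#'   small shared-factor loadings.
#' @param noise_sd Residual noise standard deviation.
#' @param category_effect_sd Standard deviation of per-category mean
#'   offsets (drawn independently per probe, category and modality).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             I = 5000L,
                             categories = c("H1", "H358", "H460", "IMR90",
                                            "iPCH358", "iPCH460",
                                            "iPSIMR90", "piPCH358"),
                             replicates = 3L,
                             nuisance_var = c(9, 4),
                             shared_factor_variance = 1,
                             n_planted = 50L,
                             planted_loading = 4,
                             planted_sign_mix = 0.5,
                             background_loading_sd = 0.1,
                             noise_sd = 1,
                             category_effect_sd = 0.5) {
  cfg <- list(seed = as.integer(seed), I = as.integer(I),
              categories = as.character(categories),
              replicates = as.integer(replicates),
              nuisance_var = as.numeric(nuisance_var),
              shared_factor_variance = shared_factor_variance,
              n_planted = as.integer(n_planted),
              planted_loading = planted_loading,
              planted_sign_mix = planted_sign_mix,
              background_loading_sd = background_loading_sd,
              noise_sd = noise_sd,
              category_effect_sd = category_effect_sd)
  if (cfg$I < 4) stop("config error: I must be at least 4")
  if (cfg$n_planted >= cfg$I)
    stop("config error: n_planted must be smaller than I")
  if (cfg$shared_factor_variance <= 0)
    stop("config error: shared_factor_variance must be positive")
  if (length(cfg$nuisance_var) > 0) {
    if (is.unsorted(rev(cfg$nuisance_var)))
      stop("config error: nuisance_var must be non-increasing")
    if (cfg$shared_factor_variance >= min(cfg$nuisance_var))
      stop("config error: shared_factor_variance must be below every ",
           "nuisance variance (the shared factor must not lead)")
  }
  if (cfg$planted_sign_mix < 0 || cfg$planted_sign_mix > 1)
    stop("config error: planted_sign_mix must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$category_effect_sd < 0)
    stop("config error: standard deviations must be non-negative")
  structure(cfg, class = "synthetic_config")
}

#' Generate a paired synthetic expression/methylation dataset
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_paired_omics` with `expression` and
#'   `methylation` ([omics_matrix()] objects over the same probe universe)
#'   and `truth`: planted probe ids, the shared factor's sample scores,
#'   the per-modality planted signs, and the configuration.
#' @export
generate_paired_omics <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  set.seed(cfg$seed)
  L <- length(cfg$categories)
  J <- L * cfg$replicates
  I <- cfg$I
  cat_idx <- rep(seq_len(L), each = cfg$replicates)
  probe_ids <- sprintf("probe_%05d", seq_len(I))
  sample_ids <- paste0(cfg$categories[cat_idx], "_r",
                       rep(seq_len(cfg$replicates), L))
  s_shared <- stats::rnorm(J, 0, sqrt(cfg$shared_factor_variance))
  planted <- sort(sample.int(I, cfg$n_planted))
  sign_e <- sample(c(-1, 1), cfg$n_planted, replace = TRUE)
  n_flip <- round(cfg$planted_sign_mix * cfg$n_planted)
  flip <- rep(FALSE, cfg$n_planted)
  if (n_flip > 0) flip[sample.int(cfg$n_planted, n_flip)] <- TRUE
  sign_m <- sign_e * ifelse(flip, -1, 1)
  one_modality <- function(planted_sign, modality) {
    nf <- length(cfg$nuisance_var)
    X <- matrix(0, I, J)
    if (cfg$category_effect_sd > 0) {
      mu <- matrix(stats::rnorm(I * L, 0, cfg$category_effect_sd), I, L)
      X <- X + mu[, cat_idx, drop = FALSE]
    }
    if (nf > 0) {
      s_n <- vapply(cfg$nuisance_var,
                    function(v) stats::rnorm(J, 0, sqrt(v)),
                    numeric(J))
      w_n <- matrix(stats::rnorm(I * nf), I, nf)
      X <- X + w_n %*% t(s_n)
    }
    w_s <- stats::rnorm(I, 0, cfg$background_loading_sd)
    w_s[planted] <- planted_sign * cfg$planted_loading
    X <- X + outer(w_s, s_shared)
    if (cfg$noise_sd > 0)
      X <- X + matrix(stats::rnorm(I * J, 0, cfg$noise_sd), I, J)
    dimnames(X) <- list(probe_ids, sample_ids)
    list(m = omics_matrix(X, data.frame(
      sample_id = sample_ids, category = cfg$categories[cat_idx],
      replicate = rep(seq_len(cfg$replicates), L), modality = modality,
      stringsAsFactors = FALSE)), shared_loadings = w_s)
  }
  e <- one_modality(sign_e, "expression")
  m <- one_modality(sign_m, "methylation")
  structure(list(
    expression = e$m, methylation = m$m,
    truth = list(planted = probe_ids[planted],
                 shared_scores = stats::setNames(s_shared, sample_ids),
                 expr_sign = sign_e, meth_sign = sign_m,
                 expr_shared_loadings = e$shared_loadings,
                 meth_shared_loadings = m$shared_loadings,
                 config = cfg)),
    class = "synthetic_paired_omics")
}

#' Write file-format fixtures from a paired dataset
#'
#' Emits three plain-text files into `dir`: a probe-profile-style
#' expression table (`expression_profile.txt`, with per-sample
#' `AVG Signal` columns and decoy `Detection Pval` columns), a
#' series-matrix-style methylation table (`methylation_series_matrix.txt`,
#' with sentinel lines and quoted identifiers), and a toy annotation table
#' (`annotation.txt`) in which consecutive probe pairs share one gene
#' symbol and the last probe is left unannotated.  The readers round-trip
#' these files exactly.
#'
#' @param expr,meth `omics_matrix` objects (non-empty).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_fixtures <- function(expr, meth, dir) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(meth, "omics_matrix"))
  if (nrow(expr$values) == 0 || ncol(expr$values) == 0 ||
      nrow(meth$values) == 0 || ncol(meth$values) == 0)
    stop("cannot write fixtures from an empty matrix")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", dir)

  prof <- file.path(dir, "expression_profile.txt")
  ids <- expr$samples$sample_id
  header <- c("ProbeID",
              as.vector(rbind(paste(ids, "AVG Signal"),
                              paste(ids, "Detection Pval"))))
  vals <- expr$values
  body <- vapply(seq_len(nrow(vals)), function(i) {
    cells <- as.vector(rbind(format_full(vals[i, ]),
                             format_full(rep(0.01, ncol(vals)))))
    paste(c(rownames(vals)[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), body), prof)

  sm <- file.path(dir, "methylation_series_matrix.txt")
  mids <- meth$samples$sample_id
  lines <- c("!Series_title\t\"synthetic paired methylation panel\"",
             "!series_matrix_table_begin",
             paste(c("\"ID_REF\"", paste0('"', mids, '"')),
                   collapse = "\t"),
             vapply(seq_len(nrow(meth$values)), function(i)
               paste(c(paste0('"', rownames(meth$values)[i], '"'),
                       format_full(meth$values[i, ])), collapse = "\t"),
               character(1)),
             "!series_matrix_table_end")
  writeLines(lines, sm)

  annp <- file.path(dir, "annotation.txt")
  probes <- rownames(expr$values)
  np <- length(probes)
  gene_idx <- ceiling(seq_len(np) / 2)
  symbol <- sprintf("GENE%04d", gene_idx)
  accession <- sprintf("NM_%06d", gene_idx)
  symbol[np] <- ""
  accession[np] <- ""
  utils::write.table(
    data.frame(ID = probes, Accession = accession, Symbol = symbol,
               stringsAsFactors = FALSE),
    annp, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")

  c(expression_profile = prof, methylation_series_matrix = sm,
    annotation = annp)
}
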