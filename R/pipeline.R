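# End-to-end orchestration: read/generate -> align -> embed -> pair ->
# directional FE + categorical FE -> gene report -> stability.  Stages
# communicate through plain data structures and, when an output directory
# is given, through TSV/JSON files, so any stage can be audited or rerun
# in isolation.

#' Default pipeline configuration
#'
#' @param seed Seed used when the input is synthetic.
#' @param k Components per modality entering the pairing (default 5).
#' @param top_n Probes per direction for the PCA-based selection and per
#'   modality for the categorical selection (default 300).
#' @param n_pairs Number of top coincident pairs carried into selection
#'   (default 2, one selection per paired component).
#' @param synthetic `NULL`, or a list of [synthetic_config()] overrides.
#' @param inputs `NULL`, or a list with paths `expression` (probe-profile
#'   table), `methylation` (series matrix), `sample_map` (TSV with
#'   sample_id/category/replicate/modality), and optionally
#'   `expr_annotation`/`meth_annotation`.
#' @param run_stability Toggle for the leave-one-out stage.
#' @param reduce Probe-to-gene reduction for correlations
#'   (see [gene_correlation_table()]).
#' @return Configuration list.
#' @export
pipeline_config <- function(seed = 1L, k = 5L, top_n = 300L, n_pairs = 2L,
                            synthetic = list(), inputs = NULL,
                            run_stability = TRUE,
                            reduce = "best_probe") {
  list(seed = as.integer(seed), k = as.integer(k),
       top_n = as.integer(top_n), n_pairs = as.integer(n_pairs),
       synthetic = synthetic, inputs = inputs,
       run_stability = isTRUE(run_stability), reduce = reduce)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (synthetic generation or file reading),
#' sample alignment, feature-embedding PCA per modality, loading
#' correlation + UPGMA pairing, directional PCA-based selection for each
#' retained pair, categorical-regression selection, gene report with
#' correlation flags, and leave-one-out stability of the pairing.  On
#' error the failing stage is named; if `out_dir` is set, a `.partial`
#' marker is left next to whatever outputs were already written.
#'
#' @param config A list from [pipeline_config()], a YAML file path, or a
#'   plain list of overrides.
#' @param out_dir Optional directory for stage TSVs and `manifest.json`.
#' @return Invisibly, a list with `manifest` and `results` (the in-memory
#'   stage objects).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  config <- read_pipeline_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  partial <- if (is.null(out_dir)) NULL else file.path(out_dir, ".partial")
  if (!is.null(partial)) file.create(partial)
  stage_name <- "setup"
  res <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    stage_name <<- name
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  input_digests <- list()

  run_stage("input", function() {
    if (!is.null(config$inputs)) {
      smap <- utils::read.delim(config$inputs$sample_map,
                                stringsAsFactors = FALSE)
      res$expr <- read_probe_profile(config$inputs$expression,
                                     sample_map = smap)
      res$meth <- read_series_matrix(config$inputs$methylation,
                                     sample_map = smap)
      res$expr_ann <- if (!is.null(config$inputs$expr_annotation))
        read_annotation(config$inputs$expr_annotation) else NULL
      res$meth_ann <- if (!is.null(config$inputs$meth_annotation))
        read_annotation(config$inputs$meth_annotation) else res$expr_ann
      paths <- unlist(config$inputs)
      input_digests <<- as.list(tools::md5sum(paths[file.exists(paths)]))
      res$truth <- NULL
    } else {
      scfg <- do.call(synthetic_config,
                      c(list(seed = config$seed), config$synthetic))
      syn <- generate_paired_omics(scfg)
      res$expr <- syn$expression
      res$meth <- syn$methylation
      res$truth <- syn$truth
      res$expr_ann <- res$meth_ann <- NULL
      input_digests <<- list(synthetic_seed = scfg$seed)
    }
    # identity probe->gene mapping when no annotation is supplied
    if (is.null(res$expr_ann)) {
      mk_ann <- function(m) {
        ann <- data.frame(probe_id = rownames(m$values),
                          accession = rownames(m$values),
                          symbol = rownames(m$values),
                          stringsAsFactors = FALSE)
        class(ann) <- c("probe_annotation", "data.frame")
        ann
      }
      res$expr_ann <- mk_ann(res$expr)
      res$meth_ann <- mk_ann(res$meth)
    }
  })

  run_stage("align", function() {
    al <- align_modalities(res$expr, res$meth)
    res$expr <- al$expression
    res$meth <- al$methylation
  })

  run_stage("embed", function() {
    res$dec_e <- embed_features(res$expr, config$k)
    res$dec_m <- embed_features(res$meth, config$k)
  })

  run_stage("pair", function() {
    res$lc <- loading_correlation(res$dec_e, res$dec_m, config$k)
    res$tree <- upgma(cor_distance(res$lc))
    pairs <- find_coincident_pairs(res$tree, res$lc)
    if (nrow(pairs) == 0)
      stop("no cross-modality sibling component pair found")
    res$pairs <- pairs
    res$selected_pairs <- utils::head(pairs, config$n_pairs)
  })

  run_stage("pca_fe", function() {
    sel <- res$selected_pairs
    res$pca_selection <- lapply(seq_len(nrow(sel)), function(i)
      intersect_directional(res$dec_e, res$dec_m,
                            sel$expression_pc[i], sel$methylation_pc[i],
                            n = min(config$top_n, nrow(res$expr$values))))
    names(res$pca_selection) <- sel$expression_pc
    res$pca_genes <- lapply(res$pca_selection, map_probes_to_genes,
                            ann = res$expr_ann)
  })

  run_stage("catreg_fe", function() {
    res$cat_e <- fit_categorical(res$expr)
    res$cat_m <- fit_categorical(res$meth)
    n <- min(config$top_n, nrow(res$cat_e))
    res$catreg_probes <- intersect_modalities(
      select_top_p(res$cat_e, n), select_top_p(res$cat_m, n))
    res$catreg_genes <- map_probes_to_genes(res$catreg_probes,
                                            res$expr_ann)
  })

  run_stage("report", function() {
    res$report <- combine_methods(res$pca_genes, res$catreg_genes)
    res$correlations <- gene_correlation_table(
      res$report$table$gene, res$expr, res$meth, res$expr_ann,
      res$meth_ann, reduce = config$reduce)
  })

  if (config$run_stability) {
    run_stage("stability", function() {
      res$stability <- loo_stability(res$expr, res$meth, config$k,
                                     res$selected_pairs)
    })
  } else res$stability <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcafe")),
    config = config[c("seed", "k", "top_n", "n_pairs", "run_stability",
                      "reduce")],
    synthetic = length(config$synthetic) > 0 || is.null(config$inputs),
    input_digests = input_digests,
    selected_pairs = res$selected_pairs[, c("expression_pc",
                                            "methylation_pc", "rho")],
    counts = list(
      probes = nrow(res$expr$values),
      samples = ncol(res$expr$values),
      pca_selected = vapply(res$pca_selection, length, integer(1)),
      pca_genes = vapply(res$pca_genes, length, integer(1)),
      catreg_selected = length(res$catreg_probes),
      catreg_genes = length(res$catreg_genes),
      unique_genes = res$report$n_unique,
      multi_method_genes = res$report$n_multi_method,
      conservation = if (is.null(res$stability)) NA_integer_
        else res$stability$count))

  if (!is.null(out_dir)) {
    utils::write.table(res$pairs, file.path(out_dir, "pc_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rho_out <- data.frame(label = rownames(res$lc$rho), res$lc$rho,
                          check.names = FALSE)
    utils::write.table(rho_out, file.path(out_dir, "loading_rho.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    upgma_newick(res$tree, file.path(out_dir, "pc_tree.nwk"))
    for (pc in names(res$pca_selection))
      utils::write.table(
        data.frame(probe = res$pca_selection[[pc]]),
        file.path(out_dir, paste0("pca_fe_", tolower(pc), "_probes.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$cat_e, file.path(out_dir, "catreg_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$cat_m, file.path(out_dir, "catreg_methylation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report_tab <- merge(res$report$table, res$correlations, by = "gene",
                        all.x = TRUE, sort = TRUE)
    utils::write.table(report_tab, file.path(out_dir, "gene_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$stability))
      utils::write.table(
        data.frame(sample = names(res$stability$per_sample),
                   conserved = unname(res$stability$per_sample)),
        file.path(out_dir, "loo_stability.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    file.remove(partial)
  }
  invisible(list(manifest = manifest, results = as.list(res)))
}
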