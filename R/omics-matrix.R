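#' Construct an omics matrix
#'
#' An `omics_matrix` holds one modality's probe-by-sample table together
#' with per-sample metadata (cell-line category, replicate, modality).
#' Values are kept in raw array units: no normalization, background
#' correction, or log transform is applied anywhere in the package.
#'
#' Probes (rows) containing any missing value are dropped on construction,
#' with a message reporting the count; the downstream decompositions assume
#' complete rows.
#'
#' @param values Numeric matrix, probes in rows (rownames are the probe
#'   identifiers), samples in columns.
#' @param samples Data frame with one row per column of `values`, carrying
#'   at least `sample_id`; `category`, `replicate` and `modality` may be
#'   `NA` until a sample map is applied (see [apply_sample_map()]).
#' @param drop_incomplete Drop probes with missing values (default `TRUE`).
#' @return An object of class `omics_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
omics_matrix <- function(values, samples, drop_incomplete = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("'values' must carry probe identifiers as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe identifiers in input: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
               collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("'samples' must contain a 'sample_id' column")
  for (col in c("category", "replicate", "modality"))
    if (!col %in% names(samples)) samples[[col]] <- NA
  if (nrow(samples) != ncol(values))
    stop("sample metadata rows (", nrow(samples),
         ") do not match value columns (", ncol(values), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample identifiers")
  key <- paste(samples$category, samples$replicate, samples$modality)
  if (!anyNA(samples$category) && anyDuplicated(key))
    stop("(category, replicate, modality) must uniquely identify a sample")
  if (drop_incomplete && anyNA(values)) {
    bad <- rowSums(is.na(values)) > 0
    message(sum(bad), " probe(s) with missing values dropped")
    values <- values[!bad, , drop = FALSE]
  }
  structure(list(values = values, samples = samples), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  mod <- unique(x$samples$modality)
  if (!all(is.na(mod))) cat("modality:", paste(mod, collapse = ", "), "\n")
  cats <- unique(x$samples$category)
  if (!all(is.na(cats)))
    cat("categories:", paste(cats, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by sample index
#'
#' @param m An `omics_matrix`.
#' @param j Column (sample) index vector, as accepted by `[`.
#' @return An `omics_matrix` with the selected samples.
#' @export
subset_samples <- function(m, j) {
  stopifnot(inherits(m, "omics_matrix"))
  omics_matrix(m$values[, j, drop = FALSE],
               m$samples[j, , drop = FALSE],
               drop_incomplete = FALSE)
}

#' Attach a sample map to an omics matrix
#'
#' Sample metadata (category, replicate, modality) is supplied explicitly
#' via a sample map rather than guessed from file headers or GEO titles.
#'
#' @param m An `omics_matrix`.
#' @param sample_map Data frame with columns `sample_id`, `category`,
#'   `replicate`, and optionally `modality`.
#' @return `m` with its `samples` metadata populated.
#' @export
apply_sample_map <- function(m, sample_map) {
  stopifnot(inherits(m, "omics_matrix"))
  sample_map <- as.data.frame(sample_map, stringsAsFactors = FALSE)
  req <- c("sample_id", "category", "replicate")
  if (!all(req %in% names(sample_map)))
    stop("sample map must contain columns: ", paste(req, collapse = ", "))
  idx <- match(m$samples$sample_id, sample_map$sample_id)
  if (anyNA(idx))
    stop("sample map is missing sample(s): ",
         paste(m$samples$sample_id[is.na(idx)][1:3], collapse = ", "))
  m$samples$category <- as.character(sample_map$category[idx])
  m$samples$replicate <- as.integer(sample_map$replicate[idx])
  if ("modality" %in% names(sample_map))
    m$samples$modality <- as.character(sample_map$modality[idx])
  key <- paste(m$samples$category, m$samples$replicate, m$samples$modality)
  if (anyDuplicated(key))
    stop("(category, replicate, modality) must uniquely identify a sample")
  m
}

#' Align the samples of two modalities
#'
#' Reorders the columns of both matrices so that column `j` of each refers
#' to the same (category, replicate) pair, in lexicographic
#' (category, replicate) order.  Samples present in only one modality are
#' dropped with a warning.
#'
#' @param expr,meth `omics_matrix` objects with category and replicate
#'   metadata populated.
#' @return A list with elements `expression` and `methylation`, column
#'   counts identical.
#' @export
align_modalities <- function(expr, meth) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(meth, "omics_matrix"))
  for (m in list(expr, meth))
    if (anyNA(m$samples$category) || anyNA(m$samples$replicate))
      stop("category/replicate metadata required for alignment; ",
           "apply a sample map first")
  key_e <- paste(expr$samples$category, expr$samples$replicate, sep = "\r")
  key_m <- paste(meth$samples$category, meth$samples$replicate, sep = "\r")
  common <- intersect(key_e, key_m)
  if (length(common) == 0)
    stop("alignment error: no (category, replicate) pair shared ",
         "between modalities")
  dropped <- length(setdiff(key_e, common)) + length(setdiff(key_m, common))
  if (dropped > 0)
    warning(dropped, " sample(s) present in only one modality dropped")
  common <- common[order(common)]
  list(expression = subset_samples(expr, match(common, key_e)),
       methylation = subset_samples(meth, match(common, key_m)))
}
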