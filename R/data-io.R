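# Readers and writers for the study's tabular formats.  All files are
# plain tab-delimited text (gzip accepted transparently); values are taken
# as-is, with no normalization.

#' Read a sample-probe profile table
#'
#' Parses a tab-delimited probe-profile file (as distributed as microarray
#' supplementary files) and keeps exactly the per-sample signal columns
#' whose header contains `signal_column_tag` (default `"AVG Signal"`);
#' auxiliary columns such as detection P-values are excluded.  Sample
#' identifiers are the column headers with the tag and surrounding
#' punctuation stripped.
#'
#' @param path Path to the file (may be gzip-compressed).
#' @param signal_column_tag Substring identifying signal columns.
#' @param probe_id_column Name of the probe-identifier column; by default
#'   the first column is used.
#' @param sample_map Optional sample map applied via [apply_sample_map()].
#' @return An [omics_matrix()].
#' @export
read_probe_profile <- function(path, signal_column_tag = "AVG Signal",
                               probe_id_column = NULL, sample_map = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop("format error: expected a probe-id column plus signal columns in ",
         path)
  if (is.null(probe_id_column)) {
    id_col <- 1L
  } else {
    id_col <- match(probe_id_column, names(tab))
    if (is.na(id_col))
      stop("format error: probe-id column '", probe_id_column,
           "' not found in ", path)
  }
  probe_ids <- tab[[id_col]]
  sig <- setdiff(grep(signal_column_tag, names(tab), fixed = TRUE), id_col)
  if (length(sig) == 0)
    stop("format error: no column header contains '", signal_column_tag,
         "' in ", path)
  values <- matrix(NA_real_, nrow(tab), length(sig),
                   dimnames = list(probe_ids, NULL))
  for (k in seq_along(sig)) {
    values[, k] <- parse_numeric_column(tab[[sig[k]]], probe_ids,
                                        names(tab)[sig[k]])
  }
  sample_ids <- strip_column_tag(names(tab)[sig], signal_column_tag)
  colnames(values) <- sample_ids
  m <- omics_matrix(values, data.frame(sample_id = sample_ids,
                                       stringsAsFactors = FALSE))
  if (!is.null(sample_map)) m <- apply_sample_map(m, sample_map)
  m
}

parse_numeric_column <- function(x, probe_ids, colname) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x) & !(x %in% c("", "NA", "null"))
  if (any(bad))
    stop("parse error: non-numeric value '", x[which(bad)[1]],
         "' at probe '", probe_ids[which(bad)[1]], "', column '", colname,
         "'")
  v
}

strip_column_tag <- function(headers, tag) {
  ids <- if (nzchar(tag)) sub(tag, "", headers, fixed = TRUE) else headers
  gsub("^[ ._:-]+|[ ._:-]+$", "", ids)
}

#' Read a series-matrix table
#'
#' Parses the tab-delimited table enclosed between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` sentinel
#' lines.  Metadata lines beginning with `!` outside the table are
#' ignored, and double quotes around identifiers are stripped.  Sample
#' category/replicate metadata is populated from the supplied sample map,
#' never guessed from headers.
#'
#' @param path Path to the series-matrix file (may be gzip-compressed).
#' @param sample_map Optional sample map applied via [apply_sample_map()].
#' @return An [omics_matrix()].
#' @export
read_series_matrix <- function(path, sample_map = NULL) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop("format error: series-matrix table sentinels missing or ",
         "malformed in ", path)
  body <- lines[(begin + 1):(end - 1)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop("parse error: ragged rows in series-matrix table (line ",
         begin + which(widths != widths[1])[1], ")")
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(cells[[1]])
  rows <- cells[-1]
  probe_ids <- unquote(vapply(rows, `[[`, "", 1L))
  sample_ids <- header[-1]
  values <- matrix(NA_real_, length(rows), length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
  for (k in seq_along(sample_ids)) {
    col <- unquote(vapply(rows, `[[`, "", k + 1L))
    values[, k] <- parse_numeric_column(col, probe_ids, sample_ids[k])
  }
  m <- omics_matrix(values, data.frame(sample_id = sample_ids,
                                       stringsAsFactors = FALSE))
  if (!is.null(sample_map)) m <- apply_sample_map(m, sample_map)
  m
}

#' Write an omics matrix as TSV
#'
#' Tab-delimited UTF-8 table with a header row; probe identifiers in the
#' first column (`ID_REF`).  Values are written with 17 significant
#' digits so that reading the file back reproduces them bit-exactly.
#'
#' @param m An `omics_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  out <- cbind(ID_REF = rownames(m$values),
               as.data.frame(apply(m$values, 2, format_full),
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

format_full <- function(x) sprintf("%.17g", x)

#' Read a platform annotation table
#'
#' Tab-delimited table mapping probe identifiers to RefSeq accessions and
#' gene symbols.  Probes with an empty accession and symbol are kept and
#' treated as unannotated.
#'
#' @param path Path to the annotation file.
#' @param probe_col,accession_col,symbol_col Column names.
#' @return A `probe_annotation`: data frame with columns `probe_id`,
#'   `accession`, `symbol`.
#' @export
read_annotation <- function(path, probe_col = "ID",
                            accession_col = "Accession",
                            symbol_col = "Symbol") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c(probe_col, accession_col, symbol_col))
    if (!col %in% names(tab))
      stop("format error: annotation column '", col, "' not found in ",
           path)
  ann <- data.frame(probe_id = tab[[probe_col]],
                    accession = tab[[accession_col]],
                    symbol = tab[[symbol_col]],
                    stringsAsFactors = FALSE)
  ann <- unique(ann)
  if (anyDuplicated(ann$probe_id))
    stop("annotation maps probe(s) to more than one gene: ",
         paste(unique(ann$probe_id[duplicated(ann$probe_id)])[1:3],
               collapse = ", "))
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Map selected probes to gene symbols
#'
#' Selection always happens at the probe level; this post-hoc mapping
#' collapses selected probes to the set of annotated gene symbols.
#' Unannotated probes are dropped and multiple probes of one gene collapse
#' to a single symbol.
#'
#' @param probes Character vector of probe identifiers.
#' @param ann A `probe_annotation` (or any data frame with `probe_id` and
#'   `symbol` columns).
#' @return Character vector of unique gene symbols (sorted).
#' @export
map_probes_to_genes <- function(probes, ann) {
  if (length(probes) == 0) return(character(0))
  sym <- ann$symbol[match(probes, ann$probe_id)]
  sym <- sym[!is.na(sym) & sym != "" & sym != "unannotated"]
  sort(unique(sym))
}
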