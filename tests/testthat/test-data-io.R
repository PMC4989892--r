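test_that("probe-profile reader keeps exactly the tagged signal columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "ProbeID\tA AVG Signal\tA Detection Pval\tB AVG Signal\tB Detection Pval",
    "p1\t1.5\t0.01\t2.5\t0.02",
    "p2\t3\t0.01\t4\t0.02",
    "p3\t-0.5\t0.01\t0\t0.02"), path)
  m <- read_probe_profile(path)
  expect_s3_class(m, "omics_matrix")
  expect_equal(dim(m$values), c(3L, 2L))
  expect_equal(rownames(m$values), c("p1", "p2", "p3"))
  expect_equal(m$samples$sample_id, c("A", "B"))
  expect_equal(m$values[, 1], c(p1 = 1.5, p2 = 3, p3 = -0.5))

  expect_error(read_probe_profile(path, signal_column_tag = "NO_SUCH"),
               "format error")
  expect_error(read_probe_profile(path, probe_id_column = "Missing"),
               "format error")
})

test_that("probe-profile reader reports non-numeric cells and duplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ProbeID\tA AVG Signal", "p1\t1.5", "p2\toops"), path)
  expect_error(read_probe_profile(path), "parse error.*p2.*A")

  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ProbeID\tA AVG Signal", "p1\t1", "p1\t2"), dup)
  expect_error(read_probe_profile(dup), "duplicate probe")
})

test_that("series-matrix reader handles sentinels, quotes, and errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"toy\"",
    "!series_matrix_table_begin",
    paste0("\"ID_REF\"\t\"S1\"\t\"S2\"\t\"S3\"\t\"S4\""),
    "\"cg0001\"\t0.1\t0.2\t0.3\t0.4",
    "\"cg0002\"\t0.5\t0.6\t0.7\t0.8",
    "cg0003\t1\t2\t3\t4",
    "\"cg0004\"\t-1\t-2\t-3\t-4",
    "\"cg0005\"\t0\t0.5\t1\t1.5",
    "!series_matrix_table_end",
    "!trailing_metadata\tignored"), path)
  m <- read_series_matrix(path)
  expect_equal(dim(m$values), c(5L, 4L))
  expect_equal(rownames(m$values)[1:3], c("cg0001", "cg0002", "cg0003"))
  expect_equal(m$samples$sample_id, c("S1", "S2", "S3", "S4"))
  expect_equal(unname(m$values["cg0004", ]), c(-1, -2, -3, -4))

  noend <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!series_matrix_table_begin", "\"ID_REF\"\t\"S1\"",
               "\"cg1\"\t1"), noend)
  expect_error(read_series_matrix(noend), "format error")

  ragged <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!series_matrix_table_begin", "\"ID_REF\"\t\"S1\"\t\"S2\"",
               "\"cg1\"\t1", "!series_matrix_table_end"), ragged)
  expect_error(read_series_matrix(ragged), "ragged")
})

test_that("write_matrix round-trips values bit-exactly", {
  set.seed(42)
  vals <- matrix(rnorm(12) * 10^sample(-3:3, 12, TRUE), 4, 3)
  m <- make_omics(vals)
  path <- withr::local_tempfile(fileext = ".txt")
  write_matrix(m, path)
  # an empty tag selects every per-sample column of the writer's output
  back <- read_probe_profile(path, signal_column_tag = "")
  expect_identical(unname(back$values), unname(vals))
  expect_equal(back$samples$sample_id, m$samples$sample_id)
})

test_that("alignment reorders to (category, replicate), drops strays, and is idempotent", {
  v1 <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  v2 <- matrix(5:8, 2, dimnames = list(c("p1", "p2"), c("c", "d")))
  expr <- make_omics(v1, categories = c("H1", "H1"), replicates = c(1, 2))
  meth <- make_omics(v2, categories = c("H1", "H1"), replicates = c(2, 1),
                     modality = "methylation")
  al <- align_modalities(expr, meth)
  expect_equal(al$expression$samples$replicate, c(1L, 2L))
  expect_equal(al$methylation$samples$replicate, c(1L, 2L))
  expect_equal(unname(al$methylation$values[1, ]), c(7, 5))
  al2 <- align_modalities(al$expression, al$methylation)
  expect_identical(al2$expression$values, al$expression$values)

  # full 8x3 design: lexicographic (category, replicate) order
  set.seed(1)
  e24 <- make_design_omics(matrix(rnorm(48), 2, 24))
  m24 <- make_design_omics(matrix(rnorm(48), 2, 24), "methylation")
  perm <- sample(24)
  al3 <- align_modalities(subset_samples(e24, perm), m24)
  key <- paste(al3$expression$samples$category,
               al3$expression$samples$replicate)
  expect_equal(key, sort(key))
  expect_equal(ncol(al3$expression$values), 24L)

  disjoint <- make_omics(v2, categories = c("H460", "H460"),
                         replicates = c(1, 2), modality = "methylation")
  expect_error(align_modalities(expr, disjoint), "alignment error")
})

test_that("probe-to-gene mapping collapses duplicates and drops unannotated", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p9"),
                    accession = c("NM_1", "NM_1", "NM_2", ""),
                    symbol = c("SFRP1", "SFRP1", "DKK3", ""),
                    stringsAsFactors = FALSE)
  expect_equal(map_probes_to_genes(c("p1", "p2", "p3"), ann),
               c("DKK3", "SFRP1"))
  expect_equal(map_probes_to_genes("p9", ann), character(0))
  expect_equal(map_probes_to_genes(character(0), ann), character(0))
  # output never larger than input
  for (k in 1:4) {
    probes <- sample(ann$probe_id, k)
    expect_lte(length(map_probes_to_genes(probes, ann)), k)
  }
})

test_that("missing values are dropped row-wise with a message", {
  vals <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  expect_message(
    m <- omics_matrix(vals, data.frame(sample_id = c("a", "b"))),
    "1 probe")
  expect_equal(rownames(m$values), c("p1", "p3"))
})
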