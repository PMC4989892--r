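Package: pcafe
Title: PCA-Based Unsupervised Feature Extraction for Paired Expression
    and Promoter Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-analysis pipeline for paired gene-expression and
    promoter-methylation microarray panels of cell-line categories.
    Principal components are computed so that probes (features), not
    samples, are embedded into the component space; the biologically
    informative expression-methylation component pair is identified by
    UPGMA clustering of standardized sample-loading correlations, and
    probes are selected as directional outliers along the paired
    components in all four direction combinations.  A complementary
    categorical-regression (one-way ANOVA) feature extraction ranks
    probes by cell-line effect, and the two selections are combined into
    a gene report with per-gene expression-methylation correlation
    flags.  Leave-one-out recomputation quantifies the stability of the
    identified component pairing, and two-group comparison utilities
    reproduce resistant versus non-resistant cell-line contrasts.  A
    synthetic paired-omics generator with a planted shared latent factor
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
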