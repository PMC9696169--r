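Package: cytosig
Title: Cytokine-Response Transcriptome Signatures and Assay Statistics for
    Epidermal Tissue Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microarray studies of cytokine-stimulated
    reconstituted human epidermis. Implements probe-set collapse and
    detection/variance gene filters, two-group linear-model contrasts with
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg false
    discovery rate control, gene-signature statistics (hypergeometric overlap,
    resampled mean fold-change, sign-majority and rank-enrichment tests),
    genome-wide fold-change concordance analysis between contrasts (Spearman
    correlation, quadrant proportions, Mahalanobis ellipse, discordant-gene
    extraction), sample-structure summaries (PCA, hierarchical clustering),
    and kinetic plate-assay statistics (least-squares slopes, percent
    inhibition, interaction tests, Fisher's least-significant-difference
    letters). A synthetic-data module generates expression matrices,
    signatures and kinetic series with known ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
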