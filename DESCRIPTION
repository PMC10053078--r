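Package: arvquant
Title: Detection and Relative Quantification of Androgen Receptor Splice
    Variants from RNA-Seq Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a cohort-level compendium of androgen receptor splice
    variants (AR-Vs) from splice junctions observed in aligned RNA-seq data,
    quantifies each variant's expression relative to the canonical exon 1-exon 2
    junction of AR, and runs the downstream cohort analyses: prevalence and
    positivity calls, co-occurrence (oncoprint) ordering, rank-based comparison
    of AR expression between variant-positive and -negative samples, and
    univariate/multivariate regression of clinical covariates on relative
    variant expression. A seeded synthetic-cohort simulator emits per-sample SAM
    files, AR expression and clinical tables from a known ground truth so the
    whole pipeline is testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
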