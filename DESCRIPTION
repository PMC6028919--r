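Package: calichip
Title: Calibrated ChIP-Seq Quantification and Anchored Profile Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spike-in calibrated ChIP-seq quantification for budding yeast
    experiments that mix sample cells with calibration-genome cells before
    immunoprecipitation. Computes the occupancy ratio (OR) from the four
    unique-alignment read totals (IP and whole-cell extract on sample and
    calibration genomes), builds zero-filled per-base coverage tracks,
    centromere (CDEIII) anchored meta-profiles, TSS/TES metagenes with
    convergent/tandem gene classification, difference plots and
    percent-of-reference scaling, pericentric versus arm summaries, and
    two-track scatter comparisons. Also provides suppressor-mutation mapping
    by SNP subtraction/intersection with genic filtering, ATPase rate
    estimation from absorbance time series via a phosphate standard curve,
    and a synthetic-data generator with known ground truth so that every
    stage of the pipeline is testable end to end without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomeInfoDb,
    vcfR,
    stats,
    utils,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
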