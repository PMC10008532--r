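Package: spikeline
Title: Mock-Community Spike-In Analysis for 16S rRNA Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of 16S rRNA gene amplicon experiments that use an
    in-situ mock community (MC) spike-in as a positive control. Detects
    mock-community sequence variants (MC-SVs) in denoised SV count tables
    by pairwise identity to reference 16S sequences, classifies primary
    and secondary variants, computes spike-in quality-control metrics
    (MC read fraction, gram-negative to gram-positive read ratio as an
    extraction-bias diagnostic), estimates the absolute number of 16S
    gene copies per library from the spiked reference taxon, rescales SV
    counts to absolute copy scale, flags copy-number outliers, and
    recommends spike-in doses. Includes a synthetic spiked-community
    generator with known ground truth, and a diversity stack: CLR
    normalization, rarefaction, alpha diversity and Hill numbers with
    bootstrap rarefaction curves, Euclidean and Bray-Curtis distances,
    principal coordinates analysis, and permutational multivariate
    ANOVA (PERMANOVA) with sequential sums of squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    biomformat,
    vegan,
    withr,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
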