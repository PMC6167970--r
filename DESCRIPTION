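Package: radelim
Title: Morphological and Genomic Species-Delimitation Diagnostics for
    Freshwater Fish Complexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether nominal species in a morphologically
    plastic complex are diagnosable, built around the inference chain used
    in recent work on the roundtail chub (Gila robusta) group: type-series
    assignment scoring and character diagnosability from morphometric and
    meristic range tables; a RAD-locus variant-processing cascade
    (complex-variant decomposition, indel removal, mitochondrial-contig
    screening, missingness and depth filters, read-backed haplotype
    collapsing); ABBA-BABA site-pattern tests of introgression with
    Patterson's D, the f_d admixture-fraction estimator and block-jackknife
    significance; uncorrected-distance phylogenies with monophyly and
    topology-concordance checks; and strict-clock divergence-time
    conversion. A synthetic species-complex generator produces genotype,
    sequence and morphometric data with known truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Phylogenetics, PopulationGenetics, SNP, Software
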