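Package: ggmrice
Title: Gene-Genealogy-Based Mutation Analysis of Rice Domestication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies mutations observed in per-locus ortholog alignments of
    Asian rice (Oryza sativa indica and japonica) and its two wild parents
    (O. rufipogon and O. nivara) onto the branches of a fixed four-taxon gene
    genealogy, separating early (pre indica/japonica split) from lineage-specific
    domestication mutations. Provides the intron-calibrated 3u threshold test for
    positive selection on 5' regulatory regions, per-branch Nei-Gojobori dN/dS
    and amino-acid-rate tests for coding regions, classification of loci into
    eight parental-affinity gene types including single-crossover recombinant
    alleles, a population-genetic estimator of the relative duration of the early
    domestication phase, and a synthetic-data generator that emulates the
    hybrid-origin structure of the rice genome with fully known planted mutation
    histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
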