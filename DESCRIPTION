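Package: ltrconv
Title: Detection of Ectopic Gene Conversion Among LTR Elements from
    Haploid Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intra-species phylogenetic analysis of non-allelic (ectopic)
    gene conversion among Long Terminal Repeat (LTR) elements on a haploid
    chromosome. Calls variants from aligned haplotype panels, polarizes them
    on a fixed rooted phylogeny by Fitch parsimony, computes Nei nucleotide
    diversity, detects clusters of phylogenetically equivalent closely
    spaced variants, quantifies their excess with a permutation null and a
    Poisson tail test, identifies donor paralogs by exact identity of the
    derived tract, and bounds conversion tracts with flanking paralogous
    sequence variants. Ships a forward simulator of haploid haplotypes
    evolving on a fixed tree under point mutation and gene conversion from
    diverged donor paralogs, with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
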