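Package: u6phylo
Title: Phylogeography of Mitochondrial Haplogroup U6
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rCRS-relative mitochondrial DNA haplotype handling and the
    phylogeography of haplogroup U6: parsing and comparison of EMPOP-style variant
    motifs, motif-based haplogroup classification against a shipped refined U6 tree
    (complete genomes and HVR-1), rho-statistic coalescence dating with Saillard
    standard errors under a fixed molecular clock, pedigree-based mutation-rate
    estimation with exact confidence intervals and unit conversions, Fisher
    wave-of-advance demic diffusion arithmetic, regional frequency and pi-diversity
    statistics with permutation comparisons and PCA, and a synthetic-data generator
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
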