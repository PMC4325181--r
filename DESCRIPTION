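Package: mhctyper
Title: Replicated-Amplicon MHC Genotyping with Artefact Filtering and
    Molecular-Evolution Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping multigene families (MHC class I exon 3) from
    replicated 454-style amplicon sequencing. Simulates barcoded amplicon runs
    with full ground truth (allele pools, multilocus genotypes, per-allele
    amplification efficiencies, PCR/pyrosequencing errors and chimeras),
    demultiplexes dual-MID reads, and calls alleles with a three-step
    artefact-filtering procedure validated across PCR replicates. Estimates
    per-allele relative amplification efficiencies, derives minimum read-depth
    thresholds for reliable genotyping, and computes sequence diversity
    (variable sites, nucleotide diversity, Watterson's theta, Hudson-Kaplan
    four-gamete recombination minimum), Nei-Gojobori/Jukes-Cantor dN/dS over
    peptide-binding-region partitions, and amino-acid z-descriptor supertype
    clustering with BIC model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
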