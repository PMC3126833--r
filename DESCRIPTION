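Package: pansort
Title: Lineage Sorting, Diversity Statistics and 454 SNP Calling for
    Bonobo and Chimpanzee Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying incomplete lineage sorting between closely
    related populations, built around multilocus resequencing designs. Provides
    a Hudson-style coalescent simulator with recombination and a two-population
    split model, a 454 pyrosequencing read simulator and SNP-calling filter
    cascade (duplicate removal, gap proximity, mismatch, homopolymer and
    neighbour-quality-score filters with a read-fraction heterozygote rule),
    per-locus and pooled diversity statistics (Watterson's theta, nucleotide
    diversity, Tajima's D, Fu and Li's D*, effective population size), Hudson
    Fst and derived-allele sharing classification, a composite simulation-based
    goodness-of-fit test of the standard neutral model, and posterior-monophyly
    analytics over Bayesian tree samples including majority-rule consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
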