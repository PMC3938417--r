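Package: mtpopgen
Title: Mitochondrial Haplotype Diversity, Neutrality Tests and Forward
    Drift Simulation for Pest Rodent Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mitochondrial DNA phylogeography of pest rodents:
    haplotype collapsing from aligned sequences (including partial
    sequences assigned by the minimal distance rule), haplotype and
    nucleotide diversity summaries, haplotype-frequency Fst with a
    permutation test, neutrality tests (Tajima's D, Fu's Fs,
    Ramos-Onsins & Rozas's R2) with significance from fixed-S coalescent
    simulation, mismatch-distribution analysis under the sudden-expansion
    model with parametric-bootstrap goodness-of-fit, and forward-time
    Wright-Fisher simulation of mtDNA haplotype drift through
    rodenticide-driven bottlenecks with an unlinked resistance locus
    under balancing selection. Ships the haplotype count tables of a
    global Norway rat survey as fixtures and a synthetic-data generator
    so that every statistical stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
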