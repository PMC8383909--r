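Package: mamut
Title: Mutation-Accumulation Experiment Analysis for Haploid Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mutation-accumulation (MA) experiments in
    haploid microbes such as Chlamydomonas. Simulates complete synthetic MA
    experiments (GC-rich multi-contig genomes, lognormal between-line rate
    heterogeneity, context-biased mutation spectra, spike-in callability
    probes), determines callable sites and accepts de novo mutations through a
    quality-filter cascade, estimates per-site per-generation mutation rates
    with overdispersion and spatial-clustering tests, computes sequence-context
    features (GC, Shannon entropy, linguistic complexity and their local
    variability, canonical trinucleotide contexts, alternate-DNA-conformation
    motifs), derives GC-corrected mutation spectra and NG86-style Ka/Ks, and
    fits regularized (elastic-net) models of site mutability with calibration
    and cross-dataset prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    glmnet,
    fitdistrplus,
    vcfR,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
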