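Package: rdnarip
Title: Discovery and RIP Profiling of Ribosomal DNA Pseudogenes in Fungal
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining 45S ribosomal DNA (18S-ITS1-5.8S-ITS2-28S-IGS)
    repeats from fungal genome assemblies, separating functional rRNA genes
    from pseudogenes created by repeat-induced point (RIP) mutation,
    profiling the dinucleotide-context spectrum of RIP transitions, mapping
    mutations onto rRNA secondary-structure pairing tables, and testing
    whether functional and pseudogenic paralogs separate into distinct
    clades in neighbor-joining phylogenies (p-distance and Kimura
    two-parameter, with bootstrap support). A fully seeded synthetic-genome
    simulator with a mutation-level truth table supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
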