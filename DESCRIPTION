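Package: mirtas
Title: Homology-Based Discovery of Conserved miRNAs and tasiRNAs with
    Herbivory-Response Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies conserved plant microRNAs and trans-acting siRNA
    (TAS) loci in a transcriptome by mismatch-tolerant homology search,
    open-reading-frame based coding filtering, minimum-free-energy hairpin
    folding with stem-loop validation, complementarity-based target and
    TAS-locus prediction with phased 21-nt tasiRNA windows, and
    neighbor-joining phylogenies with bootstrap support.  Classifies small
    RNA responses to simulated herbivory from qPCR (2^-ddCt) and microarray
    data using one-way ANOVA with Fisher's protected LSD and compact letter
    displays, assigning wound-/OS-inducible and jasmonate-dependent or
    -independent labels.  Ships a deterministic synthetic-data generator
    (transcriptomes with planted precursors and coding decoys, TAS
    transcripts, qPCR and microarray tables) so every stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
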