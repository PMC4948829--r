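Package: telodiverge
Title: Divergence-Point Analysis of Cloned Yeast Telomere Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of cloned, Sanger-sequenced yeast telomeres from
    clonal populations. Selects a reference telomere per clone set, aligns
    each clone from the centromere-proximal end with an affine-gap
    semi-global aligner, locates the point where a clone's sequence
    diverges from the reference under explicit tolerance rules (isolated
    point substitutions and indels of at most 6 nt are tolerated), flags
    telomere truncation events (undiverged span below 125 nt), and turns
    per-clone calls into divergence fractions, exact binomial confidence
    intervals and per-generation event rates. Also quantifies liquid
    culture replicative senescence assays as cumulative population
    doublings and compares genotypes at the point of maximum senescence.
    A stochastic generator of degenerate TG1-3 telomeric repeats with
    known ground truth (telomerase-mediated re-extension, end-replication
    shortening, recombination-style divergence events, truncations, and a
    technical artifact layer) makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
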