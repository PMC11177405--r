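Package: hexatub
Title: Resolving Multi-Isotype Gene Families in Allohexaploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for exhaustively resolving a conserved multi-isotype gene
    family (modelled on the plant tubulin family) in an allopolyploid genome:
    mining family members by local protein alignment and conserved-motif
    scanning, chaining reciprocal-best-hit anchors into collinear runs,
    reconstructing ancestral-karyotype genomic blocks on chromosomes,
    classifying gene relations (homeolog, ortholog, tandem and transposed
    paralog, pseudogene), assigning isotypes by cross-referenced
    phylogeny-synteny-context evidence, quantifying Ka/Ks with the
    Nei-Gojobori (1986) method, and measuring per-subgenome expression
    contributions.  A synthetic allohexaploid genome generator with full
    ground truth supports end-to-end recovery testing without any external
    genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
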