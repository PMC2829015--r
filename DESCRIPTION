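Package: orthopath
Title: Consensus Ortholog Groups and Metabolic Pathway Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds consensus groups of orthologous proteins across multiple
    genomes by combining independent orthology predictions: a filtered
    best-reciprocal-hit (BRH) detector with score-ratio and
    alignment-percentage filters, homolog-family construction, gene-tree
    based ortholog extraction, crude intersection/union of method outputs,
    and profile-HMM enrichment of the intersection ("reference") groups.
    Each final group carries a 0-10 confidence score measuring agreement
    among the input methods.  Complete four-digit EC numbers are transferred
    to groups from an annotated reference set by profile search, and the
    resulting enzyme complement is mapped onto metabolic pathway definitions
    to report per-species and per-taxon conservation, pathway-specific EC
    numbers and pathway holes.  A deterministic simulator of gene-family
    evolution (duplication, loss, substitution) provides synthetic proteomes
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: HMMER (>= 3.0) (hmmbuild, hmmsearch), MAFFT
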