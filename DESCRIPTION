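Package: consensustx
Title: Consensus De Novo Transcriptome Construction and Quality Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a consensus transcriptome from multiple per-sample de
    novo assemblies. Contigs are pooled with provenance-preserving
    identifiers, clustered greedily at a nucleotide identity threshold with
    a conservative shared-word prescreen, and filtered by a two-of-three
    rule on cluster length, contig support and summed FPKM. Reconstruction
    quality of a reference gene panel is scored by self-normalised
    local-alignment bitscore ratios, which also drive isoform prediction.
    Contig-level expression is aggregated to clusters through the
    contig-to-cluster map, normalised to a housekeeping cluster, and
    compared with qPCR measurements. A streaming median k-mer coverage
    normalizer and a fully seeded synthetic multi-assembly generator make
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
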