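Package: konnector
Title: Pseudo-Long Reads from Paired-End Reads via a Bloom Filter de
    Bruijn Graph
Version: 2.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates long "pseudo-reads" from paired-end short sequencing
    reads by searching for connecting paths in a memory-efficient de Bruijn
    graph represented implicitly by a two-level (cascading) Bloom filter.
    Read pairs are joined by a depth-limited bidirectional breadth-first
    search between trusted anchor k-mers; multiple connecting paths are
    collapsed to a consensus, connected and unconnected sequences can be
    extended to the next branching point or dead end, and a duplicate
    filter suppresses re-assembly of already covered loci. Includes a
    scaffold gap-closing application that targets N-runs in draft
    assemblies with a sweep of k-mer sizes, and a paired-end read simulator
    that provides exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
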