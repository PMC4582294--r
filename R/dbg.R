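# Implicit de Bruijn graph over a k-mer membership structure. Edges are
# never stored: neighbours are found by querying all four single-base
# extensions of a node.

#' Implicit de Bruijn graph over a loaded Bloom filter
#'
#' The node set is the seen-twice level of a cascading Bloom filter;
#' edges are implicit (k-1 base overlaps probed at query time). Traversal
#' carries an oriented word, so "left"/"right" are relative to the word
#' as written, while membership is canonical and strand-symmetric.
#'
#' @param cf A `konnector_cascade` (from [bloom_build()] or
#'   [load_bloom()]).
#' @return A `konnector_dbg` graph handle.
#' @export
dbg_graph <- function(cf) {
  stopifnot(inherits(cf, "konnector_cascade"))
  structure(list(ptr = .graph_new_bloom_cpp(cf$ptr), k = cf$k,
                 backend = "bloom", filter = cf),
            class = "konnector_dbg")
}

#' Exact-set de Bruijn graph
#'
#' A zero-false-positive graph handle backed by a hash set, sharing the
#' traversal contract of the Bloom-backed handle. Useful as an oracle in
#' tests and for constructed fixtures (planted spurs, bubbles).
#'
#' @param kmers Character vector of length-`k` words (canonicalized on
#'   insertion).
#' @param k K-mer length.
#' @return A `konnector_dbg` graph handle.
#' @export
dbg_from_kmers <- function(kmers, k) {
  structure(list(ptr = .graph_new_exact_cpp(as.character(kmers),
                                            as.integer(k)),
                 k = as.integer(k), backend = "exact", filter = NULL),
            class = "konnector_dbg")
}

#' @rdname dbg_from_kmers
#' @param seqs Sequences whose k-mers form the node set.
#' @export
dbg_from_seq <- function(seqs, k) {
  km <- unlist(lapply(as.character(seqs), kmerize, k = k), use.names = FALSE)
  dbg_from_kmers(unique(km), k)
}

#' Node membership
#' @param g A `konnector_dbg` graph.
#' @param words Character vector of length-`k` words (any strand).
#' @return Logical vector.
#' @export
dbg_contains <- function(g, words) {
  stopifnot(inherits(g, "konnector_dbg"))
  .graph_contains_cpp(g$ptr, as.character(words))
}

#' Neighbours of a node
#'
#' The canonical single-base extensions of the oriented word present in
#' the graph, as oriented words (0 to 4 of them).
#'
#' @param g A `konnector_dbg` graph.
#' @param kmer Oriented length-`k` word.
#' @param direction `"right"` extends the 3' side of the oriented word,
#'   `"left"` the 5' side.
#' @return Character vector of oriented neighbour words.
#' @export
dbg_neighbors <- function(g, kmer, direction = c("right", "left")) {
  stopifnot(inherits(g, "konnector_dbg"))
  .graph_neighbors_cpp(g$ptr, as.character(kmer)[1], match.arg(direction))
}

#' Classify a node by its out-degree in one direction
#' @inheritParams dbg_neighbors
#' @return `"dead_end"` (0 neighbours), `"linear"` (1) or `"branching"`
#'   (2 or more).
#' @export
dbg_classify <- function(g, kmer, direction = c("right", "left")) {
  stopifnot(inherits(g, "konnector_dbg"))
  .graph_classify_cpp(g$ptr, as.character(kmer)[1], match.arg(direction))
}

#' @export
print.konnector_dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph handle: k = %d, backend = %s\n", x$k,
              x$backend))
  invisible(x)
}
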