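# Extension of connected and unconnected sequences, unconnected-read
# correction, and the duplicate filter that suppresses re-assembly of
# already covered loci.

#' Duplicate filter
#'
#' A Bloom filter over the k-mers of every sequence already emitted.
#' Querying it decides whether a new connecting (or corrected) sequence
#' covers any genomic territory not yet assembled.
#'
#' @param k K-mer length.
#' @param bits Filter size in bits (defaults in [konnect()] to the graph
#'   filter's size).
#' @param h Hash functions.
#' @return A `konnector_dup` object.
#' @export
dup_filter <- function(k, bits, h = 4) {
  structure(list(filter = bloom_filter(bits, h), k = as.integer(k)),
            class = "konnector_dup")
}

#' Register an emitted sequence in the duplicate filter
#' @param d A `konnector_dup` object.
#' @param seq Sequence whose canonical k-mers are added.
#' @return The filter, invisibly (modified in place).
#' @export
register_seq <- function(d, seq) {
  stopifnot(inherits(d, "konnector_dup"))
  km <- kmerize(seq, d$k)
  if (length(km)) bloom_insert(d$filter, km)
  invisible(d)
}

#' Does a query carry any unseen k-mer?
#'
#' `TRUE` iff at least one of the k-mers is absent from the duplicate
#' filter; an empty query is not novel.
#'
#' @param d A `konnector_dup` object.
#' @param kmers Character vector of k-mers (e.g. from [kmerize()]).
#' @return Logical scalar.
#' @export
is_novel <- function(d, kmers) {
  stopifnot(inherits(d, "konnector_dup"))
  if (length(kmers) == 0) return(FALSE)
  !all(bloom_contains(d$filter, canonical_kmer(kmers)))
}

#' Extend a sequence to the next ambiguity in the graph
#'
#' Walks outward from a trusted k-mer near the sequence end, one base per
#' linear step, until a dead end, an uncollapsable fork, or a revisited
#' node (cycle guard). Branches of at most three nodes are taken to be
#' Bloom false positives and ignored; a fork with exactly two surviving
#' branches triggers a look-ahead of k+1 nodes and is collapsed when the
#' branches reconverge (the lexicographically smaller arm is emitted).
#' The seed is chosen anchor-style: the outermost solid k-mer preceded by
#' two solid k-mers where one exists; bases beyond the seed are re-derived
#' through the graph.
#'
#' @param g A `konnector_dbg` graph.
#' @param seq Sequence to extend (its trusted end k-mers must be graph
#'   members for any extension to happen).
#' @param direction `"both"`, `"left"` or `"right"` (relative to `seq` as
#'   written).
#' @param max_left,max_right Caps on appended bases per side.
#' @return The extended sequence (possibly `seq` unchanged).
#' @export
extend_seq <- function(g, seq, direction = c("both", "left", "right"),
                       max_left = Inf, max_right = Inf) {
  stopifnot(inherits(g, "konnector_dbg"))
  direction <- match.arg(direction)
  .extend_seq_cpp(g$ptr, as.character(seq)[1],
                  direction %in% c("both", "left"),
                  direction %in% c("both", "right"),
                  as.numeric(max_left), as.numeric(max_right))
}

#' Attempt to collapse a bubble at a fork
#'
#' For a fork with exactly two surviving (non-false-positive) branches, a
#' look-ahead of k+1 nodes per arm checks whether the branches
#' reconverge; if so the bubble is collapsed and extension can continue
#' through the returned continuation node. Heterozygous SNPs create
#' exactly such bubbles.
#'
#' @param g A `konnector_dbg` graph.
#' @param kmer Oriented fork word.
#' @param direction Side of the fork.
#' @return `NULL` when not collapsible, else a list with `continuation`
#'   (the reconvergence node), `arm` (chosen arm nodes) and `n_nodes`.
#' @export
collapse_bubble <- function(g, kmer, direction = c("right", "left")) {
  stopifnot(inherits(g, "konnector_dbg"))
  r <- .collapse_bubble_cpp(g$ptr, as.character(kmer)[1],
                            match.arg(direction))
  if (length(r) == 0) NULL else r
}

#' Correct an unconnected read against the graph
#'
#' Takes the longest run of solid k-mers in the read, steps left through
#' the graph by exactly k nodes from the run's rightmost k-mer (aborting
#' on a branch or dead end -- a single sequencing error can create
#' branches of up to k nodes, so this walk provably exits them), then
#' steps right up to k+1 nodes, stopping early at a branch or dead end
#' but keeping the sequence built so far.
#'
#' @param g A `konnector_dbg` graph.
#' @param read The read, as given.
#' @return A high-confidence sequence (up to 2k+1 bases), or `NULL` when
#'   the read has no solid k-mer or the leftward walk aborts.
#' @export
correct_unconnected <- function(g, read) {
  stopifnot(inherits(g, "konnector_dbg"))
  r <- .correct_unconnected_cpp(g$ptr, as.character(read)[1])
  if (is.null(r)) NULL else r
}

#' Process one read pair end-to-end
#'
#' The full per-pair flow: attempt connection; on success, test the
#' connecting sequence's k-mers (only) against the duplicate filter, and
#' if any is unseen extend the pseudo-read outward in both directions,
#' register the extended sequence and emit it. On failure, correct each
#' read independently (read 1 then read 2, the second tested after the
#' first is registered), test novelty, extend both inward (capped at
#' `F - read length` appended bases, respecting fragment bounds) and
#' outward, register and emit. With `extend = FALSE` the pre-extension
#' behaviour is kept: one pseudo-read per connected pair, no duplicate
#' filtering.
#'
#' @param g A `konnector_dbg` graph.
#' @param d A [dup_filter()] (may be `NULL` when `extend = FALSE`).
#' @param read1,read2 The pair, as sequenced.
#' @param params A [connect_params()] object.
#' @param extend Enable extension + duplicate filtering.
#' @param all_paths Keep alternate path sequences in the result.
#' @return List with `status` (the connection outcome), `connected`
#'   (logical) and `reads`: a list of emitted records, each with `seq`
#'   and `provenance` (`"connected"`, `"connected_extended"` or
#'   `"unconnected_extended"`).
#' @export
process_pair <- function(g, d, read1, read2, params, extend = TRUE,
                         all_paths = FALSE) {
  res <- connect_pair(g, read1, read2, params, all_paths = all_paths)
  out <- list()
  if (!extend) {
    if (identical(res$status, "success"))
      out[[1]] <- list(seq = res$pseudo, provenance = "connected")
    return(list(status = res$status,
                connected = identical(res$status, "success"),
                reads = out, paths = res$paths))
  }
  stopifnot(inherits(d, "konnector_dup"))
  if (identical(res$status, "success")) {
    # only the connecting k-mers decide novelty: they are putative
    # non-error k-mers, so a covered locus gives a 100% duplicate match
    if (is_novel(d, kmerize(res$connector, params$k))) {
      ext <- extend_seq(g, res$pseudo, "both")
      register_seq(d, ext)
      out[[length(out) + 1]] <- list(seq = ext,
                                     provenance = "connected_extended")
    }
  } else {
    inward_cap <- function(r) max(0, params$F - nchar(r))
    for (r in list(read1, read2)) {
      cor <- correct_unconnected(g, r)
      if (is.null(cor)) next
      if (!is_novel(d, kmerize(cor, params$k))) next
      # inward = rightward: both reads face the gap with their 3' ends
      ext <- extend_seq(g, cor, "both", max_left = Inf,
                        max_right = inward_cap(r))
      register_seq(d, ext)
      out[[length(out) + 1]] <- list(seq = ext,
                                     provenance = "unconnected_extended")
    }
  }
  list(status = res$status, connected = identical(res$status, "success"),
       reads = out, paths = res$paths)
}
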