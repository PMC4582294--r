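# Depth-limited bidirectional breadth-first search between anchors, path
# enumeration and the consensus of alternate connecting paths.

#' Tunable parameters of the read-connection algorithm
#'
#' Defaults are the parameter set used throughout the tool's published
#' protocols: up to 4 paths collapsed to a consensus, no mismatch limit,
#' 98% minimum path identity, 100 branches, 525 bp maximum fragment,
#' quality trim 15, a two-level cascade.
#'
#' @param k K-mer length.
#' @param B Maximum branches visited by one pair's search: every dequeued
#'   fork child beyond the first, summed over both frontiers.
#' @param F Maximum fragment (pseudo-read) length in bases; sets the
#'   search depth limit.
#' @param P Maximum number of alternate paths merged into a consensus.
#' @param M Maximum mismatches tolerated between alternate paths
#'   (`Inf` = no limit).
#' @param X Minimum percent identity between alternate paths.
#' @param q Phred threshold for the 3' quality trim at load time.
#' @param levels Bloom cascade depth (2).
#' @return A `konnector_params` list.
#' @examples
#' connect_params(k = 31)
#' @export
connect_params <- function(k, B = 100, F = 525, P = 4, M = Inf, X = 98,
                           q = 15, levels = 2) {
  stopifnot(k >= 1, F > 2 * k, P >= 1, X >= 0, X <= 100, B >= 1, M >= 0)
  structure(list(k = as.integer(k), B = as.numeric(B), F = as.numeric(F),
                 P = as.integer(P), M = as.numeric(M), X = as.numeric(X),
                 q = as.numeric(q), levels = as.integer(levels)),
            class = "konnector_params")
}

#' @export
print.konnector_params <- function(x, ...) {
  cat(sprintf(
    "connect parameters: k=%d B=%g F=%g P=%d M=%s X=%g q=%g levels=%d\n",
    x$k, x$B, x$F, x$P, if (is.infinite(x$M)) "nolimit" else x$M, x$X,
    x$q, x$levels))
  invisible(x)
}

#' Bidirectional depth-limited breadth-first search
#'
#' Two breadth-first searches (from the start anchor rightward, from the
#' goal anchor leftward) that can see each other's visited node lists
#' alternate strictly, forward first. An edge into a node already visited
#' by the other frontier is recorded as a *common edge* and that node is
#' not expanded further by the arriving frontier. Every node and edge
#' touched is recorded in an in-memory search graph from which the full
#' set of connecting paths is later enumerated. Each frontier expands at
#' most `ceiling(depth_limit/2) + 1` node levels.
#'
#' @param g A `konnector_dbg` graph.
#' @param start,goal Oriented anchor words on the fragment's forward
#'   strand (the goal is the reverse complement of the second read's
#'   anchor).
#' @param depth_limit Maximum number of nodes on a connecting path.
#' @param B Branch budget (see [connect_params()]).
#' @param bidirectional `FALSE` runs a plain one-sided depth-limited BFS
#'   under the same contract (used for cross-checking).
#' @return A `konnector_search` object with `status` (`"success"`,
#'   `"no_path"` or `"too_many_branches"`), `branches` and `n_common`.
#' @export
bidi_bfs <- function(g, start, goal, depth_limit, B = 100,
                     bidirectional = TRUE) {
  stopifnot(inherits(g, "konnector_dbg"))
  r <- .bfs_cpp(g$ptr, as.character(start)[1], as.character(goal)[1],
                as.integer(depth_limit), as.numeric(B),
                isTRUE(bidirectional))
  structure(list(ptr = r$ptr, status = r$status, branches = r$branches,
                 n_common = r$n_common, start = start, goal = goal,
                 depth_limit = depth_limit),
            class = "konnector_search")
}

#' @export
print.konnector_search <- function(x, ...) {
  cat(sprintf("search graph: %s -> %s, depth limit %d, status %s (%d common edges, %g branches)\n",
              x$start, x$goal, x$depth_limit, x$status, x$n_common,
              x$branches))
  invisible(x)
}

#' Enumerate all connecting paths of a search graph
#'
#' Exhaustive depth-limited traversal of the recorded search graph; the
#' result is the set of all start-to-goal node paths with at most
#' `depth_limit` nodes.
#'
#' @param sg A `konnector_search` from [bidi_bfs()].
#' @param max_paths Fail with `"too_many_paths"` beyond this many paths.
#' @return List with `status` and `paths` (each a character vector of
#'   oriented k-mers).
#' @export
enumerate_paths <- function(sg, max_paths = 4) {
  stopifnot(inherits(sg, "konnector_search"))
  .enumerate_paths_cpp(sg$ptr, as.integer(max_paths))
}

#' Spell the sequence of a node path
#'
#' @param nodes Character vector of oriented k-mers overlapping by k-1.
#' @return The spelled nucleotide string of length `k + length(nodes) - 1`.
#' @examples
#' path_to_seq(c("ACGT", "CGTA", "GTAC"))
#' @export
path_to_seq <- function(nodes) .path_to_seq_cpp(as.character(nodes))

#' Consensus of alternate connecting paths
#'
#' A single path is returned verbatim. Equal-length paths are collapsed
#' by column-wise majority vote; unequal lengths go through a progressive
#' global multiple alignment first. Pairwise mismatches (gap columns
#' included) above `M`, or pairwise identity below `X` percent, fail with
#' `"paths_disagree"`. Column ties prefer a base over a gap and the
#' lexicographically smallest base, keeping output deterministic.
#'
#' @param seqs Character vector of path sequences.
#' @param M Maximum pairwise mismatches (`Inf` = no limit).
#' @param X Minimum pairwise percent identity.
#' @return List with `status`, `seq`, `max_mismatches`, `min_identity`.
#' @examples
#' consensus_paths(c("ACGTA", "ACCTA", "ACCTA"))
#' @export
consensus_paths <- function(seqs, M = Inf, X = 98) {
  .consensus_cpp(as.character(seqs), as.numeric(M), as.numeric(X))
}

#' Connect one read pair through the de Bruijn graph
#'
#' Anchors are selected in both reads (read 2 as sequenced, its 3' end
#' facing the gap; its anchor is reverse-complemented onto the forward
#' strand as the search goal). A bidirectional depth-limited BFS runs
#' between the anchors with depth limit `F - offset1 - offset2 - k + 1`,
#' so the finished pseudo-read cannot exceed `F` bases; all connecting
#' paths are enumerated and collapsed to a consensus. The pseudo-read is
#' the first read's 5' flank (verbatim), the connecting sequence
#' (anchor-to-anchor, from the graph -- implicit error correction), and
#' the reverse-complemented second read's 3' flank (verbatim).
#'
#' @param g A `konnector_dbg` graph.
#' @param read1,read2 The pair, as sequenced (FR orientation).
#' @param params A [connect_params()] object.
#' @param all_paths Also return every alternate path sequence.
#' @return List with `status` (`"success"` or one of `"no_anchor"`,
#'   `"no_path"`, `"too_many_branches"`, `"too_many_paths"`,
#'   `"paths_disagree"`), `pseudo`, `connector`, anchor offsets, path and
#'   branch counts.
#' @export
connect_pair <- function(g, read1, read2, params, all_paths = FALSE) {
  stopifnot(inherits(g, "konnector_dbg"),
            inherits(params, "konnector_params"))
  if (params$k != g$k)
    stop("params$k does not match the graph's k")
  .connect_pair_cpp(g$ptr, as.character(read1)[1], as.character(read2)[1],
                    params$B, params$F, params$P, params$M, params$X,
                    isTRUE(all_paths))
}
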