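# Anchor selection: path searches start from trusted (solid) k-mers so
# that sequencing errors and Bloom false positives near read ends do not
# send the search into a dead end.

#' Solid k-mer mask of a read
#'
#' Position `i` is `TRUE` iff the canonical k-mer starting there is
#' present in the graph (a putative non-error k-mer). Windows containing
#' non-ACGT symbols are `FALSE`.
#'
#' @param g A `konnector_dbg` graph.
#' @param read Read sequence, oriented with its 3' end facing the
#'   fragment gap.
#' @return Logical vector over k-mer start positions (empty if the read
#'   is shorter than `k`).
#' @export
solid_mask <- function(g, read) {
  stopifnot(inherits(g, "konnector_dbg"))
  .solid_mask_cpp(g$ptr, as.character(read)[1])
}

#' Select the anchor k-mer of a read
#'
#' Among runs of at least three consecutive solid k-mers, the run closest
#' to the 3' (gap-facing) end is chosen and the anchor is the 5'-most
#' k-mer of that run: if the anchor itself is a Bloom false positive, the
#' search still proceeds through at least two more solid k-mers. If no
#' run of three exists, the longest run is used (ties resolved toward the
#' 3' end).
#'
#' @inheritParams solid_mask
#' @return A list with `kmer` (oriented as in the read), `offset`
#'   (0-based position of its first base) and `run_len`, or `NULL` when
#'   the read has no solid k-mer.
#' @export
select_anchor <- function(g, read) {
  stopifnot(inherits(g, "konnector_dbg"))
  a <- .select_anchor_cpp(g$ptr, as.character(read)[1])
  if (length(a) == 0) NULL else a
}
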