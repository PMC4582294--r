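# Scaffold gap closing: find N-runs, derive flanks, attempt connection
# over a descending k sweep, and patch closed gaps into the assembly.

#' Find scaffold gaps (N-runs) and their flanks
#'
#' Maximal runs of N, left to right, in 0-based half-open coordinates.
#' Flanks are the up-to-`flank` bases adjacent to the gap, trimmed back
#' at another N-run or the sequence end, so they never contain N; a
#' leading or trailing gap gets an empty flank on its open side.
#'
#' @param scaffolds Named character vector (or `DNAStringSet`) of
#'   scaffold sequences.
#' @param flank Flank length in bases.
#' @return Data frame: `scaffold`, `start`, `end`, `flank5`, `flank3`.
#' @export
find_gaps <- function(scaffolds, flank = 100) {
  scaffolds <- .as_named_seqs(scaffolds)
  out <- list()
  for (nm in names(scaffolds)) {
    s <- toupper(scaffolds[[nm]])
    mm <- gregexpr("N+", s)[[1]]
    if (mm[1] == -1) next
    starts <- as.integer(mm) - 1L  # 0-based
    lens <- attr(mm, "match.length")
    ends <- starts + lens
    for (z in seq_along(starts)) {
      lo <- if (z > 1) ends[z - 1] else 0L        # previous gap's end
      hi <- if (z < length(starts)) starts[z + 1] else nchar(s)
      f5_start <- max(lo, starts[z] - flank)
      f3_end <- min(hi, ends[z] + flank)
      out[[length(out) + 1]] <- data.frame(
        scaffold = nm, start = starts[z], end = ends[z],
        flank5 = substr(s, f5_start + 1L, starts[z]),
        flank3 = substr(s, ends[z] + 1L, f3_end),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), flank5 = character(),
                      flank3 = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.as_named_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  x <- as.list(x)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- sprintf("scaffold%d", seq_along(x))
  x
}

#' Attempt to close one gap over a k sweep
#'
#' For each k in descending order, the 5' flank is treated as read 1 and
#' the reverse complement of the 3' flank as read 2 (both then face the
#' gap with their 3' ends), and a connection is attempted in that k's
#' graph. The first success wins; failure is reported only after the
#' sweep is exhausted.
#'
#' @param gap One row of [find_gaps()] output (as a list or data frame
#'   row).
#' @param graphs Named list of `konnector_dbg` graphs, one per k (names
#'   are the k values).
#' @param params A [connect_params()] object; its `k` is replaced by each
#'   sweep element.
#' @return List with `closed`, and on success `k` and `seq` (the closure
#'   spanning both flanks); `reasons` records the per-k failure reasons.
#' @export
close_gap <- function(gap, graphs, params) {
  ks <- sort(as.integer(names(graphs)), decreasing = TRUE)
  reasons <- character(0)
  for (k in ks) {
    if (nchar(gap$flank5) < k || nchar(gap$flank3) < k) {
      reasons[as.character(k)] <- "flank_too_short"
      next
    }
    pk <- connect_params(k = k, B = params$B, F = params$F, P = params$P,
                         M = params$M, X = params$X, q = params$q)
    res <- connect_pair(graphs[[as.character(k)]], gap$flank5,
                        revcomp(gap$flank3), pk)
    if (identical(res$status, "success"))
      return(list(closed = TRUE, k = k, seq = res$pseudo,
                  reasons = reasons))
    reasons[as.character(k)] <- res$status
  }
  list(closed = FALSE, k = NA_integer_, seq = NA_character_,
       reasons = reasons)
}

#' Patch closed gaps into scaffolds
#'
#' Each closure replaces its gap's N-run together with both flank
#' regions, so the patched scaffold contains the closure verbatim.
#' A closure whose first/last k bases do not match its flanks is left
#' open with a warning; unclosed gaps are untouched, and no base outside
#' a replaced span changes.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param closures Data frame with `scaffold`, `start`, `end`,
#'   `flank5`, `flank3`, `k`, `seq` (`NA` seq = not closed).
#' @return List with `scaffolds` (patched) and `report` (`total`,
#'   `closed`, `percent`, rounded to one decimal).
#' @export
patch_scaffolds <- function(scaffolds, closures) {
  scaffolds <- .as_named_seqs(scaffolds)
  n_closed <- 0L
  if (nrow(closures)) {
    # right-to-left per scaffold keeps earlier coordinates valid
    ord <- order(closures$scaffold, -closures$start)
    for (i in ord) {
      cl <- closures[i, ]
      if (is.na(cl$seq)) next
      k <- cl$k
      f5 <- cl$flank5
      f3 <- cl$flank3
      ok <- nchar(cl$seq) >= k &&
        substr(cl$seq, 1, k) == substr(f5, 1, k) &&
        substr(cl$seq, nchar(cl$seq) - k + 1, nchar(cl$seq)) ==
          substr(f3, nchar(f3) - k + 1, nchar(f3))
      if (!ok) {
        warning("closure inconsistent with flanks for gap at ",
                cl$scaffold, ":", cl$start, "-", cl$end, "; left open")
        next
      }
      s <- scaffolds[[cl$scaffold]]
      repl_start <- cl$start - nchar(f5)  # 0-based
      repl_end <- cl$end + nchar(f3)
      scaffolds[[cl$scaffold]] <-
        paste0(substr(s, 1, repl_start), cl$seq,
               substr(s, repl_end + 1L, nchar(s)))
      n_closed <- n_closed + 1L
    }
  }
  total <- nrow(closures)
  list(scaffolds = unlist(scaffolds),
       report = list(total = total, closed = n_closed,
                     percent = if (total > 0)
                       round(100 * n_closed / total, 1) else NA_real_))
}

#' Close all scaffold gaps with a k sweep
#'
#' Builds one reusable Bloom filter de Bruijn graph per k from the read
#' set, then targets every N-run: flank extraction, per-k connection
#' attempts (largest k first), and patching of successful closures.
#'
#' @param scaffolds Named character vector (or `DNAStringSet`) of draft
#'   scaffolds.
#' @param reads A read list (`list(seq=, qual=)`), a character vector of
#'   sequences, or file paths understood by [bloom_build()].
#' @param ks Integer vector of k-mer sizes to sweep (used in descending
#'   order).
#' @param params Connection parameters; defaults to the gap-closing
#'   protocol `B = 1000, F = 700, P = 10`.
#' @param flank Flank length derived next to each gap.
#' @param bits Per-k graph filter size in bits (see [bloom_build()]).
#' @return List with `scaffolds` (patched), `gaps` (per-gap outcomes:
#'   coordinates, closure k, status), `closures` (successful closure
#'   sequences) and `report` (`total`, `closed`, `percent`).
#' @export
seal <- function(scaffolds, reads, ks,
                 params = connect_params(k = max(ks), B = 1000, F = 700,
                                         P = 10),
                 flank = 100, bits = NULL) {
  scaffolds <- .as_named_seqs(scaffolds)
  if (is.character(reads)) {
    reads <- if (all(file.exists(reads))) read_seqs_many(reads)
             else list(seq = reads, qual = NULL)
  }
  ks <- sort(unique(as.integer(ks)), decreasing = TRUE)
  graphs <- list()
  for (k in ks) {
    cf <- bloom_build(reads, k = k, bits = bits, q = params$q)
    graphs[[as.character(k)]] <- dbg_graph(cf)
  }
  gaps <- find_gaps(scaffolds, flank = flank)
  gaps$k <- NA_integer_
  gaps$seq <- NA_character_
  gaps$status <- "open"
  if (nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      r <- close_gap(gaps[i, ], graphs, params)
      if (r$closed) {
        gaps$k[i] <- r$k
        gaps$seq[i] <- r$seq
        gaps$status[i] <- "closed"
      } else {
        gaps$status[i] <- paste0(
          "open(", paste(names(r$reasons), r$reasons, sep = ":",
                         collapse = ","), ")")
      }
    }
  }
  patched <- patch_scaffolds(scaffolds, gaps)
  list(scaffolds = patched$scaffolds, gaps = gaps,
       closures = gaps[gaps$status == "closed",
                       c("scaffold", "start", "end", "k", "seq")],
       report = patched$report)
}
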