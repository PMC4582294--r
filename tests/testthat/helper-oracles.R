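# Independent R-level oracles used to check the compiled implementation.
# These deliberately share no code with the package internals.

o_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

o_canonical <- function(x) {
  r <- o_revcomp(x)
  ifelse(r < x, r, x)
}

# All canonical k-mers of a sequence (ACGT-only windows).
o_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  w <- substring(seq, 1:(L - k + 1), k:L)
  w <- w[grepl("^[ACGT]+$", w)]
  o_canonical(w)
}

# Exact k-mer set as an environment for O(1) membership.
o_kmer_env <- function(kmers) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (x in kmers) assign(x, TRUE, envir = e)
  e
}

o_member <- function(env, word) {
  exists(o_canonical(word), envir = env, inherits = FALSE)
}

# Brute-force application of the anchor rule to a logical mask:
# runs of >= 3 solid positions -> the run whose 3'-most position is
# largest, anchor at its 5'-most position; else the longest run (ties
# toward 3'). Returns the 0-based offset, or NA.
o_select_anchor <- function(mask) {
  if (!length(mask) || !any(mask)) return(NA_integer_)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])
  big <- runs[runs$len >= 3, ]
  pick <- if (nrow(big)) big[which.max(big$end), ]
          else runs[runs$len == max(runs$len), ][
            which.max(runs[runs$len == max(runs$len), "end"]), ]
  pick$start - 1L  # 0-based
}

# Exhaustive depth-limited DFS between two oriented words over an exact
# k-mer set: the path-set oracle for the bidirectional search. Node
# revisits are allowed (the depth limit bounds the recursion), matching
# the search contract. Returns a list of oriented-node vectors.
o_dfs_paths <- function(env, start, goal, depth_limit) {
  k <- nchar(start)
  out <- list()
  recurse <- function(path) {
    node <- path[length(path)]
    if (node == goal) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) >= depth_limit) return(invisible())
    stem <- substr(node, 2, k)
    for (b in c("A", "C", "G", "T")) {
      nxt <- paste0(stem, b)
      if (o_member(env, nxt)) recurse(c(path, nxt))
    }
  }
  if (o_member(env, start)) recurse(start)
  out
}

# Canonical form of a path set for comparison: sorted spelled sequences.
o_path_set <- function(paths) {
  sort(vapply(paths, function(p) {
    k <- nchar(p[1])
    paste0(p[1], paste(substr(p[-1], k, k), collapse = ""))
  }, ""))
}

# Random ACGT string from the test RNG (independent of the simulator).
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Plant a false-positive spur of `len` nodes branching rightward off
# `word`; returns the spur's canonical k-mers or NULL if no safe spur
# (one whose first node is absent from `env`) exists.
plant_spur <- function(env, word, len) {
  k <- nchar(word)
  spur <- character(0)
  cur <- word
  for (i in seq_len(len)) {
    stem <- substr(cur, 2, k)
    cand <- paste0(stem, c("A", "C", "G", "T"))
    free <- cand[!vapply(cand, function(w) o_member(env, w), TRUE)]
    if (!length(free)) return(NULL)
    cur <- free[1]
    spur <- c(spur, cur)
  }
  o_canonical(spur)
}
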