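# Canonical k-mer primitives and the cascading Bloom filter node set.

#' Reverse complement
#'
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) .revcomp_cpp(as.character(x))

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a word and its
#' reverse complement, making graph membership strand-symmetric. Words
#' containing symbols outside ACGT are rejected; callers split reads at
#' such symbols instead of creating degenerate k-mers.
#'
#' @param x Character vector of ACGT words.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("TTTT", "ACGT"))
#' @export
canonical_kmer <- function(x) .canonical_cpp(as.character(x))

#' Shred a read into canonical k-mers
#'
#' One canonical k-mer per position; windows containing a non-ACGT symbol
#' yield no k-mer (the read is effectively split at those positions).
#'
#' @param read A single sequence.
#' @param k K-mer length.
#' @return Character vector of canonical k-mers (empty if the read is
#'   shorter than `k`).
#' @examples
#' kmerize("ACGTA", 4)
#' @export
kmerize <- function(read, k) .kmerize_cpp(as.character(read)[1], as.integer(k))

# ---- plain Bloom filter ----------------------------------------------

#' Create a Bloom filter
#'
#' A bit array of `m` bits addressed by `h` hash values per key (two
#' fixed-seed 64-bit hashes combined by enhanced double hashing, so filter
#' contents are reproducible). No false negatives; false positives at the
#' classical rate \eqn{(1 - e^{-hn/m})^h}.
#'
#' @param m Size in bits.
#' @param h Number of hash functions.
#' @return A `konnector_bloom` object.
#' @examples
#' f <- bloom_filter(1024, 3)
#' bloom_insert(f, "ACGTACGT")
#' bloom_contains(f, c("ACGTACGT", "TTTTTTTT"))
#' @export
bloom_filter <- function(m, h) {
  stopifnot(m >= 1, h >= 1)
  structure(list(ptr = .bloom_new(as.numeric(m), as.integer(h))),
            class = "konnector_bloom")
}

#' Insert keys into a Bloom filter
#' @param f A `konnector_bloom` object.
#' @param keys Character vector of keys.
#' @return The filter, invisibly (modified in place).
#' @export
bloom_insert <- function(f, keys) {
  stopifnot(inherits(f, "konnector_bloom"))
  .bloom_insert_cpp(f$ptr, as.character(keys))
  invisible(f)
}

#' Query a Bloom filter
#' @inheritParams bloom_insert
#' @return Logical vector, `TRUE` for every key previously inserted
#'   (guaranteed) and spuriously for others at the false-positive rate.
#' @export
bloom_contains <- function(f, keys) {
  stopifnot(inherits(f, "konnector_bloom"))
  .bloom_contains_cpp(f$ptr, as.character(keys))
}

#' Bloom filter parameters and occupancy
#' @param f A `konnector_bloom` object.
#' @return List with `m`, `h` and `n_inserted`.
#' @export
bloom_info <- function(f) {
  stopifnot(inherits(f, "konnector_bloom"))
  s <- .bloom_state_cpp(f$ptr)
  list(m = s$m, h = s$h, n_inserted = s$n_inserted)
}

#' Expected Bloom filter false-positive rate
#'
#' Classical approximation \eqn{(1 - e^{-hn/m})^h} for a filter of `m`
#' bits, `h` hashes and `n` inserted keys.
#'
#' @param m Bits. @param h Hashes. @param n Distinct keys inserted.
#' @return Expected false-positive probability.
#' @export
expected_fpr <- function(m, h, n) (1 - exp(-h * n / m))^h

#' @export
print.konnector_bloom <- function(x, ...) {
  s <- bloom_info(x)
  cat(sprintf("Bloom filter: m = %s bits, h = %d, %s inserts\n",
              format(s$m, big.mark = ","), s$h,
              format(s$n_inserted, big.mark = ",")))
  invisible(x)
}

# ---- cascading (two-level) Bloom filter -------------------------------

#' Create a two-level cascading Bloom filter
#'
#' K-mers are propagated between two Bloom filters: the first holds
#' k-mers seen at least once, the second k-mers seen at least twice. The
#' second level screens out the bulk of sequencing-error k-mers and is the
#' node set of the de Bruijn graph; the first level can be discarded once
#' loading completes.
#'
#' Default sizing follows roughly 12 bits per expected k-mer across both
#' levels (about 1.5 bytes), split equally; `h` defaults to
#' `round(ln 2 * m / n)` with a floor of 1 when `n_expected` is given,
#' else 4 (the value that rule yields at 6 bits per key per level).
#'
#' @param k K-mer length.
#' @param bits Total bits across both levels.
#' @param h Hash functions per level; see Details for the default.
#' @param n_expected Expected number of distinct k-mers (used only to
#'   derive `h` when `h` is `NULL`).
#' @param levels Cascade depth; only 2 is supported.
#' @return A `konnector_cascade` object.
#' @examples
#' cf <- cascading_bloom(k = 5, bits = 2048)
#' cascade_insert(cf, c("ACGTA", "ACGTA", "TTTTT"))
#' cascade_contains(cf, c("ACGTA", "TTTTT"))
#' @export
cascading_bloom <- function(k, bits, h = NULL, n_expected = NULL, levels = 2) {
  stopifnot(k >= 1, bits >= 2)
  if (levels != 2)
    stop("only a two-level cascade is supported")
  m_per_level <- floor(bits / 2)
  if (is.null(h)) {
    h <- if (!is.null(n_expected) && n_expected > 0)
      max(1L, as.integer(round(log(2) * m_per_level / n_expected)))
    else 4L
  }
  structure(
    list(ptr = .cascade_new(as.integer(k), as.numeric(m_per_level),
                            as.integer(h)),
         k = as.integer(k), levels = 2L),
    class = "konnector_cascade")
}

#' Insert k-mers into a cascading Bloom filter
#'
#' Each word is canonicalized; a word already present in level 1 is
#' promoted into level 2, otherwise it is recorded in level 1.
#'
#' @param cf A `konnector_cascade` object.
#' @param words Character vector of length-`k` ACGT words.
#' @return The filter, invisibly (modified in place).
#' @export
cascade_insert <- function(cf, words) {
  stopifnot(inherits(cf, "konnector_cascade"))
  .cascade_insert_cpp(cf$ptr, as.character(words))
  invisible(cf)
}

#' Query a cascading Bloom filter
#' @inheritParams cascade_insert
#' @param level 2 (default) queries the seen-at-least-twice level; 1 the
#'   seen-at-least-once level (only before it is discarded).
#' @return Logical vector of memberships.
#' @export
cascade_contains <- function(cf, words, level = 2) {
  stopifnot(inherits(cf, "konnector_cascade"), level %in% c(1, 2))
  .cascade_contains_cpp(cf$ptr, as.character(words), as.integer(level))
}

#' Cascade parameters and occupancy
#' @param cf A `konnector_cascade` object.
#' @return List of `k`, `levels`, `m_per_level`, `h`, per-level insert
#'   counts and whether level 1 has been discarded.
#' @export
cascade_info <- function(cf) {
  stopifnot(inherits(cf, "konnector_cascade"))
  .cascade_info_cpp(cf$ptr)
}

#' Discard level 1 after loading
#'
#' After all reads are loaded, only the seen-twice level is needed for
#' graph traversal; dropping level 1 halves resident memory. Further
#' inserts are refused.
#'
#' @param cf A `konnector_cascade` object.
#' @return The filter, invisibly.
#' @export
drop_level1 <- function(cf) {
  stopifnot(inherits(cf, "konnector_cascade"))
  .cascade_drop_level1_cpp(cf$ptr)
  invisible(cf)
}

#' @export
print.konnector_cascade <- function(x, ...) {
  s <- cascade_info(x)
  cat(sprintf(
    "Cascading Bloom filter: k = %d, %s bits/level, h = %d\n", s$k,
    format(s$m_per_level, big.mark = ","), s$h))
  cat(sprintf("  level 1 (seen >= 1): %s inserts%s\n",
              format(s$n_level1, big.mark = ","),
              if (s$level1_dropped) " [discarded]" else ""))
  cat(sprintf("  level 2 (seen >= 2): %s inserts\n",
              format(s$n_level2, big.mark = ",")))
  invisible(x)
}

# ---- read loading -----------------------------------------------------

#' Load reads into a cascading Bloom filter
#'
#' Builds the node set of the de Bruijn graph from sequencing reads:
#' every k-mer occurring at least twice in the (quality-trimmed) input
#' ends up in level 2. FASTQ reads are hard-trimmed at the 3' side from
#' the first base with Phred quality below `q`; FASTA input skips
#' trimming. Reads are split at non-ACGT symbols.
#'
#' `bits` defaults to 12 times the total number of input bases -- an upper
#' bound on the number of distinct k-mers, so the realized false-positive
#' rate is at or below the ~1.5-bytes-per-k-mer design point.
#'
#' @param files Character vector of FASTA/FASTQ paths (optionally
#'   gzip-compressed), or a list as returned by [read_seqs()].
#' @param k K-mer length.
#' @param bits Total filter size in bits (both levels); see Details.
#' @param h Hash functions per level (default derived as in
#'   [cascading_bloom()]).
#' @param q Phred quality threshold for the 3' hard trim (0 disables).
#' @param drop_level1 Discard the seen-once level when loading completes.
#' @return A `konnector_cascade` holding the loaded k-mer spectrum.
#' @export
bloom_build <- function(files, k, bits = NULL, h = NULL, q = 15,
                        drop_level1 = TRUE) {
  reads <- if (is.list(files) && !is.null(files$seq)) files
           else read_seqs_many(files)
  total_bases <- sum(nchar(reads$seq))
  if (is.null(bits) || is.na(bits)) bits <- max(1024, 12 * total_bases)
  cf <- cascading_bloom(k, bits, h = h, n_expected = total_bases)
  .cascade_insert_reads_cpp(cf$ptr, reads$seq, reads$qual, as.integer(q))
  if (drop_level1) .cascade_drop_level1_cpp(cf$ptr)
  cf
}

# ---- on-disk format ---------------------------------------------------

.BLOOM_MAGIC <- "KONBLOOM"
.BLOOM_VERSION <- 1L

.write_u64 <- function(con, x) {
  # doubles are exact below 2^53, far beyond any filter built here
  writeBin(as.integer(c(x %% 2^32 - (x %% 2^32 >= 2^31) * 2^32,
                        x %/% 2^32)), con, size = 4, endian = "little")
}

.read_u64 <- function(con) {
  v <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(v) < 2) stop("truncated Bloom filter file")
  lo <- v[1] + (v[1] < 0) * 2^32
  lo + v[2] * 2^32
}

#' Save a cascading Bloom filter
#'
#' Writes the bit-exact on-disk format: a little-endian header (magic
#' `"KONBLOOM"`, version, k, cascade levels, number of stored arrays)
#' followed by the stored level's parameters and raw bit array. Only the
#' seen-twice level is stored: level 1 exists only during loading.
#'
#' @param cf A `konnector_cascade` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_bloom <- function(cf, path) {
  stopifnot(inherits(cf, "konnector_cascade"))
  st <- .cascade_state_cpp(cf$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.BLOOM_MAGIC, con, nchars = 8, eos = NULL)
  writeBin(as.integer(c(.BLOOM_VERSION, st$k, st$levels, 1L)), con,
           size = 4, endian = "little")
  .write_u64(con, st$m)
  writeBin(as.integer(st$h), con, size = 4, endian = "little")
  .write_u64(con, st$n_level2)
  writeBin(st$bits_level2, con)
  invisible(path)
}

#' Load a cascading Bloom filter
#'
#' Restores a filter written by [save_bloom()]. Refuses files with a bad
#' magic, an unsupported version, or a truncated bit array; if `k` is
#' given, a k mismatch is an error.
#'
#' @param path File written by [save_bloom()].
#' @param k Optional expected k-mer length.
#' @return A `konnector_cascade` (level 1 already discarded).
#' @export
load_bloom <- function(path, k = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, .BLOOM_MAGIC))
    stop("not a Bloom filter file (bad magic): ", path)
  hd <- readBin(con, "integer", n = 4, size = 4, endian = "little")
  if (length(hd) < 4) stop("truncated Bloom filter file: ", path)
  if (hd[1] != .BLOOM_VERSION)
    stop("unsupported Bloom filter file version ", hd[1])
  if (!is.null(k) && hd[2] != k)
    stop(sprintf("filter was built with k = %d, not k = %d", hd[2], k))
  m <- .read_u64(con)
  h <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  n2 <- .read_u64(con)
  nbytes <- ceiling(m / 8)
  bits <- readBin(con, "raw", n = nbytes)
  if (length(bits) != nbytes) stop("truncated Bloom filter file: ", path)
  structure(
    list(ptr = .cascade_from_state_cpp(hd[2], m, h, n2, bits),
         k = hd[2], levels = hd[3]),
    class = "konnector_cascade")
}
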