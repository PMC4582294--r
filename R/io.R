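# FASTA/FASTQ readers and writers (Biostrings-backed, gzip transparent),
# the read-pair stream, the per-run statistics record, and the top-level
# pipeline driver.

.guess_format <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    return("fastq")
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
    return("fasta")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) stop("empty sequence file: ", path)
  if (startsWith(first, "@")) "fastq"
  else if (startsWith(first, ">")) "fasta"
  else stop("cannot determine format (FASTA/FASTQ) of ", path)
}

#' Read sequences from FASTA/FASTQ (optionally gzipped)
#'
#' @param path Input file.
#' @return List with `id` (first header token), `seq` and `qual` (Phred
#'   strings for FASTQ, `NULL` for FASTA).
#' @export
read_seqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- .guess_format(path)
  if (fmt == "fastq") {
    # Biostrings warns about dropped metadata columns on FASTQ input;
    # quality decoding is lazy, so it sits inside the same error guard
    parsed <- tryCatch({
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      list(x = x, qual = as.character(Biostrings::quality(x)))
    }, error = function(e)
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE))
    x <- parsed$x
    qual <- parsed$qual
  } else {
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
    qual <- NULL
  }
  list(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)),
       qual = unname(qual))
}

# Concatenate several files into one read list.
read_seqs_many <- function(paths) {
  parts <- lapply(paths, read_seqs)
  has_q <- vapply(parts, function(p) !is.null(p$qual), logical(1))
  qual <- if (all(has_q))
    unlist(lapply(parts, `[[`, "qual"), use.names = FALSE) else NULL
  list(id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
       seq = unlist(lapply(parts, `[[`, "seq"), use.names = FALSE),
       qual = qual)
}

.strip_mate <- function(id) sub("/[12]$", "", id)

#' Read a paired-end read stream
#'
#' Mates are paired by file position (two-file mode) or adjacency
#' (interleaved mode); gzip input is handled transparently. Pair ids are
#' the read names stripped of `/1` `/2` suffixes; a name mismatch warns
#' but trusts position.
#'
#' @param path1 First-mate file, or the interleaved file.
#' @param path2 Second-mate file (`NULL` for interleaved input).
#' @return List with `id`, `read1`, `read2`, `qual1`, `qual2`.
#' @export
read_pairs <- function(path1, path2 = NULL) {
  if (is.null(path2)) {
    s <- read_seqs(path1)
    n <- length(s$seq)
    if (n %% 2 != 0)
      stop("interleaved file ", path1, " has an odd number of records (",
           n, ")")
    odd <- seq(1L, n, by = 2L)
    even <- odd + 1L
    id1 <- .strip_mate(s$id[odd])
    id2 <- .strip_mate(s$id[even])
    if (any(id1 != id2))
      warning("mate names disagree for ",
              sum(id1 != id2), " interleaved pairs; pairing by position")
    list(id = id1, read1 = s$seq[odd], read2 = s$seq[even],
         qual1 = s$qual[odd], qual2 = s$qual[even])
  } else {
    s1 <- read_seqs(path1)
    s2 <- read_seqs(path2)
    if (length(s1$seq) != length(s2$seq))
      stop(sprintf("record count mismatch: %s has %d records, %s has %d",
                   path1, length(s1$seq), path2, length(s2$seq)))
    id1 <- .strip_mate(s1$id)
    id2 <- .strip_mate(s2$id)
    if (any(id1 != id2))
      warning("mate names disagree for ", sum(id1 != id2),
              " pairs; pairing by position")
    list(id = id1, read1 = s1$seq, read2 = s2$seq,
         qual1 = s1$qual, qual2 = s2$qual)
  }
}

#' Write sequences as FASTA
#' @param ids Record names. @param seqs Sequences. @param path Output.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 60) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write sequences as FASTQ
#' @inheritParams write_fasta
#' @param quals Phred quality strings (defaults to uniform Q40).
#' @export
write_fastq <- function(ids, seqs, path, quals = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  q <- Biostrings::PhredQuality(quals)
  y <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(y, path)
  invisible(path)
}

#' Write pseudo-reads as FASTA
#'
#' Headers carry the source pair id and the provenance tag
#' (`connected`, `connected_extended` or `unconnected_extended`);
#' sequence lines wrap at 60 columns.
#'
#' @param pseudo_reads Data frame from [konnect()] (`id`, `provenance`,
#'   `seq`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pseudo_reads <- function(pseudo_reads, path) {
  write_fasta(paste(pseudo_reads$id, pseudo_reads$provenance),
              pseudo_reads$seq, path, width = 60)
}

# ---- pipeline ---------------------------------------------------------

.FAIL_REASONS <- c("no_anchor", "no_path", "too_many_branches",
                   "too_many_paths", "paths_disagree")

#' Connect a whole read set
#'
#' Runs the per-pair flow of [process_pair()] over every pair, in input
#' order (the duplicate filter makes order matter; the order is fixed for
#' determinism), and tallies run statistics. The graph is built from the
#' reads themselves when not supplied.
#'
#' @param pairs A pair list as from [read_pairs()] (fields `id`, `read1`,
#'   `read2`, optionally `qual1`, `qual2`).
#' @param params A [connect_params()] object.
#' @param graph Optional prebuilt `konnector_dbg`; default builds a
#'   cascading Bloom filter from the reads at `params$k` with quality
#'   trim `params$q`.
#' @param extend Extend and de-duplicate (the v2 behaviour); `FALSE`
#'   emits one pseudo-read per connected pair with no duplicate filter.
#' @param all_paths Also collect every alternate connecting path.
#' @param bits Graph filter size in bits (see [bloom_build()]).
#' @param dup_bits Duplicate filter size in bits; defaults to the graph
#'   filter's total size.
#' @return List with `pseudo_reads` (data frame: `id`, `provenance`,
#'   `length`, `seq`), `stats` (see [write_stats()]) and `paths` (named
#'   list, when `all_paths`).
#' @export
konnect <- function(pairs, params, graph = NULL, extend = TRUE,
                    all_paths = FALSE, bits = NULL, dup_bits = NULL) {
  stopifnot(inherits(params, "konnector_params"))
  n <- length(pairs$read1)
  if (is.null(graph)) {
    quals <- if (!is.null(pairs$qual1) && !is.null(pairs$qual2))
      c(pairs$qual1, pairs$qual2) else NULL
    cf <- bloom_build(list(seq = c(pairs$read1, pairs$read2), qual = quals),
                      k = params$k, bits = bits, q = params$q)
    graph <- dbg_graph(cf)
  }
  stopifnot(inherits(graph, "konnector_dbg"))
  d <- NULL
  if (extend) {
    if (is.null(dup_bits) || is.na(dup_bits)) {
      dup_bits <- if (identical(graph$backend, "bloom"))
        2 * cascade_info(graph$filter)$m_per_level
      else max(1024, 12 * sum(nchar(pairs$read1), nchar(pairs$read2)))
    }
    d <- dup_filter(params$k, dup_bits)
  }
  ids <- if (!is.null(pairs$id)) pairs$id else sprintf("pair%06d", seq_len(n))

  failures <- setNames(numeric(length(.FAIL_REASONS)), .FAIL_REASONS)
  connected <- 0
  connected_unique <- 0
  unconnected_emitted <- 0
  out_id <- character(0)
  out_prov <- character(0)
  out_seq <- character(0)
  paths <- if (all_paths) list() else NULL

  for (i in seq_len(n)) {
    pr <- process_pair(graph, d, pairs$read1[i], pairs$read2[i], params,
                       extend = extend, all_paths = all_paths)
    if (pr$connected) {
      connected <- connected + 1
      if (length(pr$reads)) connected_unique <- connected_unique + 1
    } else {
      failures[pr$status] <- failures[pr$status] + 1
      unconnected_emitted <- unconnected_emitted + length(pr$reads)
    }
    for (rec in pr$reads) {
      out_id <- c(out_id, ids[i])
      out_prov <- c(out_prov, rec$provenance)
      out_seq <- c(out_seq, rec$seq)
    }
    if (all_paths && !is.null(pr$paths) && length(pr$paths) > 1)
      paths[[ids[i]]] <- pr$paths
  }
  stats <- list(pairs_total = n, pairs_connected = connected,
                connected_unique = connected_unique,
                unconnected_emitted = unconnected_emitted,
                failures = failures,
                bases_emitted = sum(nchar(out_seq)))
  list(pseudo_reads = data.frame(id = out_id, provenance = out_prov,
                                 length = nchar(out_seq), seq = out_seq,
                                 stringsAsFactors = FALSE),
       stats = stats, paths = paths)
}

#' Write run statistics
#'
#' One `key<TAB>value` line per statistic, stable key set, for
#' scriptability. The identity
#' `pairs_connected + sum(failures) == pairs_total` holds on every run.
#'
#' @param stats The `stats` element of a [konnect()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  keys <- c(pairs_total = stats$pairs_total,
            pairs_connected = stats$pairs_connected,
            connected_unique = stats$connected_unique,
            unconnected_emitted = stats$unconnected_emitted,
            setNames(as.numeric(stats$failures),
                     paste0("failed_", names(stats$failures))),
            bases_emitted = stats$bases_emitted)
  writeLines(paste(names(keys), format(keys, scientific = FALSE,
                                       trim = TRUE), sep = "\t"), path)
  invisible(path)
}
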