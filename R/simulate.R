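# Fixture generator: random genomes, diploid variants, paired-end reads
# with substitution errors, and N-masked scaffolds with retained truth.
# The defaults reproduce the synthetic study conditions the connection
# algorithm assumes: 0.1% substitution error, 50-fold coverage, 100 bp
# reads and a 400 +/- 50 bp insert.

# Run code under a fixed, platform-stable RNG without disturbing the
# caller's random stream.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

.BASES <- c("A", "C", "G", "T")

#' Simulation settings
#'
#' @param genome_len Genome length in bases.
#' @param frag_mean,frag_sd Fragment (insert) length distribution, bp.
#' @param read_len Read length, bp.
#' @param coverage Fold sequencing coverage.
#' @param err_rate Per-base substitution probability.
#' @param het_snp_rate Per-base heterozygous SNP rate for diploid fixtures.
#' @param seed RNG seed; every simulation is deterministic per seed.
#' @return A `konnector_simconfig` list.
#' @export
sim_config <- function(genome_len = 20000, frag_mean = 400, frag_sd = 50,
                       read_len = 100, coverage = 50, err_rate = 0.001,
                       het_snp_rate = 0, seed = 1) {
  stopifnot(frag_mean >= 2 * read_len, err_rate >= 0, err_rate <= 1,
            het_snp_rate >= 0, het_snp_rate <= 1, coverage > 0)
  structure(list(genome_len = as.integer(genome_len),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 read_len = as.integer(read_len), coverage = coverage,
                 err_rate = err_rate, het_snp_rate = het_snp_rate,
                 seed = as.integer(seed)),
            class = "konnector_simconfig")
}

#' Random genome sequence
#'
#' I.i.d. uniform ACGT bases; deterministic for a given seed.
#'
#' @param length Genome length (>= 1).
#' @param seed RNG seed.
#' @return A single nucleotide string.
#' @export
random_genome <- function(length, seed = 1) {
  stopifnot(length >= 1)
  .with_seed(seed, paste(sample(.BASES, length, replace = TRUE),
                         collapse = ""))
}

# Substitute each base independently with probability err; errors always
# change the base. Returns the mutated reads and the error count.
.apply_errors <- function(reads, err) {
  if (err <= 0 || !length(reads)) return(list(reads = reads, n_errors = 0L))
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) <= 1)
  rl <- rl[1]
  total <- length(reads) * rl
  hit <- which(runif(total) < err)
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)  # offset to a new base
    ri <- (hit - 1L) %/% rl + 1L
    pos <- (hit - 1L) %% rl + 1L
    for (z in seq_along(hit)) {
      old <- substr(reads[ri[z]], pos[z], pos[z])
      new <- .BASES[(match(old, .BASES) - 1L + shift[z]) %% 4L + 1L]
      substr(reads[ri[z]], pos[z], pos[z]) <- new
    }
  }
  list(reads = reads, n_errors = length(hit))
}

#' Simulate paired-end reads with exact ground truth
#'
#' Fragments are drawn from a normal length distribution truncated to
#' `[2 * read_len, genome_len]` with uniform start positions; read 1 is
#' the fragment's 5' prefix and read 2 the reverse complement of its 3'
#' suffix (FR orientation). Substitution errors are i.i.d. per base. The
#' truth table records each pair's exact fragment span, so connection
#' output can be scored by exact sequence equality with no aligner.
#'
#' @param genome Genome string (e.g. from [random_genome()]).
#' @param cfg A [sim_config()].
#' @return List with `id`, `read1`, `read2`, `qual1`, `qual2`, `truth`
#'   (data frame: `id`, `start`, `end` 1-based inclusive, `frag_len`),
#'   `n_errors` and `cfg`.
#' @export
simulate_pairs <- function(genome, cfg = sim_config()) {
  G <- nchar(genome)
  rl <- cfg$read_len
  stopifnot(G > cfg$frag_mean + 4 * cfg$frag_sd)
  n <- max(1L, as.integer(round(cfg$coverage * G / (2 * rl))))
  .with_seed(cfg$seed, {
    frag <- pmin(pmax(round(rnorm(n, cfg$frag_mean, cfg$frag_sd)), 2 * rl), G)
    start <- 1L + as.integer(floor(runif(n) * (G - frag + 1)))
    read1 <- substring(genome, start, start + rl - 1L)
    read2 <- revcomp(substring(genome, start + frag - rl, start + frag - 1L))
    e1 <- .apply_errors(read1, cfg$err_rate)
    e2 <- .apply_errors(read2, cfg$err_rate)
    qual <- strrep("I", rl)
    list(id = sprintf("pair%06d", seq_len(n)),
         read1 = e1$reads, read2 = e2$reads,
         qual1 = rep(qual, n), qual2 = rep(qual, n),
         truth = data.frame(id = sprintf("pair%06d", seq_len(n)),
                            start = start, end = start + frag - 1L,
                            frag_len = as.integer(frag),
                            stringsAsFactors = FALSE),
         n_errors = e1$n_errors + e2$n_errors, cfg = cfg)
  })
}

#' True fragment sequences for simulated pairs
#' @param genome The genome the pairs were simulated from.
#' @param truth The `truth` table of [simulate_pairs()].
#' @return Character vector of exact fragment sequences.
#' @export
true_fragments <- function(genome, truth) {
  substring(genome, truth$start, truth$end)
}

#' Derive a second haplotype by planting heterozygous SNPs
#'
#' @param genome Haplotype 1.
#' @param het_snp_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @return List with `hap2` and `variants` (data frame: `pos` 1-based,
#'   `ref`, `alt`).
#' @export
make_diploid <- function(genome, het_snp_rate, seed = 1) {
  G <- nchar(genome)
  .with_seed(seed, {
    pos <- which(runif(G) < het_snp_rate)
    hap2 <- genome
    ref <- character(length(pos))
    alt <- character(length(pos))
    if (length(pos)) {
      shift <- sample(1:3, length(pos), replace = TRUE)
      for (z in seq_along(pos)) {
        ref[z] <- substr(genome, pos[z], pos[z])
        alt[z] <- .BASES[(match(ref[z], .BASES) - 1L + shift[z]) %% 4L + 1L]
        substr(hap2, pos[z], pos[z]) <- alt[z]
      }
    }
    list(hap2 = hap2,
         variants = data.frame(pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE))
  })
}

#' Mask random windows of a genome with N
#'
#' Places `n_windows` non-overlapping N-runs, at least `min_dist` bases
#' apart and away from the sequence ends (one window per equal-size
#' block, uniformly positioned within it), retaining the masked-out truth
#' sequences. Coordinates are 0-based half-open, matching [find_gaps()].
#'
#' @param genome Genome string.
#' @param n_windows Number of windows.
#' @param len_range Min/max window length.
#' @param seed RNG seed.
#' @param min_dist Minimum distance between windows and from sequence
#'   ends (keep at least the flank length used downstream).
#' @return List with `scaffold` (masked sequence) and `windows` (data
#'   frame: `start`, `end`, `truth`).
#' @export
mask_windows <- function(genome, n_windows, len_range = c(50, 300),
                         seed = 1, min_dist = 150) {
  G <- nchar(genome)
  block <- G %/% n_windows
  if (block < max(len_range) + 2 * min_dist)
    stop("cannot pack ", n_windows, " windows of up to ", max(len_range),
         " bases with ", min_dist, " base spacing into ", G, " bases")
  .with_seed(seed, {
    len <- as.integer(round(runif(n_windows, len_range[1], len_range[2])))
    off <- min_dist +
      as.integer(floor(runif(n_windows) * (block - len - 2 * min_dist + 1)))
    start0 <- (seq_len(n_windows) - 1L) * block + off  # 0-based
    truth <- substring(genome, start0 + 1L, start0 + len)
    scaffold <- genome
    for (z in seq_len(n_windows))
      substr(scaffold, start0[z] + 1L, start0[z] + len[z]) <-
        strrep("N", len[z])
    list(scaffold = scaffold,
         windows = data.frame(start = start0, end = start0 + len,
                              truth = truth, stringsAsFactors = FALSE))
  })
}

#' Write a simulated read set to disk
#'
#' Emits `prefix_1.fq`, `prefix_2.fq`, `prefix_genome.fa` and
#' `prefix_truth.tsv`.
#'
#' @param sim Result of [simulate_pairs()].
#' @param genome The genome the pairs came from.
#' @param prefix Output path prefix.
#' @return Character vector of the paths written, invisibly.
#' @export
write_sim <- function(sim, genome, prefix) {
  p1 <- paste0(prefix, "_1.fq")
  p2 <- paste0(prefix, "_2.fq")
  pg <- paste0(prefix, "_genome.fa")
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq(sim$id, sim$read1, p1, sim$qual1)
  write_fastq(sim$id, sim$read2, p2, sim$qual2)
  write_fasta("genome", genome, pg)
  write.table(sim$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pg, pt))
}
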