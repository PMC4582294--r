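# Extension, false-positive branch skipping, bubble collapse, correction
# of unconnected reads, and the duplicate filter.

test_that("an interior seed extends to both ends of a linear genome", {
  set.seed(501)
  k <- 21
  genome <- rand_seq(2000)
  g <- dbg_from_seq(genome, k)
  seed <- substr(genome, 900, 899 + 3 * k)
  expect_equal(extend_seq(g, seed, "both"), genome)
  expect_equal(extend_seq(g, seed, "right"),
               substr(genome, 900, nchar(genome)))
  expect_equal(extend_seq(g, seed, "both", max_left = 10, max_right = 0),
               substr(genome, 890, 899 + 3 * k))
})

test_that("extension stops at a genuine fork but ignores short spurs", {
  set.seed(502)
  k <- 15
  # two >= 4-node arms diverging from the end of a stem
  stem <- rand_seq(120)
  tail <- substr(stem, 121 - k + 1, 120)
  armA <- paste0(tail, "A", rand_seq(7))  # arms diverge at the first base
  armB <- paste0(tail, "C", rand_seq(7))
  g <- dbg_from_seq(c(stem, armA, armB), k)
  got <- extend_seq(g, substr(stem, 40, 39 + 3 * k), "right")
  expect_equal(got, substr(stem, 40, 120))  # stopped at the fork

  # a <= 3-node spur is treated as a false-positive branch and skipped
  genome <- rand_seq(800)
  env <- o_kmer_env(unique(o_kmers(genome, k)))
  spur <- plant_spur(env, substr(genome, 400, 399 + k), 2)
  g2 <- dbg_from_kmers(c(unique(o_kmers(genome, k)), spur), k)
  expect_equal(extend_seq(g2, substr(genome, 300, 299 + 3 * k), "both"),
               genome)
})

test_that("SNP bubbles collapse to the lexicographically smaller arm and extension continues", {
  set.seed(503)
  k <- 15
  hap1 <- rand_seq(400)
  hap2 <- hap1
  substr(hap2, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                    substr(hap1, 200, 200))[1]
  g <- dbg_from_seq(c(hap1, hap2), k)
  fork <- substr(hap1, 200 - k, 199)  # node just before the variant
  cb <- collapse_bubble(g, fork, "right")
  expect_false(is.null(cb))
  expect_equal(cb$continuation, substr(hap1, 201, 200 + k))
  # extension passes through and emits one of the two haplotype bases
  ext <- extend_seq(g, substr(hap1, 50, 49 + 3 * k), "right")
  expect_gte(nchar(ext), 400 - 50)
  got_base <- substr(ext, 200 - 49, 200 - 49)
  expect_true(got_base %in% c(substr(hap1, 200, 200), substr(hap2, 200, 200)))
  expect_equal(got_base, min(substr(hap1, 200, 200), substr(hap2, 200, 200)))

  # a three-way fork is never collapsed
  hap3 <- hap1
  substr(hap3, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                    c(substr(hap1, 200, 200),
                                      substr(hap2, 200, 200)))[1]
  g3 <- dbg_from_seq(c(hap1, hap2, hap3), k)
  expect_null(collapse_bubble(g3, fork, "right"))

  # permanently diverging branches are not a bubble
  armA <- paste0(substr(hap1, 200 - k, 199), rand_seq(30))
  armB <- paste0(substr(hap1, 200 - k, 199), rand_seq(30))
  g4 <- dbg_from_seq(c(substr(hap1, 1, 199), armA, armB), k)
  expect_null(collapse_bubble(g4, fork, "right"))
})

test_that("unconnected-read correction walks k left then up to k+1 right", {
  set.seed(504)
  k <- 21
  genome <- rand_seq(1500)
  g <- dbg_from_seq(genome, k)
  # clean read mid-genome: the walk spells 2k+1 bases around the run end
  read <- substr(genome, 700, 799)
  cor <- correct_unconnected(g, read)
  run_end <- 799 - k + 1              # genome position of rightmost k-mer
  expect_equal(cor, substr(genome, run_end - k, run_end + k))
  expect_equal(nchar(cor), 2 * k + 1)

  # leftward walk must cover k full nodes: a dead end aborts correction
  near_start <- substr(genome, 1, 35)  # run ends < k nodes from the 5' end
  expect_null(correct_unconnected(g, near_start))

  # a fork 3 nodes into the rightward walk truncates but keeps the walk
  read2 <- substr(genome, 700, 779)
  run_end2 <- 779 - k + 1
  fork_at <- run_end2 - k + 3          # 4th node of the right walk
  fork_word <- substr(genome, fork_at, fork_at + k - 1)
  env <- o_kmer_env(unique(o_kmers(genome, k)))
  spur_head <- plant_spur(env, fork_word, 5)
  g2 <- dbg_from_kmers(c(unique(o_kmers(genome, k)), spur_head), k)
  cor2 <- correct_unconnected(g2, read2)
  expect_equal(cor2, substr(genome, run_end2 - k, fork_at + k - 1))
})

test_that("duplicate filter novelty follows the any-unseen-k-mer rule", {
  set.seed(505)
  d <- dup_filter(k = 21, bits = 2^20)
  s <- rand_seq(200)
  expect_true(is_novel(d, kmerize(s, 21)))     # fresh filter
  expect_false(is_novel(d, character(0)))      # nothing to assert novel
  register_seq(d, s)
  expect_false(is_novel(d, kmerize(s, 21)))
  expect_false(is_novel(d, kmerize(substr(s, 50, 150), 21)))  # substring
  other <- rand_seq(100)
  expect_true(is_novel(d, kmerize(other, 21)))
  # sharing all but one k-mer still counts as novel
  mixed <- c(kmerize(s, 21)[1:20], kmerize(other, 21)[1])
  expect_true(is_novel(d, mixed))
})

test_that("process_pair de-duplicates loci and keeps the v1 mode intact", {
  genome <- random_genome(4000, seed = 51)
  k <- 31
  g <- dbg_from_seq(genome, k)
  params <- connect_params(k = k)
  mk_pair <- function(start, frag) {
    list(r1 = substr(genome, start, start + 99),
         r2 = o_revcomp(substr(genome, start + frag - 100,
                               start + frag - 1)))
  }
  p1 <- mk_pair(1000, 400)
  p2 <- mk_pair(1050, 380)  # same locus
  d <- dup_filter(k, 2^20)
  out1 <- process_pair(g, d, p1$r1, p1$r2, params, extend = TRUE)
  out2 <- process_pair(g, d, p2$r1, p2$r2, params, extend = TRUE)
  expect_length(out1$reads, 1)
  expect_equal(out1$reads[[1]]$provenance, "connected_extended")
  expect_equal(out1$reads[[1]]$seq, genome)  # extended to both dead ends
  expect_length(out2$reads, 0)               # fully duplicate

  # v1 compatibility: one pseudo-read per connected pair, no dedup
  o1 <- process_pair(g, NULL, p1$r1, p1$r2, params, extend = FALSE)
  o2 <- process_pair(g, NULL, p2$r1, p2$r2, params, extend = FALSE)
  expect_equal(o1$reads[[1]]$provenance, "connected")
  expect_length(o2$reads, 1)
  expect_equal(nchar(o1$reads[[1]]$seq), 400)

  # unconnectable pair: corrected + extended reads, deduplicated
  far <- list(r1 = substr(genome, 1000, 1099),
              r2 = o_revcomp(substr(genome, 2500, 2599)))
  d2 <- dup_filter(k, 2^20)
  oo <- process_pair(g, d2, far$r1, far$r2, params, extend = TRUE)
  expect_equal(oo$status, "no_path")
  expect_gte(length(oo$reads), 1)
  expect_lte(length(oo$reads), 2)
  for (rec in oo$reads)
    expect_equal(rec$provenance, "unconnected_extended")
})

test_that("planted false branches never change emitted sequences", {
  genome <- random_genome(5000, seed = 52)
  k <- 31
  cfg <- sim_config(genome_len = 5000, err_rate = 0, coverage = 10,
                    seed = 52)
  sim <- simulate_pairs(genome, cfg)
  clean <- unique(o_kmers(genome, k))
  env <- o_kmer_env(clean)
  set.seed(520)
  hosts <- sample(length(clean) - k, ceiling(0.01 * length(clean)))
  spurs <- character(0)
  for (h in hosts) {
    s <- plant_spur(env, substr(genome, h, h + k - 1), sample(1:3, 1))
    if (!is.null(s)) spurs <- c(spurs, s)
  }
  params <- connect_params(k = k)
  run <- function(kmers) {
    g <- dbg_from_kmers(kmers, k)
    konnect(sim, params, graph = g, extend = TRUE, dup_bits = 2^22)
  }
  base <- run(clean)
  spiked <- run(c(clean, spurs))
  expect_identical(base$pseudo_reads$seq, spiked$pseudo_reads$seq)
})
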