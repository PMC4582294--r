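# Bidirectional BFS, path enumeration, consensus, pair connection.

test_that("a linear chain yields one common edge and the unique path", {
  set.seed(401)
  k <- 21
  genome <- rand_seq(k + 5)           # 6-node chain
  g <- dbg_from_seq(genome, k)
  start <- substr(genome, 1, k)
  goal <- substr(genome, 6, 5 + k)
  sg <- bidi_bfs(g, start, goal, depth_limit = 6, B = 100)
  expect_equal(sg$status, "success")
  expect_gte(sg$n_common, 1)
  en <- enumerate_paths(sg, max_paths = 4)
  expect_equal(en$status, "success")
  expect_length(en$paths, 1)
  expect_equal(path_to_seq(en$paths[[1]]), genome)

  # start == goal: degenerate success with the trivial one-node path
  sg2 <- bidi_bfs(g, start, start, depth_limit = 6, B = 100)
  expect_equal(sg2$status, "success")
  en2 <- enumerate_paths(sg2, max_paths = 4)
  expect_equal(path_to_seq(en2$paths[[1]]), start)

  # disjoint components cannot connect
  other <- rand_seq(k + 5)
  g2 <- dbg_from_seq(c(genome, other), k)
  sg3 <- bidi_bfs(g2, start, substr(other, 1, k), depth_limit = 20, B = 100)
  expect_equal(sg3$status, "no_path")
})

test_that("a SNP bubble gives exactly two paths differing at one base", {
  set.seed(402)
  k <- 15
  hap1 <- rand_seq(120)
  hap2 <- hap1
  substr(hap2, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                  substr(hap1, 60, 60))[1]
  g <- dbg_from_seq(c(hap1, hap2), k)
  start <- substr(hap1, 20, 19 + k)
  goal <- substr(hap1, 90, 89 + k)
  sg <- bidi_bfs(g, start, goal, depth_limit = 100, B = 100)
  en <- enumerate_paths(sg, max_paths = 4)
  expect_equal(en$status, "success")
  expect_length(en$paths, 2)
  seqs <- vapply(en$paths, path_to_seq, "")
  expect_equal(nchar(seqs[1]), nchar(seqs[2]))
  expect_equal(sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]]),
               1)
})

test_that("path count over parallel bubbles is combinatorial and P-capped", {
  set.seed(403)
  k <- 11
  hap1 <- rand_seq(260)
  hap2 <- hap1
  for (p in seq(40, 200, by = 40))  # 5 well-separated SNPs => 2^5 paths
    substr(hap2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(hap1, p, p))[1]
  g <- dbg_from_seq(c(hap1, hap2), k)
  start <- substr(hap1, 10, 9 + k)
  goal <- substr(hap1, 230, 229 + k)
  sg <- bidi_bfs(g, start, goal, depth_limit = 250, B = 1000)
  expect_equal(enumerate_paths(sg, max_paths = 4)$status, "too_many_paths")
  en <- enumerate_paths(sg, max_paths = 40)
  expect_equal(en$status, "success")
  expect_length(en$paths, 32)
})

test_that("paths agree with the exhaustive DFS oracle and the one-sided search", {
  set.seed(404)
  for (trial in 1:5) {
    k <- 21
    genome <- rand_seq(3000)
    env <- o_kmer_env(unique(o_kmers(genome, k)))
    g <- dbg_from_seq(genome, k)
    for (j in 1:8) {
      i1 <- sample(2500, 1)
      span <- sample(50:300, 1)
      start <- substr(genome, i1, i1 + k - 1)
      goal <- substr(genome, i1 + span, i1 + span + k - 1)
      dl <- span + 20
      oracle <- o_path_set(o_dfs_paths(env, start, goal, dl))
      bi <- enumerate_paths(bidi_bfs(g, start, goal, dl, B = 1e6), 1000)
      un <- enumerate_paths(bidi_bfs(g, start, goal, dl, B = 1e6,
                                     bidirectional = FALSE), 1000)
      got_bi <- o_path_set(bi$paths)
      got_un <- o_path_set(un$paths)
      expect_equal(got_bi, oracle)
      expect_equal(got_un, oracle)
    }
  }
})

test_that("path spelling overlaps nodes by k-1 bases", {
  expect_equal(path_to_seq(c("ACGT", "CGTA", "GTAC")), "ACGTAC")
  expect_equal(path_to_seq("ACGT"), "ACGT")
  expect_error(path_to_seq(c("ACGT", "GGGG")), "overlap")
})

test_that("consensus votes columns, enforces M and X, and is deterministic", {
  expect_equal(consensus_paths("ACGTA")$seq, "ACGTA")
  r <- consensus_paths(c("ACGTA", "ACCTA", "ACCTA"), M = 1, X = 0)
  expect_equal(r$status, "success")
  expect_equal(r$seq, "ACCTA")   # majority at the variant column
  expect_equal(r$max_mismatches, 1)

  # identity on a 100-column pair with 3 mismatches is 97% < X = 98
  set.seed(405)
  a <- rand_seq(100)
  b <- a
  for (p in c(10, 50, 90))
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  r2 <- consensus_paths(c(a, b), M = Inf, X = 98)
  expect_equal(r2$status, "paths_disagree")
  expect_equal(r2$min_identity, 97)
  expect_equal(consensus_paths(c(a, b), M = 2, X = 0)$status,
               "paths_disagree")
  expect_equal(consensus_paths(c(a, b), M = 3, X = 0)$status, "success")

  # unequal lengths go through the aligner; the majority wins
  r3 <- consensus_paths(c("ACGTTTACG", "ACGTTACG", "ACGTTTACG"),
                        M = Inf, X = 0)
  expect_equal(r3$seq, "ACGTTTACG")

  # column ties break to the lexicographically smallest base
  expect_equal(consensus_paths(c("AAGAA", "AATAA"), M = Inf, X = 0)$seq,
               "AAGAA")
})

test_that("connect_pair restores the exact fragment on clean data", {
  genome <- random_genome(20000, seed = 42)
  cfg <- sim_config(genome_len = 20000, err_rate = 0, coverage = 2,
                    seed = 42)
  sim <- simulate_pairs(genome, cfg)
  g <- dbg_from_seq(genome, 31)   # complete clean graph
  params <- connect_params(k = 31)
  truth <- true_fragments(genome, sim$truth)
  idx <- which(sim$truth$frag_len <= 525 & sim$truth$frag_len > 200)[1:50]
  for (i in idx) {
    res <- connect_pair(g, sim$read1[i], sim$read2[i], params)
    expect_equal(res$status, "success")
    expect_equal(res$pseudo, truth[i])
    # flank invariant: read termini survive verbatim at the ends
    expect_true(startsWith(res$pseudo, substr(sim$read1[i], 1, 10)))
    expect_true(endsWith(res$pseudo, substr(revcomp(sim$read2[i]), 91, 100)))
  }
  # a fragment longer than F cannot connect within the depth limit
  big <- which(sim$truth$frag_len > 525)
  if (length(big)) {
    res <- connect_pair(g, sim$read1[big[1]], sim$read2[big[1]], params)
    expect_equal(res$status, "no_path")
  }
})

test_that("a substitution near the gap-facing end is overridden by the graph path", {
  genome <- random_genome(10000, seed = 43)
  k <- 31
  g <- dbg_from_seq(genome, k)
  params <- connect_params(k = k)
  start <- 2001
  frag <- 400
  read1 <- substr(genome, start, start + 99)
  read2 <- o_revcomp(substr(genome, start + frag - 100, start + frag - 1))
  # error inside the last k bases of read 1: the 3'-most solid run then
  # precedes it, the anchor offset is 0, and the path re-derives the base
  mut <- read1
  substr(mut, 85, 85) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read1, 85, 85))[1]
  res <- connect_pair(g, mut, read2, params)
  expect_equal(res$status, "success")
  expect_equal(res$offset1, 0)
  expect_equal(res$pseudo, substr(genome, start, start + frag - 1))
})

test_that("search effort and results respond monotonically to B, F and P", {
  set.seed(406)
  k <- 15
  hap1 <- rand_seq(150)
  hap2 <- hap1
  substr(hap2, 70, 70) <- setdiff(c("A", "C", "G", "T"),
                                  substr(hap1, 70, 70))[1]
  g <- dbg_from_seq(c(hap1, hap2), k)
  start <- substr(hap1, 10, 9 + k)
  goal <- substr(hap1, 120, 119 + k)
  base <- o_path_set(enumerate_paths(
    bidi_bfs(g, start, goal, 130, B = 1000), 100)$paths)
  # raising B or the depth limit never removes a found path
  more_b <- o_path_set(enumerate_paths(
    bidi_bfs(g, start, goal, 130, B = 10000), 100)$paths)
  deeper <- o_path_set(enumerate_paths(
    bidi_bfs(g, start, goal, 160, B = 1000), 100)$paths)
  expect_true(all(base %in% more_b))
  expect_true(all(base %in% deeper))
  # lowering P converts success into too_many_paths, never a wrong set
  expect_equal(enumerate_paths(bidi_bfs(g, start, goal, 130, B = 1000),
                               1)$status, "too_many_paths")
  # starving B fails explicitly
  expect_equal(bidi_bfs(g, start, goal, 130, B = 0)$status,
               "too_many_branches")
})
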