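# Canonical k-mer primitives and the (cascading) Bloom filter.

test_that("canonicalization picks the lexicographic minimum of both strands", {
  expect_equal(canonical_kmer("AAAA"), "AAAA")
  expect_equal(canonical_kmer("TTTT"), "AAAA")
  expect_equal(canonical_kmer("ACGT"), "ACGT")  # palindrome
  expect_error(canonical_kmer("ACNT"), "non-ACGT")
  set.seed(101)
  w <- vapply(1:50, function(i) rand_seq(21), "")
  expect_equal(canonical_kmer(w), o_canonical(w))
  expect_equal(canonical_kmer(revcomp(w)), canonical_kmer(w))
})

test_that("kmerize emits one canonical k-mer per clean window", {
  expect_equal(kmerize("ACGTA", 4),
               canonical_kmer(c("ACGT", "CGTA")))
  expect_equal(kmerize("ACNGT", 3), character(0))  # every window hits N
  expect_equal(kmerize("ACGNACGT", 3),
               canonical_kmer(c("ACG", "ACG", "CGT")))  # split at the N
  expect_equal(kmerize("AAA", 4), character(0))    # too short
  set.seed(102)
  s <- rand_seq(200)
  expect_equal(sort(kmerize(s, 21)), sort(o_kmers(s, 21)))
})

test_that("Bloom filter has no false negatives and matches the FPR formula", {
  set.seed(103)
  f <- bloom_filter(m = 1e5, h = 3)
  keys <- unique(vapply(1:2000, function(i) rand_seq(21), ""))
  expect_false(any(bloom_contains(f, keys[1:50])))  # fresh: all bits zero
  bloom_insert(f, keys)
  expect_true(all(bloom_contains(f, keys)))         # never a false negative
  expect_equal(bloom_info(f)$n_inserted, length(keys))

  # measured FPR vs (1 - e^(-hn/m))^h on the spec'd setting
  f2 <- bloom_filter(m = 1000, h = 2)
  ins <- unique(vapply(1:150, function(i) rand_seq(21), ""))[1:100]
  bloom_insert(f2, ins)
  probes <- setdiff(unique(vapply(1:12000, function(i) rand_seq(21), "")),
                    ins)[1:10000]
  fpr <- mean(bloom_contains(f2, probes))
  p <- expected_fpr(1000, 2, 100)
  expect_equal(p, 0.0329, tolerance = 0.01)
  sd3 <- 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(fpr - p), sd3)
})

test_that("cascade promotes k-mers seen twice into level 2", {
  set.seed(104)
  cf <- cascading_bloom(k = 21, bits = 2^21)
  singles <- unique(vapply(1:1200, function(i) rand_seq(21), ""))[1:1000]
  doubles <- unique(vapply(1:80, function(i) rand_seq(21), ""))
  doubles <- setdiff(doubles, singles)[1:50]
  cascade_insert(cf, singles)
  cascade_insert(cf, doubles)
  cascade_insert(cf, doubles)  # second sighting
  # level-2 membership is exactly the doubleton set (filter sized so
  # level-1 collisions are vanishingly rare)
  expect_true(all(cascade_contains(cf, doubles)))
  expect_false(any(cascade_contains(cf, singles)))
  # strand symmetry of membership
  expect_equal(cascade_contains(cf, revcomp(doubles)),
               cascade_contains(cf, doubles))
})

test_that("read loading puts every twice-seen k-mer of trimmed reads in level 2", {
  set.seed(105)
  genome <- rand_seq(1000)
  # 30 identical error-free passes over the genome in 100 bp tiles
  starts <- rep(seq(1, 901, by = 50), 30)
  reads <- substring(genome, starts, starts + 99)
  cf <- bloom_build(list(seq = reads, qual = NULL), k = 31)
  gk <- unique(o_kmers(genome, 31))
  expect_true(all(cascade_contains(cf, gk)))
  info <- cascade_info(cf)
  expect_true(info$level1_dropped)
  expect_error(cascade_insert(cf, gk[1]), "discarded")

  # 3' hard quality trim: bases from the first low-quality base on are
  # never k-merized
  r <- substr(genome, 1, 60)
  qual <- paste0(strrep("I", 40), strrep("#", 20))  # Phred 40 then Phred 2
  cf2 <- bloom_build(list(seq = c(r, r), qual = c(qual, qual)),
                     k = 31, q = 15)
  kept <- o_kmers(substr(r, 1, 40), 31)
  cut <- setdiff(o_kmers(r, 31), kept)
  expect_true(all(cascade_contains(cf2, kept)))
  expect_false(any(cascade_contains(cf2, cut)))
})

test_that("filter files round-trip bit-exactly and refuse corrupt input", {
  set.seed(106)
  reads <- vapply(1:40, function(i) rand_seq(80), "")
  cf <- bloom_build(list(seq = c(reads, reads), qual = NULL), k = 25)
  p1 <- tempfile(fileext = ".bloom")
  p2 <- tempfile(fileext = ".bloom")
  save_bloom(cf, p1)
  cf2 <- load_bloom(p1)
  save_bloom(cf2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))  # bitwise round trip
  km <- o_kmers(reads[1], 25)
  expect_equal(cascade_contains(cf2, km), cascade_contains(cf, km))
  expect_error(load_bloom(p1, k = 31), "k = 25")

  # two builds from the same reads give identical files
  cfb <- bloom_build(list(seq = c(reads, reads), qual = NULL), k = 25)
  p3 <- tempfile(fileext = ".bloom")
  save_bloom(cfb, p3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))

  # truncation is an error, not a silent misread
  raw <- readBin(p1, "raw", file.size(p1))
  pt <- tempfile(fileext = ".bloom")
  writeBin(raw[1:(length(raw) - 100)], pt)
  expect_error(load_bloom(pt), "truncated")
  pb <- tempfile(fileext = ".bloom")
  writeBin(c(charToRaw("NOTBLOOM"), raw[-(1:8)]), pb)
  expect_error(load_bloom(pb), "magic")
})
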