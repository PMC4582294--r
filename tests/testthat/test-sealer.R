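# Gap finding, the k sweep, and scaffold patching.

test_that("find_gaps reports maximal N-runs with half-open coordinates and clean flanks", {
  g <- find_gaps(c(sc = "ACGTNNNNACGT"), flank = 100)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(4, 8))
  expect_equal(g$flank5, "ACGT")
  expect_equal(g$flank3, "ACGT")

  expect_equal(nrow(find_gaps(c(sc = "ACGTACGT"))), 0)

  lead <- find_gaps(c(sc = "NNACGT"))
  expect_equal(c(lead$start, lead$end), c(0, 2))
  expect_equal(lead$flank5, "")     # unflankable on the 5' side
  expect_equal(lead$flank3, "ACGT")

  # flanks are trimmed back at a neighbouring gap
  two <- find_gaps(c(sc = "AAAANNCCCCCNNGGGG"), flank = 100)
  expect_equal(two$flank3[1], "CCCCC")
  expect_equal(two$flank5[2], "CCCCC")
})

test_that("masked windows round-trip through find_gaps", {
  genome <- random_genome(10000, seed = 61)
  mw <- mask_windows(genome, 3, c(50, 120), seed = 2, min_dist = 150)
  g <- find_gaps(c(sc = mw$scaffold), flank = 100)
  expect_equal(g$start, mw$windows$start)
  expect_equal(g$end, mw$windows$end)
  # restoring the truth reproduces the genome
  s <- mw$scaffold
  for (i in rev(seq_len(nrow(mw$windows))))
    substr(s, mw$windows$start[i] + 1, mw$windows$end[i]) <-
      mw$windows$truth[i]
  expect_equal(s, genome)
})

test_that("the k sweep closes gaps exactly and falls through to smaller k", {
  genome <- random_genome(12000, seed = 62)
  mw <- mask_windows(genome, 3, c(60, 200), seed = 4, min_dist = 200)
  sim <- simulate_pairs(genome, sim_config(genome_len = 12000, err_rate = 0,
                                           seed = 6))
  res <- seal(c(chr = mw$scaffold),
              list(seq = c(sim$read1, sim$read2), qual = NULL),
              ks = c(50, 40),
              params = connect_params(k = 50, B = 1000, F = 700, P = 10))
  expect_equal(res$report$closed, 3)
  expect_equal(res$report$percent, 100)
  expect_equal(res$scaffolds[["chr"]], genome)  # exact restoration

  # a flank shorter than the larger k is skipped, then closed at k = 40:
  # shrink the 5' flank by masking right up to 45 bases before the gap
  sc2 <- mw$scaffold
  substr(sc2, mw$windows$start[2] - 45, mw$windows$start[2] - 45) <- "N"
  res2 <- seal(c(chr = sc2),
               list(seq = c(sim$read1, sim$read2), qual = NULL),
               ks = c(50, 40),
               params = connect_params(k = 50, B = 1000, F = 700, P = 10))
  row <- which(res2$gaps$start == mw$windows$start[2])
  expect_equal(res2$gaps$k[row], 40)
  expect_equal(res2$gaps$status[row], "closed")
})

test_that("patching replaces only closed spans and reports the closure rate", {
  genome <- random_genome(8000, seed = 63)
  mw <- mask_windows(genome, 2, c(50, 80), seed = 5, min_dist = 150)
  gaps <- find_gaps(c(chr = mw$scaffold), flank = 100)
  gaps$k <- 21L
  # close only the first gap, with the exact truth spanning both flanks
  gaps$seq <- NA_character_
  gaps$seq[1] <- paste0(gaps$flank5[1], mw$windows$truth[1], gaps$flank3[1])
  pat <- patch_scaffolds(c(chr = mw$scaffold), gaps)
  expect_equal(pat$report$total, 2)
  expect_equal(pat$report$closed, 1)
  expect_equal(pat$report$percent, 50)
  out <- pat$scaffolds[["chr"]]
  # first window restored, second untouched, nothing else moved
  expect_equal(substr(out, mw$windows$start[1] + 1, mw$windows$end[1]),
               mw$windows$truth[1])
  expect_equal(substr(out, mw$windows$start[2] + 1, mw$windows$end[2]),
               strrep("N", mw$windows$end[2] - mw$windows$start[2]))
  expect_equal(nchar(out), nchar(genome))
  keep <- substr(genome, 1, mw$windows$start[1] - 100)
  expect_true(startsWith(out, keep))

  # zero closures leave the input identical
  gaps$seq <- NA_character_
  expect_equal(patch_scaffolds(c(chr = mw$scaffold), gaps)$scaffolds[["chr"]],
               mw$scaffold)

  # a closure inconsistent with its flanks is rejected with a warning
  bad <- gaps
  bad$seq[1] <- paste0("TTTTTTTTTTTTTTTTTTTTTTTTT", mw$windows$truth[1],
                       bad$flank3[1])
  expect_warning(pb <- patch_scaffolds(c(chr = mw$scaffold), bad),
                 "inconsistent")
  expect_equal(pb$scaffolds[["chr"]], mw$scaffold)
})
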