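# Fast bulk generator of random k-mers (vectorized; rand_seq is per-string).
rand_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), n, k)
  unique(do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE)))
}

# Shared study-scale fixture: a 20 kb random genome sequenced at 50x with
# 100 bp reads and 400 +/- 50 bp inserts, once error-free and once at the
# 0.1% substitution rate, connected pair by pair at k = 31, F = 525.
# Built lazily once and reused by the acceptance checks.
study_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    genome <- random_genome(20000, seed = 20)
    params <- connect_params(k = 31, F = 525)
    run <- function(err, seed) {
      cfg <- sim_config(genome_len = 20000, err_rate = err, coverage = 50,
                        seed = seed)
      sim <- simulate_pairs(genome, cfg)
      cf <- bloom_build(list(seq = c(sim$read1, sim$read2), qual = NULL),
                        k = 31)
      g <- dbg_graph(cf)
      res <- vector("list", length(sim$id))
      for (i in seq_along(sim$id))
        res[[i]] <- connect_pair(g, sim$read1[i], sim$read2[i], params)
      list(sim = sim, graph = g, res = res,
           truth = true_fragments(genome, sim$truth),
           status = vapply(res, function(r) r$status, ""))
    }
    cache <<- list(genome = genome, params = params,
                   clean = run(0, 21), err = run(0.001, 22))
    cache
  }
})
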