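# Shared fixtures, built in code. The "small" dataset is large enough for a
# meaningful SOM (600 genes) but cheap; heavier default-size runs live only
# in the acceptance tests.

small_config <- function(seed = 42L, ...) {
  sim_config(n_genes = 600L, n_modules = 4L, module_size = 30L,
             n_housekeeping = 27L, seed = seed, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      truth <- generate_truth(cfg)
      sim <- simulate_counts(truth)
      keep <- filter_expressed_genes(sim$counts, sim$metadata)
      cts <- sim$counts[keep, , drop = FALSE]
      sf <- size_factors(cts)
      cache <<- list(cfg = cfg, truth = truth, counts = sim$counts,
                     metadata = sim$metadata, keep = keep, filtered = cts,
                     sf = sf, norm = normalized_log2(cts, sf),
                     annotations = truth_annotations(truth))
    }
    cache
  }
})

# toy 4-gene / 4-sample (2 conditions x 2 replicates) matrix with known
# per-condition means
toy_counts <- function() {
  m <- rbind(
    gA = c(6L, 6L, 6L, 6L),      # condition means (6, 6)
    gB = c(4L, 6L, 9L, 9L),      # (5, 9): boundary, mean exactly 5 in cond 1
    gC = c(0L, 0L, 100L, 100L),  # (0, 100)
    gD = c(10L, 10L, 10L, 10L)   # (10, 10)
  )
  colnames(m) <- c("AH1_1", "AH1_2", "AH2_1", "AH2_2")
  m
}

toy_metadata <- function() {
  data.frame(sample_id = c("AH1_1", "AH1_2", "AH2_1", "AH2_2"),
             substrate = "AH", growth_point = c(1L, 1L, 2L, 2L),
             replicate = c("1", "2", "1", "2"), stringsAsFactors = FALSE)
}
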