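test_that("cpm rescales columns to a million", {
  m <- matrix(c(250000L, 750000L, 5L, 15L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("big", "small")))
  x <- cpm(m)
  expect_equal(unname(x[, "big"]), c(250000, 750000))
  expect_equal(unname(x[, "small"]), c(250000, 750000))
  expect_equal(attr(x, "scale"), "cpm")

  m2 <- rbind(m, gz = c(0L, 0L))
  expect_equal(unname(cpm(m2)["gz", ]), c(0, 0))

  m3 <- cbind(m, dead = c(0L, 0L))
  expect_error(cpm(m3), "dead")

  d <- small_dataset()
  expect_equal(unname(colSums(cpm(d$filtered))), rep(1e6, 20), tolerance = 1e-9)
})

test_that("median-of-ratios size factors have the documented symmetries", {
  m <- matrix(as.integer(c(4, 10, 40, 8, 20, 80)), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1 / sqrt(2), s2 = sqrt(2)))

  ident <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  d <- small_dataset()
  sf <- size_factors(d$filtered)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  # scale equivariance: multiplying one sample by c multiplies its factor by
  # c, up to the global geometric-mean rescale (checked via factor ratios)
  scaled <- d$filtered
  scaled[, 3] <- scaled[, 3] * 5L
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[3] / sf[3]) / unname(sf2[1] / sf[1]), 5,
               tolerance = 1e-10)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "filter")
})

test_that("size factors match an independent median-of-ratios oracle", {
  set.seed(77)
  m <- matrix(rnbinom(200, mu = 50, size = 5), nrow = 50,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  storage.mode(m) <- "integer"
  # brute-force oracle, written independently of the implementation
  ref <- apply(m, 1L, function(r) all(r > 0))
  oracle <- sapply(seq_len(ncol(m)), function(s) {
    ratios <- sapply(which(ref), function(g) {
      m[g, s] / prod(m[g, ])^(1 / ncol(m))
    })
    median(ratios)
  })
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(size_factors(m)), oracle, tolerance = 1e-12)
})

test_that("size factors agree with DESeq2 up to geometric-mean rescaling", {
  skip_if_not_installed("DESeq2")
  set.seed(78)
  m <- matrix(rnbinom(400, mu = 80, size = 5), nrow = 100)
  dimnames(m) <- list(sprintf("g%d", 1:100), sprintf("s%d", 1:4))
  storage.mode(m) <- "integer"
  ds <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 takes the median of log-ratios; with an even reference count the
  # two central ratios are averaged geometrically there vs arithmetically
  # here, so agreement is near- but not bit-exact
  expect_equal(unname(size_factors(m)), unname(ds / exp(mean(log(ds)))),
               tolerance = 1e-4)
})

test_that("normalized log2 applies factors and pseudocount", {
  m <- matrix(c(0L, 7L, 15L, 1L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- c(s1 = 1, s2 = 2)
  x <- normalized_log2(m, f)
  expect_equal(x["g1", "s1"], 0)
  expect_equal(x["g2", "s1"], 3)
  expect_equal(x["g1", "s2"], log2(15 / 2 + 1))
  expect_equal(unname(normalized_log2(m, c(s1 = 1, s2 = 1))["g1", "s2"]), log2(16))
  expect_equal(attr(x, "scale"), "log2_normalized")
})

test_that("the mean-reads filter is strict and per-condition", {
  keep <- filter_expressed_genes(toy_counts(), toy_metadata())
  # gB: one condition mean exactly 5 -> dropped; gC: a zero condition -> dropped
  expect_equal(keep, c("gA", "gD"))
  expect_equal(filter_expressed_genes(toy_counts(), toy_metadata(),
                                      scope = "any"),
               c("gA", "gB", "gC", "gD"))
  # invariant to sample column order
  perm <- c(3, 1, 4, 2)
  expect_equal(filter_expressed_genes(toy_counts()[, perm],
                                      toy_metadata()[perm, ]),
               keep)
})

test_that("replicate Spearman correlation and clustering behave", {
  m <- cbind(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = c(9, 5, 1, 8))
  rownames(m) <- paste0("g", 1:4)
  qc <- replicate_spearman(m)
  expect_equal(qc$rho["a", "b"], 1)
  expect_equal(qc$rho["a", "c"], -1)

  m2 <- cbind(m, flat = rep(3, 4))
  expect_warning(qc2 <- replicate_spearman(m2), "constant")
  expect_true(anyNA(qc2$rho))
  expect_null(qc2$hclust)
})

test_that("replicate pairs cluster together on synthetic data", {
  d <- small_dataset()
  qc <- replicate_spearman(d$norm)
  # replicates of the same condition correlate above 0.95
  reps <- diag(qc$rho[seq(1, 19, 2), seq(2, 20, 2)])
  expect_gt(min(reps), 0.95)

  # count conditions whose two replicates merge as a singleton pair; the two
  # substrates share identical expectations at growth point 1 by
  # construction, so one or two cross-substrate early merges are expected
  hc <- qc$hclust
  lab <- hc$labels
  singleton_pairs <- apply(hc$merge, 1L, function(r) {
    if (all(r < 0)) sort(lab[-r]) else NULL
  })
  singleton_pairs <- Filter(Negate(is.null), singleton_pairs)
  conds <- unique(d$metadata$condition)
  good <- sum(vapply(conds, function(cc) {
    rr <- sort(d$metadata$sample_id[d$metadata$condition == cc])
    any(vapply(singleton_pairs, identical, logical(1), y = rr))
  }, logical(1)))
  expect_gte(good, 8L)
})

test_that("housekeeping consistency check flags unstable genes", {
  d <- small_dataset()
  hk <- housekeeping_check(d$norm, d$metadata, d$annotations)
  expect_equal(nrow(hk), 27L)
  expect_gte(sum(!hk$flagged), 25L)

  # a planted rising gene labelled housekeeping must be flagged
  rising <- d$truth$genes$gene_id[d$truth$genes$shape == "rising"][1L]
  fake <- rbind(d$annotations,
                data.frame(gene_id = rising, namespace = "housekeeping",
                           label = "chitin_synthase"))
  hk2 <- housekeeping_check(d$norm, d$metadata, fake)
  expect_true(hk2[rising, "flagged"])

  # zero-noise flat gene has zero spread
  m <- matrix(4, nrow = 1, ncol = 4,
              dimnames = list("flat", toy_metadata()$sample_id))
  ann <- data.frame(gene_id = "flat", namespace = "housekeeping", label = "x")
  hk3 <- housekeeping_check(m, toy_metadata(), ann)
  expect_equal(hk3$spread, 0)
  expect_false(hk3$flagged)

  expect_warning(out <- housekeeping_check(m, toy_metadata(),
                                           ann[0, , drop = FALSE]),
                 "housekeeping")
  expect_equal(nrow(out), 0L)
})
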