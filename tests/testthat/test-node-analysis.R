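make_tiny_fit <- function() {
  # 2x2 grid, hand-made assignment over 4 genes and 2 conditions x 2 reps
  norm <- rbind(g1 = c(4, 4, 6.5, 6.5),
                g2 = c(2, 2, 2, 2),
                g3 = c(10, 11, 10, 11),
                g4 = c(1, 1, 5, 5))
  colnames(norm) <- c("AH1_1", "AH1_2", "AH4_1", "AH4_2")
  md <- data.frame(sample_id = colnames(norm), substrate = "AH",
                   growth_point = c(1L, 1L, 4L, 4L),
                   replicate = c("1", "2", "1", "2"))
  assignment <- c(g1 = 1L, g2 = 2L, g3 = 3L, g4 = 3L)
  list(norm = norm, md = md, assignment = assignment, grid = som_grid(2, 2))
}

test_that("node condition means average member genes and replicates", {
  tf <- make_tiny_fit()
  prof <- node_condition_means(tf$assignment, tf$norm, tf$md, grid = tf$grid)
  expect_equal(prof$means["1", "AH_GP1"], 4)
  expect_equal(prof$means["1", "AH_GP4"], 6.5)
  expect_equal(prof$fold["1", "AH_GP4"], 2.5)
  # node 3 averages both members and both replicates
  expect_equal(prof$means["3", "AH_GP1"], mean(c(10, 11, 1, 1)))
  expect_equal(prof$means["3", "AH_GP4"], mean(c(10, 11, 5, 5)))
  # node 4 is empty: undefined profile, zero members
  expect_true(is.nan(prof$means["4", "AH_GP1"]))
  expect_equal(prof$n_members[4], 0L)

  # brute-force oracle on a random instance
  set.seed(61)
  norm <- matrix(rnorm(30 * 4, mean = 5), nrow = 30,
                 dimnames = list(sprintf("g%d", 1:30), tf$md$sample_id))
  assign2 <- setNames(sample(1:4, 30, replace = TRUE), rownames(norm))
  prof2 <- node_condition_means(assign2, norm, tf$md, grid = tf$grid)
  for (nd in 1:4) {
    for (cc in unique(tf$md$condition)) {
      g <- names(assign2)[assign2 == nd]
      cols <- tf$md$sample_id[tf$md$condition == cc]
      expect_equal(prof2$means[as.character(nd), cc],
                   mean(norm[g, cols]))
    }
  }
})

test_that("the expression threshold is a linear-interpolation percentile", {
  m <- matrix(1:100, nrow = 10)
  expect_equal(expression_threshold(m, 95), 95.05)
  expect_equal(expression_threshold(matrix(7, 3, 3)), 7)
  expect_equal(expression_threshold(m, 95, override = 10.2), 10.2)
})

test_that("condition-specific node calls follow the two strict criteria", {
  tf <- make_tiny_fit()
  prof <- node_condition_means(tf$assignment, tf$norm, tf$md, grid = tf$grid)
  calls <- call_specific_nodes(prof, threshold = 5)
  # node 3 mean 5.75 > 5 at GP1 -> mean criterion flags it
  expect_true(calls["3", "AH_GP1"])
  # node 1 fold 2.5 > 2 at GP4 -> fold criterion flags it despite low mean
  expect_true(calls["1", "AH_GP4"])
  expect_false(calls["1", "AH_GP1"])   # GP1: mean criterion only
  # node 3 fold is exactly 2: fold criterion alone never fires (strict)
  expect_false(call_specific_nodes(prof, threshold = 10.2)["3", "AH_GP4"])
  # empty node never called
  expect_false(any(calls["4", ]))

  # boundary: mean exactly at the threshold is not called
  prof_b <- prof
  prof_b$means["2", ] <- 10.2
  calls_b <- call_specific_nodes(prof_b, threshold = 10.2)
  expect_false(any(calls_b["2", ]))

  # combine = "all" requires both criteria away from the reference
  calls_all <- call_specific_nodes(prof, threshold = 5, combine = "all")
  expect_true(calls_all["1", "AH_GP4"])   # mean 6.5 > 5 and fold 2.5 > 2
  expect_false(calls_all["3", "AH_GP4"])  # fold exactly 2 fails under "all"
  expect_true(calls_all["3", "AH_GP1"])   # reference: mean-only in both modes
  # "any" calls are a superset of "all" calls
  expect_true(all(!calls_all | calls))
  calls_all_hi <- call_specific_nodes(prof, threshold = 10.2, combine = "all")
  expect_false(calls_all_hi["1", "AH_GP4"])
})

test_that("node calls are invariant to gene order within nodes", {
  tf <- make_tiny_fit()
  prof1 <- node_condition_means(tf$assignment, tf$norm, tf$md, grid = tf$grid)
  perm <- c(4, 2, 1, 3)
  prof2 <- node_condition_means(tf$assignment[perm], tf$norm[perm, ], tf$md,
                                grid = tf$grid)
  expect_equal(prof1$means, prof2$means)
  c1 <- call_specific_nodes(prof1, 5); c2 <- call_specific_nodes(prof2, 5)
  expect_equal(unclass(c1), unclass(c2), ignore_attr = TRUE)
})

test_that("high-expression selection uses the strict 2.5x-median rule", {
  cpm_mat <- matrix(c(1, 10, 10, 10, 100), ncol = 1,
                    dimnames = list(sprintf("g%d", 1:5), "AH1_1"))
  cpm_mat <- cbind(cpm_mat, AH1_2 = cpm_mat[, 1])
  md <- data.frame(sample_id = c("AH1_1", "AH1_2"), substrate = "AH",
                   growth_point = 1L, replicate = c("1", "2"))
  he <- high_expression_genes(cpm_mat, md)
  # median 10, threshold 25: only the CPM-100 gene passes
  expect_equal(he$per_condition[["AH_GP1"]], "g5")
  expect_equal(unname(he$medians["AH_GP1"]), 10)

  # boundary: exactly 2.5x the median fails
  cpm_b <- cpm_mat; cpm_b["g5", ] <- 25
  expect_equal(length(high_expression_genes(cpm_b, md)$per_condition[["AH_GP1"]]), 0L)
  cpm_c <- cpm_mat; cpm_c["g5", ] <- 26
  expect_equal(high_expression_genes(cpm_c, md)$per_condition[["AH_GP1"]], "g5")

  # scoping changes the median population
  he_scoped <- high_expression_genes(cpm_mat, md, genes = c("g1", "g5"))
  expect_equal(unname(he_scoped$medians["AH_GP1"]), 50.5)
  expect_error(high_expression_genes(cpm_mat, md, genes = "gX"), "scope")
})

test_that("annotation overlay counts labels per node", {
  assignment <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L)
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g4"),
                    namespace = c("CAZy", "CAZy", "CAZy", "P450_clan", "CAZy"),
                    label = c("AA9", "AA9", "GH5", "CYP52", "AA2"))
  out <- annotate_nodes(assignment, ann)
  expect_equal(out$n[out$node_id == 1 & out$label == "AA9"], 2L)
  expect_equal(out$n[out$node_id == 1 & out$label == "GH5"], 1L)
  expect_setequal(out$label[out$node_id == 2], c("CYP52", "AA2"))

  # unannotated genes are counted under "unannotated"
  out2 <- annotate_nodes(c(g1 = 1L, gX = 2L), ann)
  expect_equal(out2$label[out2$node_id == 2], "unannotated")

  expect_equal(nodes_with_labels(out, c("AA9", "GH5")), 1L)
  expect_equal(nodes_with_labels(out, c("AA9", "CYP52")), integer(0))
})

test_that("module annotations are enriched in the module's called nodes", {
  d <- small_dataset()
  fit <- som_fit(d$norm, rows = 8, cols = 6, epochs = 48000, seed = 7)
  prof <- node_condition_means(fit, d$norm, d$metadata)
  thr <- expression_threshold(d$norm, 95)
  calls <- call_specific_nodes(prof, thr)
  node_ann <- annotate_nodes(fit, d$annotations)

  # the rising module (labelled AA2 by truth_annotations) peaks at GP5
  rising_mod <- names(d$truth$module_shapes)[d$truth$module_shapes == "rising"]
  lab <- "AA2"
  called <- which(calls[, "AH_GP5"])
  aa2_nodes <- unique(node_ann$node_id[node_ann$label == lab])
  aa2_genes <- intersect(d$truth$genes$gene_id[d$truth$genes$class == rising_mod],
                         rownames(d$norm))
  in_called <- sum(fit$assignment[aa2_genes] %in% called)
  # hypergeometric enrichment of AA2 genes in called nodes vs background
  bg_genes <- rownames(d$norm)
  n_called_genes <- sum(fit$assignment %in% called)
  p <- phyper(in_called - 1, n_called_genes,
              length(bg_genes) - n_called_genes, length(aa2_genes),
              lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("tatami rendering writes one panel per condition", {
  tf <- make_tiny_fit()
  prof <- node_condition_means(tf$assignment, tf$norm, tf$md, grid = tf$grid)
  calls <- call_specific_nodes(prof, threshold = 10.2)
  dir <- withr::local_tempdir()
  files <- render_tatami(prof, calls, dir, format = "pdf")
  expect_length(files, 2L)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))

  f2 <- render_tatami(prof, NULL, file.path(dir, "map_%s.pdf"), format = "pdf")
  expect_true(file.exists(file.path(dir, "map_AH_GP1.pdf")))
})
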