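#' Configuration for the synthetic time-course simulator
#'
#' Describes a two-substrate, five-growth-point, two-replicate negative-
#' binomial count experiment with planted co-expressed gene modules. The
#' defaults emulate the design the package targets: 10 conditions
#' (aspen `AH` / spruce `WH` x growth points 1-5), 2 sequencing replicates
#' per condition, 27 flat housekeeping genes, and module effect amplitudes of
#' 3 log2 units.
#'
#' The negative binomial is parameterised by mean and dispersion `alpha`
#' (variance = mu + alpha * mu^2). Replicate-to-replicate variability is
#' log-normal on the mean, `replicate_sd` log2 units; the default 0.1 keeps
#' replicate Spearman correlations above 0.95, matching the tight replicate
#' clustering that well-behaved sequencing runs show.
#'
#' @param n_genes Total genes simulated.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module.
#' @param substrates Substrate labels (first label carries the "rising" arm of
#'   substrate-divergent modules).
#' @param growth_points Ordered growth-point labels; at least 2.
#' @param n_replicates Replicates per condition.
#' @param baseline_log2_mean_range Range of per-gene baseline log2 expected
#'   counts at nominal library size.
#' @param dispersion NB dispersion alpha (> 0).
#' @param library_size_range Range library sizes are drawn from (uniform,
#'   then fixed); expressed counts scale by library size / nominal (the range
#'   midpoint).
#' @param effect_log2fc Amplitude of temporal/substrate effects (log2 units).
#' @param n_housekeeping Number of flat housekeeping genes.
#' @param replicate_sd Log-normal replicate noise, sd in log2 units.
#' @param seed Integer seed; same config + seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_modules = 4L, module_size = 50L,
                       substrates = c("AH", "WH"), growth_points = 1:5,
                       n_replicates = 2L,
                       baseline_log2_mean_range = c(3, 10),
                       dispersion = 0.03,
                       library_size_range = c(8e5, 1.2e6),
                       effect_log2fc = 3,
                       n_housekeeping = 27L,
                       replicate_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    substrates = as.character(substrates),
    growth_points = as.integer(growth_points),
    n_replicates = as.integer(n_replicates),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    dispersion = as.numeric(dispersion),
    library_size_range = as.numeric(library_size_range),
    effect_log2fc = as.numeric(effect_log2fc),
    n_housekeeping = as.integer(n_housekeeping),
    replicate_sd = as.numeric(replicate_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid sim_config: '%s' %s", field, why))
  }
  chk(cfg$n_genes >= 1L, "n_genes", "must be a positive integer")
  chk(cfg$n_modules >= 0L, "n_modules", "must be non-negative")
  chk(cfg$module_size >= 1L, "module_size", "must be positive")
  chk(cfg$n_housekeeping >= 0L, "n_housekeeping", "must be non-negative")
  chk(cfg$n_modules * cfg$module_size + cfg$n_housekeeping <= cfg$n_genes,
      "module_size", "module and housekeeping genes exceed n_genes")
  chk(cfg$dispersion > 0, "dispersion", "must be > 0")
  chk(length(cfg$growth_points) >= 2L, "growth_points", "needs >= 2 levels")
  chk(length(cfg$substrates) >= 1L, "substrates", "needs >= 1 label")
  chk(cfg$n_replicates >= 1L, "n_replicates", "must be positive")
  chk(length(cfg$library_size_range) == 2L &&
        cfg$library_size_range[1] <= cfg$library_size_range[2] &&
        cfg$library_size_range[1] > 0,
      "library_size_range", "must be an increasing positive pair")
  chk(length(cfg$baseline_log2_mean_range) == 2L &&
        cfg$baseline_log2_mean_range[1] <= cfg$baseline_log2_mean_range[2],
      "baseline_log2_mean_range", "must be an increasing pair")
  chk(cfg$effect_log2fc > 0, "effect_log2fc", "must be positive")
  chk(cfg$replicate_sd >= 0, "replicate_sd", "must be non-negative")
  cfg
}

# Temporal offset (log2 units) of a module shape at growth-point fraction
# frac in [0,1], per substrate arm (1 = first substrate).
shape_offset <- function(shape, frac, arm, effect) {
  switch(shape,
    flat = 0,
    rising = effect * frac,
    falling = -effect * frac,
    substrate_divergent = if (arm == 1L) effect * frac else -effect * frac,
    late_burst = if (frac >= 1) effect else 0,
    stop("unknown module shape: ", shape)
  )
}

module_shape_cycle <- c("rising", "falling", "substrate_divergent",
                        "late_burst", "flat")

#' Plant ground-truth module structure
#'
#' Assigns every gene to a planted module, the housekeeping set, or flat
#' background, and lays down the true per-condition mean log2 expression.
#' Module shapes cycle through rising, falling, substrate-divergent and
#' late-burst (then flat): "rising" increases monotonically by
#' `effect_log2fc` from the first to the last growth point on both
#' substrates; "substrate_divergent" rises on the first substrate and falls
#' on the second; "late_burst" is flat until the final growth point.
#' Housekeeping genes have identical true means across all conditions.
#'
#' Module baselines are drawn from the upper part of
#' `baseline_log2_mean_range` so that planted genes (including falling ones)
#' stay above typical expression filters; background and housekeeping
#' baselines span the range.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `genes` (data.frame:
#'   `gene_id`, `class` = module id / "housekeeping" / "background",
#'   `shape`), `mu_log2` (genes x conditions matrix of true mean log2
#'   expected counts at nominal library size), `conditions` (data.frame),
#'   `module_shapes` (named character), and the generating `config`.
#' @export
generate_truth <- function(config) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  n_mod_genes <- cfg$n_modules * cfg$module_size
  gene_id <- sprintf("g%05d", seq_len(n))

  cls <- rep("background", n)
  if (cfg$n_modules > 0L) {
    cls[seq_len(n_mod_genes)] <- rep(sprintf("module%02d", seq_len(cfg$n_modules)),
                                     each = cfg$module_size)
  }
  if (cfg$n_housekeeping > 0L) {
    cls[n_mod_genes + seq_len(cfg$n_housekeeping)] <- "housekeeping"
  }

  shapes <- rep_len(module_shape_cycle, max(cfg$n_modules, 1L))[seq_len(cfg$n_modules)]
  names(shapes) <- sprintf("module%02d", seq_len(cfg$n_modules))

  lo <- cfg$baseline_log2_mean_range[1]
  hi <- cfg$baseline_log2_mean_range[2]
  # upper band keeps falling modules expressed and rising ones off the ceiling
  mod_base <- stats::runif(cfg$n_modules,
                           min = lo + 0.6 * (hi - lo),
                           max = lo + 0.85 * (hi - lo))
  hk_base <- stats::runif(cfg$n_housekeeping,
                          min = lo + 0.25 * (hi - lo),
                          max = lo + 0.75 * (hi - lo))
  bg_base <- stats::runif(sum(cls == "background"), min = lo, max = hi)

  G <- length(cfg$growth_points)
  conditions <- expand.grid(growth_point = cfg$growth_points,
                            substrate = cfg$substrates,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)[, c("substrate", "growth_point")]
  conditions$condition <- condition_label(conditions$substrate, conditions$growth_point)

  mu_log2 <- matrix(0, nrow = n, ncol = nrow(conditions),
                    dimnames = list(gene_id, conditions$condition))
  gene_shape <- rep("flat", n)
  for (ci in seq_len(nrow(conditions))) {
    arm <- match(conditions$substrate[ci], cfg$substrates)
    frac <- (match(conditions$growth_point[ci], cfg$growth_points) - 1) / (G - 1)
    col <- numeric(n)
    col[cls == "background"] <- bg_base
    col[cls == "housekeeping"] <- hk_base
    for (m in seq_len(cfg$n_modules)) {
      mid <- names(shapes)[m]
      off <- shape_offset(shapes[[m]], frac, arm, cfg$effect_log2fc)
      col[cls == mid] <- mod_base[m] + off
    }
    mu_log2[, ci] <- col
  }
  gene_shape[cls %in% names(shapes)] <- shapes[cls[cls %in% names(shapes)]]

  structure(list(
    genes = data.frame(gene_id = gene_id, class = cls, shape = gene_shape,
                       stringsAsFactors = FALSE),
    mu_log2 = mu_log2,
    conditions = conditions,
    module_shapes = shapes,
    config = cfg
  ), class = "sim_truth")
}

#' Simulate a negative-binomial count matrix from planted truth
#'
#' Draws library sizes uniformly from `library_size_range` (then fixed),
#' then counts gene-major: for gene g and sample s,
#' `counts ~ NB(mean = lib_scale_s * 2^(mu_log2 + eps), size = 1/alpha)`
#' where `eps ~ N(0, replicate_sd)` in log2 units and `lib_scale_s` is the
#' sample's library size over the nominal (range midpoint). One RNG stream,
#' seeded from `config$seed`; draw order is library sizes, then replicate
#' noise, then counts, each gene-major — so output is reproducible
#' bit-for-bit.
#'
#' @param truth A [generate_truth()] result.
#' @param config The same [sim_config()] used for the truth.
#' @return list with `counts` (integer matrix, genes x samples; columns named
#'   `AH1_1 ... WH5_2` at defaults), `metadata` (sample data.frame) and
#'   `library_sizes`.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  cfg <- validate_config(config)
  if (!identical(dim(truth$mu_log2), c(cfg$n_genes, nrow(truth$conditions)))) {
    stop("truth is not consistent with config")
  }
  set.seed(cfg$seed)

  md <- expand.grid(replicate = seq_len(cfg$n_replicates),
                    growth_point = cfg$growth_points,
                    substrate = cfg$substrates,
                    KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)[, c("substrate", "growth_point", "replicate")]
  md$sample_id <- paste0(md$substrate, md$growth_point, "_", md$replicate)
  md$replicate <- as.character(md$replicate)
  md$condition <- condition_label(md$substrate, md$growth_point)
  md <- md[c("sample_id", "substrate", "growth_point", "replicate", "condition")]
  S <- nrow(md)
  n <- cfg$n_genes

  lib <- round(stats::runif(S, cfg$library_size_range[1], cfg$library_size_range[2]))
  names(lib) <- md$sample_id
  scale <- lib / mean(cfg$library_size_range)

  cond_idx <- match(md$condition, truth$conditions$condition)
  mu_base <- truth$mu_log2[, cond_idx, drop = FALSE]  # genes x samples, log2

  # gene-major draw order: fill by row
  eps <- matrix(stats::rnorm(n * S, sd = cfg$replicate_sd),
                nrow = n, ncol = S, byrow = TRUE)
  mu <- sweep(2^(mu_base + eps), 2L, scale, "*")
  counts <- matrix(stats::rnbinom(n * S, mu = as.vector(t(mu)),
                                  size = 1 / cfg$dispersion),
                   nrow = n, ncol = S, byrow = TRUE,
                   dimnames = list(rownames(truth$mu_log2), md$sample_id))
  storage.mode(counts) <- "integer"
  list(counts = counts, metadata = md, library_sizes = lib)
}

#' Mock annotation table matching a simulated truth
#'
#' Labels module genes with mock CAZy families (AA2, AA9, GH5, GH16, ...,
#' cycling) so annotation-overlay analyses have ground truth, and splits the
#' housekeeping set between chitin synthase and NADH dehydrogenase in the
#' 11:16 proportion of the canonical 27-gene housekeeping panel.
#'
#' @param truth A [generate_truth()] result.
#' @return Annotation data.frame (`gene_id`, `namespace`, `label`).
#' @export
truth_annotations <- function(truth) {
  fams <- c("AA2", "AA9", "GH5", "GH16", "AA5", "CE1", "GH7", "PL8")
  rows <- list()
  mods <- names(truth$module_shapes)
  for (m in seq_along(mods)) {
    g <- truth$genes$gene_id[truth$genes$class == mods[m]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, namespace = "CAZy",
      label = rep_len(fams, length(mods))[m], stringsAsFactors = FALSE)
  }
  hk <- truth$genes$gene_id[truth$genes$class == "housekeeping"]
  if (length(hk)) {
    n_chs <- round(length(hk) * 11 / 27)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = hk, namespace = "housekeeping",
      label = rep(c("chitin_synthase", "NADH_dehydrogenase"),
                  c(n_chs, length(hk) - n_chs)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), namespace = character(),
                      label = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to TSV files
#'
#' Writes `counts.tsv`, `metadata.tsv`, `truth.tsv` and `annotation.tsv`
#' into a directory, in the package's interchange dialect.
#'
#' @param truth A [generate_truth()] result.
#' @param sim A [simulate_counts()] result for that truth.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(truth$genes, file.path(dir, "truth.tsv"))
  write_annotations(truth_annotations(truth), file.path(dir, "annotation.tsv"))
  invisible(dir)
}
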