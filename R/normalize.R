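#' Counts-per-million conversion
#'
#' Scales each sample column to counts per million mapped reads:
#' `cpm(g, s) = counts(g, s) / library_size(s) * 1e6`, library size being the
#' column sum. Every column of the result sums to exactly 1e6 (up to
#' floating-point rounding).
#'
#' @param counts Integer count matrix (genes x samples).
#' @return Numeric matrix with attribute `scale = "cpm"`.
#' @export
cpm <- function(counts) {
  validate_counts(counts)
  lib <- colSums(counts)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  }
  out <- sweep(counts + 0, 2L, lib, "/") * 1e6
  attr(out, "scale") <- "cpm"
  out
}

#' Median-of-ratios size factors
#'
#' The classic size-factor estimator for sequencing depth: for each gene
#' expressed in every sample, compute the ratio of its count to its
#' geometric mean across samples; a sample's factor is the median of those
#' ratios. Factors are then rescaled to geometric mean 1, making them
#' scale-equivariant up to that global rescaling.
#'
#' @param counts Integer count matrix.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has nonzero counts in all samples; filter low-count genes first")
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  f <- apply(exp(sweep(lg, 1L, geo, "-")), 2L, stats::median)
  f <- f / exp(mean(log(f)))
  f
}

#' Log2 transform of size-factor-normalized counts
#'
#' `log2(counts / factor + pseudocount)`. The default pseudocount of 1 keeps
#' zero counts at exactly 0 on the log2 scale.
#'
#' @param counts Integer count matrix.
#' @param factors Size factors from [size_factors()] (or any positive
#'   per-sample scalars).
#' @param pseudocount Added before the log; default 1.
#' @return Numeric matrix with attribute `scale = "log2_normalized"`.
#' @export
normalized_log2 <- function(counts, factors = size_factors(counts),
                            pseudocount = 1) {
  validate_counts(counts)
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  factors <- factors[colnames(counts)]
  if (anyNA(factors) || any(factors <= 0)) stop("invalid size factors")
  out <- log2(sweep(counts + 0, 2L, factors, "/") + pseudocount)
  attr(out, "scale") <- "log2_normalized"
  out
}

#' Filter genes by mean raw reads per condition
#'
#' Keeps a gene when its mean raw count across the replicates of a condition
#' exceeds `threshold` (strict `>`). With `scope = "all"` (default) the rule
#' must hold in every condition; `scope = "any"` requires a single condition.
#' The strict-inequality, all-conditions default is the conservative reading
#' of "more than averaged five reads per condition".
#'
#' @param counts Integer count matrix.
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param threshold Mean-read threshold, default 5.
#' @param scope `"all"` or `"any"` conditions.
#' @return Character vector of kept gene IDs, in the input row order.
#' @export
filter_expressed_genes <- function(counts, metadata, threshold = 5,
                                   scope = c("all", "any")) {
  scope <- match.arg(scope)
  md <- validate_metadata(metadata, counts)
  conds <- unique(md$condition)
  pass <- sapply(conds, function(cc) {
    cols <- md$sample_id[md$condition == cc]
    rowMeans(counts[, cols, drop = FALSE]) > threshold
  })
  keep <- if (scope == "all") rowSums(pass) == length(conds) else rowSums(pass) > 0
  rownames(counts)[keep]
}

#' Spearman correlation and clustering of samples
#'
#' Computes the pairwise Spearman rank correlation between sample columns of
#' a normalized expression matrix (ties get average ranks) and clusters
#' samples by average-linkage hierarchical clustering on distance `1 - rho`.
#' On well-behaved data the two replicates of every condition are each
#' other's first merge; this is reported, not enforced. A constant column has
#' undefined rank correlation and yields `NA` entries (with a warning), in
#' which case no dendrogram is produced.
#'
#' @param norm Expression matrix (samples in columns), usually from
#'   [normalized_log2()].
#' @param linkage Hierarchical clustering linkage, default "average".
#' @return list with `rho` (correlation matrix) and `hclust` (an hclust
#'   object, or NULL when rho has missing values).
#' @export
replicate_spearman <- function(norm, linkage = "average") {
  if (ncol(norm) < 2L) stop("need at least 2 samples")
  rho <- suppressWarnings(stats::cor(norm, method = "spearman"))
  hc <- NULL
  if (anyNA(rho)) {
    warning("constant sample column(s): Spearman correlation undefined for some pairs")
  } else {
    hc <- stats::hclust(stats::as.dist(1 - rho), method = linkage)
  }
  list(rho = rho, hclust = hc)
}

#' Housekeeping-gene consistency check
#'
#' Housekeeping genes (chitin synthase, NADH dehydrogenase) are expected to
#' express stably across all conditions; a large spread signals inconsistent
#' growth or normalization trouble. For each gene annotated with namespace
#' `housekeeping`, reports the per-condition mean log2 expression and the
#' max - min spread, flagging genes whose spread exceeds `threshold`.
#'
#' @param norm Log2-normalized expression matrix.
#' @param metadata Sample metadata.
#' @param annotations Annotation data.frame; rows with
#'   `namespace == "housekeeping"` define the gene set.
#' @param threshold Spread flag threshold in log2 units, default 1.
#' @return data.frame with one row per housekeeping gene: per-condition mean
#'   columns, `spread`, and logical `flagged`. Empty (with a warning) when no
#'   housekeeping gene is annotated and present.
#' @export
housekeeping_check <- function(norm, metadata, annotations, threshold = 1) {
  md <- validate_metadata(metadata)
  md <- md[md$sample_id %in% colnames(norm), , drop = FALSE]
  hk <- unique(annotations$gene_id[annotations$namespace == "housekeeping"])
  hk <- intersect(rownames(norm), hk)
  conds <- unique(md$condition)
  if (!length(hk)) {
    warning("no annotated housekeeping gene found in the expression matrix")
    out <- as.data.frame(matrix(numeric(), 0, length(conds) + 2,
                                dimnames = list(NULL, c(conds, "spread", "flagged"))))
    out$flagged <- logical()
    return(out)
  }
  means <- sapply(conds, function(cc) {
    cols <- md$sample_id[md$condition == cc]
    rowMeans(norm[hk, cols, drop = FALSE])
  })
  means <- matrix(means, nrow = length(hk), dimnames = list(hk, conds))
  spread <- apply(means, 1L, max) - apply(means, 1L, min)
  out <- data.frame(means, spread = spread,
                    flagged = spread > threshold, check.names = FALSE)
  out
}
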