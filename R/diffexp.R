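#' Log2 fold differences of each growth point against the reference
#'
#' For every substrate and growth point `k > reference`, computes the
#' per-gene difference of mean log2 expression at GPk minus the mean at the
#' reference growth point, within the same substrate (contrasts never cross
#' substrates).
#'
#' @param norm Log2-normalized expression matrix.
#' @param metadata Sample metadata.
#' @param reference Reference growth point, default 1.
#' @return Numeric matrix genes x contrasts; contrast columns are named
#'   `<substrate>_GP<k>` and described by `attr(, "contrasts")`
#'   (data.frame of substrate, growth_point).
#' @export
log2_fold_vs_reference <- function(norm, metadata, reference = 1L) {
  md <- validate_metadata(metadata)
  md <- md[md$sample_id %in% colnames(norm), , drop = FALSE]
  contrasts <- unique(md[md$growth_point != reference,
                         c("substrate", "growth_point")])
  if (!nrow(contrasts)) stop("need at least 2 growth points for fold contrasts")
  contrasts <- contrasts[order(contrasts$substrate, contrasts$growth_point), ,
                         drop = FALSE]
  lfc <- sapply(seq_len(nrow(contrasts)), function(i) {
    sub <- contrasts$substrate[i]
    ref_cols <- md$sample_id[md$substrate == sub & md$growth_point == reference]
    if (!length(ref_cols)) {
      stop("reference growth point ", reference, " missing for substrate ", sub)
    }
    k_cols <- md$sample_id[md$substrate == sub &
                             md$growth_point == contrasts$growth_point[i]]
    rowMeans(norm[, k_cols, drop = FALSE]) - rowMeans(norm[, ref_cols, drop = FALSE])
  })
  lfc <- matrix(lfc, nrow = nrow(norm),
                dimnames = list(rownames(norm),
                                condition_label(contrasts$substrate,
                                                contrasts$growth_point)))
  rownames(contrasts) <- NULL
  attr(lfc, "contrasts") <- contrasts
  lfc
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' A deliberately simplified NB test: counts are scaled by size factors,
#' group means are estimated by the arithmetic mean of normalized counts,
#' and the per-gene dispersion alpha (variance = mu + alpha mu^2) is
#' estimated by the method of moments within groups. There is no
#' empirical-Bayes dispersion shrinkage, no fold-change shrinkage and no
#' independent filtering. With few replicates the per-gene moment estimate
#' is very noisy, so every gene's dispersion is floored at the median of the
#' positive per-gene estimates (genes with non-positive or undefined
#' estimates get exactly that median): a below-typical estimate on two
#' residual degrees of freedom carries no evidence and, if trusted, makes
#' the test anti-conservative. Estimates are additionally floored at 1e-8.
#' The Wald statistic is the difference of log means over its
#' delta-method standard error, referred to the standard normal (two-sided).
#' A gene with zero counts in both groups has p = 1 by convention.
#'
#' @param counts Integer count matrix.
#' @param factors Size factors (named, covering both groups).
#' @param group_a,group_b Character vectors of sample IDs.
#' @param pseudocount Added to normalized group means before taking logs
#'   (keeps zero-count groups finite); default 0.5.
#' @return data.frame with per-gene `lfc` (log2 of the moderated mean
#'   ratio B/A), `stat`, `pvalue`, and the dispersion estimate `alpha`.
#' @export
nb_wald_test <- function(counts, factors, group_a, group_b, pseudocount = 0.5) {
  validate_counts(counts)
  all_s <- c(group_a, group_b)
  if (length(all_s) < 2L) stop("need at least 2 samples in total")
  missing_s <- setdiff(all_s, colnames(counts))
  if (length(missing_s)) stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  if (anyNA(factors[all_s]) || any(factors[all_s] <= 0)) stop("invalid size factors")

  q <- sweep(counts[, all_s, drop = FALSE] + 0, 2L, factors[all_s], "/")
  qa <- q[, group_a, drop = FALSE]
  qb <- q[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  inv_sa <- mean(1 / factors[group_a]); inv_sb <- mean(1 / factors[group_b])

  # method-of-moments dispersion: Var(q_i) = mu/s_i + alpha mu^2, so the
  # within-group sample variance estimates mu*mean(1/s) + alpha*mu^2
  mom_alpha <- function(qg, mu, inv_s, n) {
    if (n < 2L) return(rep(NA_real_, length(mu)))
    v <- apply(qg, 1L, stats::var)
    (v - mu * inv_s) / mu^2
  }
  aa <- mom_alpha(qa, mu_a, inv_sa, na)
  ab <- mom_alpha(qb, mu_b, inv_sb, nb)
  w <- c(na - 1L, nb - 1L)
  alpha_hat <- if (all(w == 0L)) rep(NA_real_, nrow(q)) else
    (ifelse(is.na(aa), 0, aa) * w[1] + ifelse(is.na(ab), 0, ab) * w[2]) /
      (sum(w * c(na >= 2, nb >= 2)))
  bad <- !is.finite(alpha_hat) | alpha_hat <= 0
  fallback <- stats::median(alpha_hat[!bad])
  if (!is.finite(fallback)) fallback <- 1e-8
  alpha_hat[bad] <- fallback
  # with so few residual df, a below-typical per-gene estimate is noise:
  # floor every gene at the experiment-wide median dispersion
  alpha_hat <- pmax(alpha_hat, fallback, 1e-8)

  mu_a_m <- mu_a + pseudocount
  mu_b_m <- mu_b + pseudocount
  # Var(log mean) by the delta method, with the moderated mean in the
  # denominator so zero-count groups stay finite
  v_log_a <- (mu_a_m * inv_sa + alpha_hat * mu_a_m^2) / (na * mu_a_m^2)
  v_log_b <- (mu_b_m * inv_sb + alpha_hat * mu_b_m^2) / (nb * mu_b_m^2)
  stat <- (log(mu_b_m) - log(mu_a_m)) / sqrt(v_log_a + v_log_b)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  allzero <- mu_a == 0 & mu_b == 0
  pvalue[allzero] <- 1
  stat[allzero] <- 0
  data.frame(gene_id = rownames(counts),
             lfc = log2(mu_b_m / mu_a_m),
             stat = stat, pvalue = pvalue, alpha = alpha_hat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), with input validation:
#' p-values must lie in \[0, 1\].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Growth-point differential-expression table
#'
#' Runs, for every substrate and growth point k > 1, the NB Wald test of GPk
#' versus GP1 within that substrate, attaches the mean log2 fold difference
#' from the normalized matrix, and BH-adjusts p-values within each contrast.
#'
#' @param counts Integer count matrix (ideally already filtered with
#'   [filter_expressed_genes()]).
#' @param metadata Sample metadata.
#' @param factors Size factors; computed from `counts` when NULL.
#' @param reference Reference growth point, default 1.
#' @return data.frame: `gene_id`, `substrate`, `growth_point`, `lfc`,
#'   `pvalue`, `padj`.
#' @export
de_table <- function(counts, metadata, factors = NULL, reference = 1L) {
  md <- validate_metadata(metadata, counts)
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- normalized_log2(counts, factors)
  lfc <- log2_fold_vs_reference(norm, md, reference)
  contrasts <- attr(lfc, "contrasts")
  out <- lapply(seq_len(nrow(contrasts)), function(i) {
    sub <- contrasts$substrate[i]; gp <- contrasts$growth_point[i]
    ga <- md$sample_id[md$substrate == sub & md$growth_point == reference]
    gb <- md$sample_id[md$substrate == sub & md$growth_point == gp]
    w <- nb_wald_test(counts, factors, ga, gb)
    data.frame(gene_id = w$gene_id, substrate = sub, growth_point = gp,
               lfc = lfc[, i], pvalue = w$pvalue,
               padj = bh_adjust(w$pvalue),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select significant genes per contrast
#'
#' Strict `padj < alpha`, matching FDR-adjusted p < 0.05 selection; a gene
#' sitting exactly at `alpha` is excluded.
#'
#' @param table A [de_table()] result.
#' @param alpha FDR level, default 0.05.
#' @return Named list (one element per `<substrate>_GP<k>` contrast) of gene
#'   ID vectors.
#' @export
significant_genes <- function(table, alpha = 0.05) {
  key <- condition_label(table$substrate, table$growth_point)
  sel <- table$padj < alpha
  out <- split(table$gene_id[sel], key[sel])
  keys <- unique(key)
  out <- out[intersect(keys, names(out))]
  for (k in setdiff(keys, names(out))) out[[k]] <- character()
  out[keys]
}
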