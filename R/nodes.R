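#' Per-node, per-condition mean expression profiles
#'
#' For each SOM node, the mean log2 expression over all member-gene x
#' replicate values per condition, plus the node-level log2 fold difference
#' of each growth point against growth point 1 within each substrate.
#' Empty nodes get NaN profiles and are excluded from downstream calls.
#'
#' @param fit A fitted [som_fit()] object (or a named gene -> node
#'   assignment vector, in which case `grid` must be given).
#' @param norm Log2-normalized expression matrix covering the assigned
#'   genes.
#' @param metadata Sample metadata.
#' @param reference Reference growth point for fold differences, default 1.
#' @param grid A [som_grid()]; taken from `fit` when it is a `tatami_som`.
#' @return list of class `node_profiles`: `means` (nodes x conditions),
#'   `fold` (nodes x non-reference conditions), `n_members`, `conditions`,
#'   `grid`.
#' @export
node_condition_means <- function(fit, norm, metadata, reference = 1L,
                                 grid = NULL) {
  if (inherits(fit, "tatami_som")) {
    assignment <- fit$assignment
    grid <- fit$grid
  } else {
    assignment <- fit
    if (is.null(grid)) stop("grid must be supplied with a raw assignment vector")
    grid <- as_som_grid(grid)
  }
  md <- validate_metadata(metadata)
  md <- md[md$sample_id %in% colnames(norm), , drop = FALSE]
  genes <- intersect(rownames(norm), names(assignment))
  if (!length(genes)) stop("no assigned gene found in the expression matrix")
  n_nodes <- grid$rows * grid$cols
  nodef <- factor(assignment[genes], levels = seq_len(n_nodes))

  conds <- unique(md[c("substrate", "growth_point", "condition")])
  conds <- conds[order(match(conds$substrate, unique(md$substrate)),
                       conds$growth_point), , drop = FALSE]
  rownames(conds) <- NULL

  n_members <- as.integer(table(nodef))
  means <- sapply(conds$condition, function(cc) {
    cols <- md$sample_id[md$condition == cc]
    gene_sum <- rowSums(norm[genes, cols, drop = FALSE])
    node_sum <- as.numeric(tapply(gene_sum, nodef, sum, default = 0))
    node_sum / (n_members * length(cols))   # empty nodes: 0/0 = NaN
  })
  means <- matrix(means, nrow = n_nodes,
                  dimnames = list(seq_len(n_nodes), conds$condition))

  non_ref <- conds$growth_point != reference
  fold <- means[, non_ref, drop = FALSE]
  for (i in which(non_ref)) {
    ref_cond <- condition_label(conds$substrate[i], reference)
    if (!ref_cond %in% conds$condition) {
      stop("reference growth point missing for substrate ", conds$substrate[i])
    }
    fold[, conds$condition[i]] <- means[, conds$condition[i]] - means[, ref_cond]
  }

  structure(list(means = means, fold = fold, n_members = n_members,
                 conditions = conds, reference = reference, grid = grid),
            class = "node_profiles")
}

#' @export
print.node_profiles <- function(x, ...) {
  cat(sprintf("Node profiles: %d nodes (%d empty), %d conditions, reference GP%d\n",
              nrow(x$means), sum(x$n_members == 0L), ncol(x$means), x$reference))
  invisible(x)
}

#' Genome-wide expression percentile threshold
#'
#' The given percentile (linear-interpolation quantile) of all gene x sample
#' values of the expression matrix. Used as the "high transcription" cut for
#' node calling; an absolute override (e.g. the fixed 10.2 log2 cut) takes
#' precedence when supplied.
#'
#' @param norm Expression matrix.
#' @param percentile Percentile in (0, 100); default 95.
#' @param override Optional absolute threshold returned as-is.
#' @return A single number.
#' @export
expression_threshold <- function(norm, percentile = 95, override = NULL) {
  if (!is.null(override)) return(override)
  if (!length(norm)) stop("empty expression matrix")
  unname(stats::quantile(as.vector(norm), probs = percentile / 100, type = 7))
}

#' Call condition-specific nodes
#'
#' Flags a node for a (substrate, growth point) condition when its mean log2
#' expression exceeds `threshold` and/or its log2 fold difference against
#' growth point 1 exceeds `lfc_threshold` (both strict `>`). With
#' `combine = "any"` (default) either criterion suffices; with `"all"` both
#' are required. Reference-growth-point conditions have no fold difference
#' and can only satisfy the mean criterion. Empty nodes are never flagged.
#'
#' @param profiles A [node_condition_means()] result.
#' @param threshold High-expression cut on mean log2 values (e.g. from
#'   [expression_threshold()], or the fixed 10.2 override).
#' @param lfc_threshold Fold-difference cut, default 2 log2 units.
#' @param combine `"any"` or `"all"`.
#' @return Logical matrix nodes x conditions of class `node_calls`, with the
#'   thresholds in attributes.
#' @export
call_specific_nodes <- function(profiles, threshold, lfc_threshold = 2,
                                combine = c("any", "all")) {
  combine <- match.arg(combine)
  stopifnot(inherits(profiles, "node_profiles"))
  mean_pass <- profiles$means > threshold
  lfc_pass <- matrix(FALSE, nrow(profiles$means), ncol(profiles$means),
                     dimnames = dimnames(profiles$means))
  lfc_pass[, colnames(profiles$fold)] <- profiles$fold > lfc_threshold
  is_ref <- profiles$conditions$growth_point == profiles$reference
  calls <- if (combine == "any") mean_pass | lfc_pass else mean_pass & lfc_pass
  # the reference growth point has no fold contrast: mean criterion only
  calls[, is_ref] <- mean_pass[, is_ref]
  calls[profiles$n_members == 0L, ] <- FALSE
  calls[is.na(calls)] <- FALSE
  structure(calls, class = c("node_calls", class(calls)),
            threshold = threshold, lfc_threshold = lfc_threshold,
            combine = combine)
}

#' High-expression genes relative to the growth-point median
#'
#' For each (substrate, growth point), averages the replicates of each gene
#' on the CPM scale and flags genes whose mean exceeds `factor` times the
#' median CPM of all scoped genes at that growth point (strict `>`; the
#' median is the linear-interpolation 50% quantile over the scoped set). The
#' scope defaults to every gene in the matrix but can be restricted, e.g. to
#' CAZy- or P450-annotated genes, which changes the median population.
#'
#' @param cpm_mat CPM-scale expression matrix (see [cpm()]).
#' @param metadata Sample metadata.
#' @param factor Multiple of the median, default 2.5.
#' @param genes Optional character vector restricting the scope.
#' @return list with `per_condition` (named list of gene ID vectors, one per
#'   `<substrate>_GP<k>`), `union`, and `medians` (named numeric).
#' @export
high_expression_genes <- function(cpm_mat, metadata, factor = 2.5,
                                  genes = NULL) {
  md <- validate_metadata(metadata)
  md <- md[md$sample_id %in% colnames(cpm_mat), , drop = FALSE]
  if (is.null(genes)) genes <- rownames(cpm_mat)
  genes <- intersect(rownames(cpm_mat), genes)
  if (!length(genes)) stop("empty gene scope after annotation join")
  conds <- unique(md$condition)
  medians <- numeric(0)
  per_condition <- lapply(conds, function(cc) {
    cols <- md$sample_id[md$condition == cc]
    m <- rowMeans(cpm_mat[genes, cols, drop = FALSE])
    med <- unname(stats::quantile(m, probs = 0.5, type = 7))
    medians[[cc]] <<- med
    genes[m > factor * med]
  })
  names(per_condition) <- conds
  list(per_condition = per_condition,
       union = unique(unlist(per_condition, use.names = FALSE)),
       medians = medians)
}

#' Annotation label counts per node
#'
#' Overlays an annotation table on a node assignment: for every node, counts
#' member genes per (namespace, label); genes without any annotation are
#' counted under namespace/label `unannotated`.
#'
#' @param fit A fitted [som_fit()] object or named gene -> node vector.
#' @param annotations Annotation data.frame.
#' @return data.frame: `node_id`, `namespace`, `label`, `n`.
#' @export
annotate_nodes <- function(fit, annotations) {
  assignment <- if (inherits(fit, "tatami_som")) fit$assignment else fit
  genes <- names(assignment)
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  un <- setdiff(genes, ann$gene_id)
  if (length(un)) {
    ann <- rbind(ann, data.frame(gene_id = un, namespace = "unannotated",
                                 label = "unannotated", stringsAsFactors = FALSE))
  }
  ann$node_id <- assignment[ann$gene_id]
  agg <- stats::aggregate(list(n = ann$gene_id),
                          by = list(node_id = ann$node_id,
                                    namespace = ann$namespace,
                                    label = ann$label),
                          FUN = length)
  agg <- agg[order(agg$node_id, agg$namespace, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Nodes whose members carry all the given labels
#'
#' Co-occurrence query over [annotate_nodes()] output, e.g. nodes containing
#' both a P450 and a glutathione-S-transferase label.
#'
#' @param node_annotations An [annotate_nodes()] result.
#' @param labels Character vector of labels that must all be present.
#' @return Sorted integer vector of node IDs.
#' @export
nodes_with_labels <- function(node_annotations, labels) {
  per_label <- lapply(labels, function(l) {
    unique(node_annotations$node_id[node_annotations$label == l])
  })
  sort(Reduce(intersect, per_label))
}

#' Render Tatami maps
#'
#' Draws the node grid as one heat panel per condition: nodes coloured by
#' mean log2 expression, condition-specific nodes outlined, node IDs
#' labelled 1..N row-major (row 1 at the top). Writes one image file per
#' condition.
#'
#' @param profiles A [node_condition_means()] result.
#' @param calls Optional [call_specific_nodes()] result to outline.
#' @param path Output template containing `%s` (replaced by the condition
#'   label), or a directory (files named `tatami_<condition>.<format>`).
#' @param format `"png"` or `"pdf"`.
#' @param width,height Device size in pixels (png) or inches (pdf).
#' @return Character vector of written file paths, invisibly.
#' @export
render_tatami <- function(profiles, calls = NULL, path, format = c("png", "pdf"),
                          width = NULL, height = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(profiles, "node_profiles"))
  if (!grepl("%s", path, fixed = TRUE)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(path, paste0("tatami_%s.", format))
  }
  files <- character(0)
  rng <- range(profiles$means[profiles$n_members > 0L, ], finite = TRUE)
  for (cc in colnames(profiles$means)) {
    f <- sprintf(path, cc)
    if (format == "png") {
      grDevices::png(f, width = width %||% 900, height = height %||% 1000)
    } else {
      grDevices::pdf(f, width = width %||% 8, height = height %||% 9)
    }
    tryCatch(
      draw_tatami_panel(profiles$grid, profiles$means[, cc],
                        flagged = if (!is.null(calls)) which(calls[, cc]) else integer(),
                        main = cc, zlim = rng),
      finally = grDevices::dev.off()
    )
    files <- c(files, f)
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_tatami_panel <- function(grid, values, flagged = integer(), main = "",
                              zlim = range(values, finite = TRUE)) {
  rows <- grid$rows; cols <- grid$cols
  pal <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, cols), ylim = c(0, rows), asp = 1)
  graphics::title(main = main)
  for (i in seq_len(rows * cols)) {
    r <- grid$coords[i, 1L]; c <- grid$coords[i, 2L]
    v <- values[i]
    col <- if (is.finite(v)) {
      pal[1 + floor(99 * (v - zlim[1]) / max(zlim[2] - zlim[1], 1e-12))]
    } else "grey85"
    graphics::rect(c - 1, rows - r, c, rows - r + 1, col = col, border = "white")
    graphics::text(c - 0.5, rows - r + 0.5, labels = i, cex = 0.45)
  }
  for (i in flagged) {
    r <- grid$coords[i, 1L]; c <- grid$coords[i, 2L]
    graphics::rect(c - 1, rows - r, c, rows - r + 1, border = "black", lwd = 2)
  }
  invisible(NULL)
}

#' Tatami plot of a fitted SOM
#'
#' Single-panel Tatami view on the active graphics device: nodes coloured by
#' a per-node statistic (mean codebook value by default, or one condition of
#' a [node_condition_means()] profile), with optional outlined nodes.
#'
#' @param x A fitted [som_fit()] object.
#' @param values Per-node numeric vector; defaults to row means of the
#'   codebook.
#' @param flagged Integer node IDs to outline.
#' @param main Plot title.
#' @param ... Unused.
#' @return Invisibly, NULL.
#' @export
plot.tatami_som <- function(x, values = rowMeans(x$codebook),
                            flagged = integer(), main = "SOM codebook mean", ...) {
  draw_tatami_panel(x$grid, values, flagged = flagged, main = main)
}
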