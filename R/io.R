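#' Read a gene-level count matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers. Counts must be non-negative
#' integers. Row and column order are preserved exactly as in the file;
#' downstream tie-breaking (e.g. best-matching-unit ties) depends on it.
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV (optionally `.gz`) file.
#' @return An integer matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs).
#' @seealso [write_counts()], [read_metadata()], [read_annotations()]
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("count file must have a gene-id column and at least 2 sample columns")
  }
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicated gene ID(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicated sample ID(s): ", paste(dup_s, collapse = ", "))
  }
  raw <- df[-1L]
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf(
        "non-integer or negative count '%s' at gene '%s' (row %d), sample '%s' (column %d)",
        as.character(raw[[j]][bad[1L]]), gene_ids[bad[1L]], bad[1L],
        sample_ids[j], j
      ))
    }
  }
  counts <- as.matrix(raw)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  validate_counts(counts)
  counts
}

validate_counts <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and sample colnames")
  }
  if (nrow(counts) < 1L || ncol(counts) < 2L) {
    stop("count matrix needs at least 1 gene and 2 samples")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample IDs")
  if (any(counts < 0)) stop("negative counts")
  invisible(counts)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: the first column is `gene_id`, remaining
#' columns are samples. `read_counts(write_counts(x, f))` reproduces `x`
#' exactly.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `substrate`, `growth_point`, `replicate`.
#' Growth points are coerced to ordered integers; growth point 1 is the
#' reference for all fold-difference contrasts. A condition is a
#' (substrate, growth point) pair.
#'
#' @param path TSV file path.
#' @param counts Optional count matrix; when given, every sample column must
#'   have a metadata row (missing samples are an error listing the IDs).
#' @return A data.frame with columns `sample_id`, `substrate`,
#'   `growth_point` (integer), `replicate`, `condition`.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df, counts)
}

validate_metadata <- function(df, counts = NULL) {
  need <- c("sample_id", "substrate", "growth_point", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  gp <- suppressWarnings(as.integer(df$growth_point))
  if (anyNA(gp)) stop("growth_point values must be integers")
  df$growth_point <- gp
  df$substrate <- as.character(df$substrate)
  df$replicate <- as.character(df$replicate)
  df$condition <- condition_label(df$substrate, df$growth_point)
  if (!is.null(counts)) {
    absent <- setdiff(colnames(counts), df$sample_id)
    if (length(absent)) {
      stop("sample(s) in counts missing from metadata: ",
           paste(absent, collapse = ", "))
    }
    df <- df[match(colnames(counts), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

condition_label <- function(substrate, growth_point) {
  paste0(substrate, "_GP", growth_point)
}

#' Write sample metadata as TSV
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  keep <- c("sample_id", "substrate", "growth_point", "replicate")
  write_tsv(metadata[keep], path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Long-format TSV with columns `gene_id`, `namespace`, `label`; one row per
#' (gene, namespace, label) triple. Recognised namespaces are `CAZy`,
#' `P450_clan`, `housekeeping`, `signalp` and `unknown_function`; other
#' namespaces are kept with a warning. Genes absent from a count matrix are
#' allowed (annotation catalogues are usually genome-wide).
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `namespace`, `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  need <- c("gene_id", "namespace", "label")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$gene_id <- as.character(df$gene_id)
  df$namespace <- as.character(df$namespace)
  df$label <- as.character(df$label)
  if (any(!nzchar(df$label))) stop("empty annotation label")
  known <- c("CAZy", "P450_clan", "housekeeping", "signalp", "unknown_function")
  odd <- setdiff(unique(df$namespace), known)
  if (length(odd)) {
    warning("unknown annotation namespace(s): ", paste(odd, collapse = ", "))
  }
  df
}

#' Write an annotation table as TSV
#' @param annotations data.frame with `gene_id`, `namespace`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv(validate_annotations(annotations), path)
  invisible(path)
}

#' Look up annotations for one gene
#' @param annotations Annotation data.frame.
#' @param gene_id Gene identifier.
#' @return data.frame of (namespace, label) pairs for that gene (0 rows if
#'   unannotated).
#' @export
gene_annotations <- function(annotations, gene_id) {
  hit <- annotations[annotations$gene_id == gene_id, c("namespace", "label")]
  rownames(hit) <- NULL
  hit
}
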