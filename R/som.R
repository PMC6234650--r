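#' Rectangular SOM lattice geometry
#'
#' A rows x cols rectangular grid (4-neighbour topology). Node IDs run 1 to
#' rows*cols in row-major order; lattice coordinates are integer (row, col)
#' pairs, so the Euclidean distance between horizontally or vertically
#' adjacent nodes is 1.
#'
#' @param rows,cols Positive grid dimensions (default 24 x 20, i.e. 480
#'   nodes).
#' @return list of class `som_grid`: `rows`, `cols`, `coords` (nodes x 2
#'   matrix).
#' @export
som_grid <- function(rows = 24L, cols = 20L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid dimensions must be positive")
  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  structure(list(rows = rows, cols = cols, coords = coords),
            class = "som_grid")
}

as_som_grid <- function(x) {
  if (inherits(x, "tatami_som")) return(x$grid)
  if (inherits(x, "som_grid")) return(x)
  stop("expected a som_grid or tatami_som object")
}

#' Training-step budget from the epoch rule
#'
#' The number of online training steps is `factor` times the map size: a
#' 24 x 20 grid with the default factor of 1000 trains for 480,000 steps.
#'
#' @param grid A [som_grid()] (or fitted [som_fit()] object).
#' @param factor Steps per node, default 1000.
#' @return Integer step count.
#' @export
epoch_count <- function(grid, factor = 1000L) {
  g <- as_som_grid(grid)
  as.integer(g$rows) * as.integer(g$cols) * as.integer(factor)
}

#' Initial neighbourhood radius from lattice distances
#'
#' The given quantile (linear interpolation) of all pairwise Euclidean
#' distances between node lattice coordinates — the neighbour-distance
#' convention for choosing a starting radius that covers most of the map.
#'
#' @param grid A [som_grid()] (or fitted object).
#' @param quantile Quantile in (0, 1]; default 0.67.
#' @return The radius (a positive real).
#' @export
initial_radius <- function(grid, quantile = 0.67) {
  g <- as_som_grid(grid)
  if (g$rows * g$cols < 2L) stop("radius undefined for a single-node grid")
  d <- stats::dist(g$coords)
  unname(stats::quantile(d, probs = quantile, type = 7))
}

#' Best-matching unit of a profile vector
#'
#' The node whose codebook vector has the smallest Euclidean distance to
#' `x`; ties are broken toward the lowest node ID.
#'
#' @param object A fitted [som_fit()] object or a codebook matrix
#'   (nodes x dim, row order = node ID).
#' @param x Numeric vector, length = codebook dimension.
#' @return Integer node ID.
#' @export
bmu <- function(object, x) {
  cb <- if (inherits(object, "tatami_som")) object$codebook else as.matrix(object)
  if (length(x) != ncol(cb)) {
    stop("vector length ", length(x), " does not match codebook dimension ", ncol(cb))
  }
  d2 <- rowSums(sweep(cb, 2L, as.numeric(x), "-")^2)
  which.min(d2)   # first minimum = lowest node ID
}

#' Fit a self-organizing map to gene expression profiles
#'
#' Trains an online Kohonen SOM on gene-wise expression vectors (rows of
#' `x`, typically log2-normalized values over all samples — 20 dimensions in
#' the standard 2-substrate x 5-growth-point x 2-replicate design). The
#' codebook is initialized by sampling data rows without replacement; each
#' training step presents one observation (a seeded random order, cycled)
#' and moves the best-matching unit plus every node whose lattice distance
#' to it is strictly below the current radius (bubble neighbourhood,
#' uniform weight) toward it. The learning
#' rate decays linearly from `lr[1]` to `lr[2]` and the radius from
#' `initial_radius()` down to 1 (so the map keeps minimal smoothing at the
#' end) over the step budget. Input vectors are not feature-scaled by
#' default; set `scale = TRUE` to standardize columns.
#'
#' @param x Numeric matrix, observations (genes) in rows, with rownames.
#' @param rows,cols Grid dimensions; default 24 x 20 (480 nodes).
#' @param epochs Total step budget; default [epoch_count()] (1000 x map
#'   size). Interpreted per `steps_mode`.
#' @param steps_mode `"presentations"` (default): `epochs` is the total
#'   number of single-observation updates. `"passes"`: `epochs` full passes
#'   over the data (`epochs * nrow(x)` updates).
#' @param lr Numeric pair: initial and final learning rate (default
#'   0.05 to 0.01).
#' @param radius Initial radius; default the 0.67 lattice-distance quantile
#'   via [initial_radius()].
#' @param radius_quantile Quantile used when `radius` is NULL.
#' @param scale Standardize columns before training (default FALSE).
#' @param seed Integer seed controlling initialization and presentation
#'   order; same data + seed reproduces the fit exactly.
#' @return An object of class `tatami_som`: list with `codebook` (nodes x
#'   dim), `grid`, `assignment` (named integer vector gene -> node),
#'   `qe`/`qe_initial` (quantization errors after/before training),
#'   `config`, and the training data dimensions.
#' @seealso [predict.tatami_som()], [quantization_error()],
#'   [node_condition_means()], [plot.tatami_som()]
#' @export
som_fit <- function(x, rows = 24L, cols = 20L, epochs = NULL,
                    steps_mode = c("presentations", "passes"),
                    lr = c(0.05, 0.01), radius = NULL,
                    radius_quantile = 0.67, scale = FALSE, seed = 1L) {
  steps_mode <- match.arg(steps_mode)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  bad <- rownames(x)[!stats::complete.cases(x) | apply(x, 1L, function(v) any(is.nan(v)))]
  if (length(bad)) {
    stop("NA/NaN values in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  if (scale) x <- base::scale(x)
  grid <- som_grid(rows, cols)
  n_nodes <- grid$rows * grid$cols
  n <- nrow(x)
  if (n < n_nodes) {
    warning("fewer observations (", n, ") than nodes (", n_nodes,
            "); codebook initialized with replacement")
  }
  if (is.null(epochs)) epochs <- epoch_count(grid)
  total_steps <- if (steps_mode == "presentations") as.integer(epochs)
                 else as.integer(epochs) * n
  if (total_steps < 1L) stop("epochs must be positive")
  r0 <- if (is.null(radius)) initial_radius(grid, radius_quantile) else radius

  set.seed(seed)
  init_idx <- sample.int(n, n_nodes, replace = n < n_nodes)
  codebook0 <- x[init_idx, , drop = FALSE]
  perm <- sample.int(n)
  order0 <- perm[((seq_len(total_steps) - 1L) %% n) + 1L] - 1L

  map0 <- som_map_cpp(codebook0, x)
  codebook <- som_train_cpp(codebook0, x, order0, grid$coords,
                            lr[1], lr[2], r0, 1.0)
  rownames(codebook) <- seq_len(n_nodes)
  colnames(codebook) <- colnames(x)
  map1 <- som_map_cpp(codebook, x)
  assignment <- stats::setNames(map1$bmu, rownames(x))

  structure(list(
    codebook = codebook,
    grid = grid,
    assignment = assignment,
    qe = mean(map1$dist),
    qe_initial = mean(map0$dist),
    config = list(epochs = epochs, steps_mode = steps_mode,
                  total_steps = total_steps, lr = lr, radius = r0,
                  radius_quantile = radius_quantile, scale = scale,
                  seed = as.integer(seed)),
    n_obs = n, dim = ncol(x), sample_ids = colnames(x)
  ), class = "tatami_som")
}

#' @export
print.tatami_som <- function(x, ...) {
  cat(sprintf("Self-organizing map: %d x %d grid (%d nodes), %d-dim codebooks\n",
              x$grid$rows, x$grid$cols, x$grid$rows * x$grid$cols, x$dim))
  cat(sprintf("Trained on %d profiles for %d steps (lr %.3g -> %.3g, radius %.3g -> 1)\n",
              x$n_obs, x$config$total_steps, x$config$lr[1], x$config$lr[2],
              x$config$radius))
  cat(sprintf("Quantization error: %.4g (initial %.4g)\n", x$qe, x$qe_initial))
  invisible(x)
}

#' @export
summary.tatami_som <- function(object, ...) {
  occ <- tabulate(object$assignment, nbins = object$grid$rows * object$grid$cols)
  out <- list(grid = c(rows = object$grid$rows, cols = object$grid$cols),
              n_obs = object$n_obs, qe = object$qe,
              qe_initial = object$qe_initial,
              empty_nodes = sum(occ == 0L),
              occupancy = summary(occ))
  class(out) <- "summary.tatami_som"
  out
}

#' @export
print.summary.tatami_som <- function(x, ...) {
  cat(sprintf("SOM %d x %d, %d profiles, QE %.4g (initial %.4g), %d empty nodes\n",
              x$grid["rows"], x$grid["cols"], x$n_obs, x$qe, x$qe_initial,
              x$empty_nodes))
  cat("Node occupancy:\n"); print(x$occupancy)
  invisible(x)
}

#' Map profiles to their best-matching units
#'
#' @param object A fitted [som_fit()] object.
#' @param newdata Numeric matrix of profiles (columns matching the training
#'   dimension). Defaults to returning the training assignment.
#' @param ... Unused.
#' @return Named integer vector of node IDs.
#' @export
predict.tatami_som <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignment)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop("newdata has ", ncol(newdata), " columns; codebook dimension is ", object$dim)
  }
  map <- som_map_cpp(object$codebook, newdata)
  stats::setNames(map$bmu, rownames(newdata))
}

#' Quantization error of a fitted map
#'
#' Mean Euclidean distance of profiles to their best-matching unit; smaller
#' is a tighter fit.
#'
#' @param object A fitted [som_fit()] object.
#' @param newdata Optional profile matrix; defaults to the training QE.
#' @return A single non-negative number.
#' @export
quantization_error <- function(object, newdata = NULL) {
  if (is.null(newdata)) return(object$qe)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) stop("dimension mismatch")
  mean(som_map_cpp(object$codebook, newdata)$dist)
}

#' Genes per node
#'
#' @param object A fitted [som_fit()] object (or any named gene -> node
#'   vector).
#' @return list: for each node ID (as character), the member gene IDs;
#'   empty nodes are present with zero-length entries when the grid is
#'   known.
#' @export
node_members <- function(object) {
  if (inherits(object, "tatami_som")) {
    a <- object$assignment
    n_nodes <- object$grid$rows * object$grid$cols
  } else {
    a <- object
    n_nodes <- max(a)
  }
  out <- split(names(a), factor(a, levels = seq_len(n_nodes)))
  out
}

#' Lattice distance between nodes
#'
#' Euclidean distance between node lattice coordinates; used for topology-
#' preservation checks ("within lattice distance 2 of the modal node").
#'
#' @param grid A [som_grid()] or fitted object.
#' @param a,b Integer node IDs (vectors recycle).
#' @return Numeric distances.
#' @export
lattice_distance <- function(grid, a, b) {
  g <- as_som_grid(grid)
  ca <- g$coords[a, , drop = FALSE]
  cb <- g$coords[b, , drop = FALSE]
  sqrt(rowSums((ca - cb)^2))
}
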