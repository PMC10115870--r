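#' Voxel-level structural connectome and dysconnectome projection
#'
#' The connectome is an undirected weighted graph whose nodes are grey-matter
#' voxels on a common grid and whose edge weights are mean normalised
#' streamline values from probabilistic tractography (or a synthetic
#' stand-in). Projecting a stimulation through it renders the direct edge
#' weights from the seed node to every other node as an image volume: the
#' transient dysconnectome of that stimulation.
#'
#' @name dysconnectome
NULL

#' Read a connectome from Matrix Market + node coordinates
#'
#' @param matrix_path Matrix Market (.mtx) sparse weight matrix.
#' @param coords_path delimited table with columns `node_id`, `x_mm`, `y_mm`,
#'   `z_mm` (node_id is 1-based and must match matrix row order).
#' @param grid `vol_grid` of the connectome sampling (2 mm in the reference
#'   analysis).
#' @return a `connectome_graph`: `weights` (sparse symmetric dgCMatrix),
#'   `node_coords_mm`, `node_voxel` (linear voxel index per node), `grid`.
#' @export
read_connectome <- function(matrix_path, coords_path, grid) {
  A <- methods::as(Matrix::readMM(matrix_path) * 1, "CsparseMatrix")
  header <- readLines(coords_path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  coords <- utils::read.table(coords_path, header = TRUE, sep = sep)
  req <- c("node_id", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(coords)))
    stop("node coordinate table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  coords <- coords[order(coords$node_id), ]
  if (nrow(A) != ncol(A) || nrow(A) != nrow(coords))
    stop(sprintf(
      "node count mismatch: matrix is %d x %d but coordinate table has %d rows",
      nrow(A), ncol(A), nrow(coords)), call. = FALSE)
  if (any(A@x < 0))
    stop("connectome contains negative edge weights", call. = FALSE)
  asym <- max(abs(A - Matrix::t(A)))
  if (asym > 1e-9) {
    warning(sprintf("asymmetric connectome (max |A - t(A)| = %g); symmetrised by averaging",
                    asym), call. = FALSE)
    A <- (A + Matrix::t(A)) / 2
  }
  new_connectome(A, as.matrix(coords[, c("x_mm", "y_mm", "z_mm")]), grid)
}

new_connectome <- function(weights, node_coords_mm, grid) {
  vox <- grid_voxel(grid, node_coords_mm)
  vox <- matrix(vox, ncol = 3L)
  if (!all(in_grid(grid, vox)))
    stop("some connectome nodes fall outside the grid", call. = FALSE)
  lin <- vox_linear(grid, vox)
  if (anyDuplicated(lin))
    stop("multiple connectome nodes map to the same voxel", call. = FALSE)
  structure(
    list(weights = methods::as(weights, "CsparseMatrix"),
         node_coords_mm = unname(node_coords_mm),
         node_voxel = lin, grid = grid),
    class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf("<connectome_graph> %d nodes, %d stored entries on %s grid\n",
              nrow(x$weights), length(x$weights@x),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Write a connectome as Matrix Market + TSV coordinates
#' @param graph a `connectome_graph`.
#' @param matrix_path,coords_path destination paths.
#' @export
write_connectome <- function(graph, matrix_path, coords_path) {
  Matrix::writeMM(graph$weights, matrix_path)
  df <- data.frame(node_id = seq_len(nrow(graph$node_coords_mm)),
                   x_mm = graph$node_coords_mm[, 1],
                   y_mm = graph$node_coords_mm[, 2],
                   z_mm = graph$node_coords_mm[, 3])
  utils::write.table(df, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Row-sum normalise a connectome
#'
#' Divides each row by its sum (emulating waytotal normalisation of
#' streamline counts, which scales each seed's counts by its total
#' successful tracts) and re-symmetrises by averaging. Intended for
#' synthetic graphs; real connectomes are assumed normalised upstream.
#'
#' @param graph a `connectome_graph`.
#' @return a `connectome_graph` with normalised weights.
#' @export
normalise_connectome <- function(graph) {
  rs <- Matrix::rowSums(graph$weights)
  rs[rs == 0] <- 1
  A <- graph$weights / rs
  graph$weights <- methods::as((A + Matrix::t(A)) / 2, "CsparseMatrix")
  graph
}

#' Unique undirected edge capacity of a complete graph
#' @param n_nodes number of nodes.
#' @return n (n - 1) / 2 as a double (exceeds 32-bit range at connectome scale).
#' @export
edge_capacity <- function(n_nodes) {
  n <- as.numeric(n_nodes)
  n * (n - 1) / 2
}

#' Nearest connectome node to a world point
#'
#' @param graph a `connectome_graph`.
#' @param world_mm world coordinate (length 3).
#' @param cutoff_mm maximum admissible seed-to-node distance (default 5 mm).
#' @return list(`node`, `distance_mm`); ties break toward the lower node id.
#' @export
nearest_node <- function(graph, world_mm, cutoff_mm = 5) {
  d2 <- colSums((t(graph$node_coords_mm) - as.numeric(world_mm))^2)
  node <- which.min(d2)  # which.min returns the first (lowest id) tie
  dist <- sqrt(d2[node])
  if (dist > cutoff_mm)
    stop(sprintf("unmappable seed: nearest node is %.2f mm away (cutoff %.2f mm)",
                 dist, cutoff_mm), call. = FALSE)
  list(node = node, distance_mm = dist)
}

#' Project a stimulation through the connectome
#'
#' Renders the direct edge weights from the seed node to all other nodes as a
#' volume on the connectome grid (no path composition or diffusion). The
#' seed's own voxel takes the maximum of its edge weights by default so that
#' the seed is never the dimmest point of its own map; `seed_value = "zero"`
#' leaves it at zero.
#'
#' @param graph a `connectome_graph`.
#' @param world_mm seed world coordinate, or a single-row `stim_table`.
#' @param cutoff_mm seed mapping cutoff passed to [nearest_node()].
#' @param seed_value `"max"` (default) or `"zero"`.
#' @return a `vol_volume` on the connectome grid.
#' @export
project_stimulation <- function(graph, world_mm, cutoff_mm = 5,
                                seed_value = c("max", "zero")) {
  seed_value <- match.arg(seed_value)
  if (inherits(world_mm, "stim_table")) {
    stopifnot(nrow(world_mm) == 1L)
    world_mm <- as.numeric(stim_coords(world_mm)[1, ])
  }
  nn <- nearest_node(graph, world_mm, cutoff_mm)
  w <- as.numeric(graph$weights[nn$node, ])
  w[nn$node] <- 0
  if (all(w == 0))
    message("seed node ", nn$node, " has no edges; projection is all zero")
  else if (seed_value == "max") w[nn$node] <- max(w)
  vals <- numeric(prod(graph$grid$shape))
  vals[graph$node_voxel] <- w
  new_volume(graph$grid, vals)
}

#' Clamp extreme intensities of a projected volume
#'
#' Values below the `low_q` quantile of the nonzero intensities are raised to
#' that quantile and values above the `high_q` quantile lowered to it
#' (defaults 0.001 / 0.999, i.e. the 0.1 and 99.9 percentiles), suppressing
#' presumably spurious extremes. Quantiles are computed per volume over its
#' nonzero values as order statistics (type-1 quantiles), which makes
#' clamping exactly idempotent; zeros (non-node or unconnected voxels) are
#' left untouched.
#'
#' @param vol a `vol_volume`.
#' @param low_q,high_q quantile bounds, 0 <= low_q < high_q <= 1.
#' @return clamped `vol_volume`.
#' @export
clamp_intensities <- function(vol, low_q = 0.001, high_q = 0.999) {
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  nz <- vol$values != 0
  if (!any(nz)) return(vol)
  q <- stats::quantile(vol$values[nz], c(low_q, high_q), names = FALSE,
                       type = 1)
  v <- vol$values
  v[nz] <- pmin(pmax(v[nz], q[1]), q[2])
  new_volume(vol$grid, v)
}

#' Run the dysconnectome inference pipeline
#'
#' Per stimulation: project through the connectome, clamp extremes, smooth
#' (6 mm FWHM by default); then the same repeated-measures GLM, whitening and
#' permutation maxT threshold as the focal arm, on the connectome grid. The
#' analysis mask is the set of node voxels.
#'
#' @param graph a `connectome_graph`.
#' @param records a `stim_table`.
#' @param behaviour behaviour column to model.
#' @param fwhm_mm smoothing FWHM (default 6).
#' @param clamp quantile bounds c(low, high) (default c(0.001, 0.999));
#'   `NULL` disables clamping.
#' @param clamp_after_smooth apply clamping after rather than before
#'   smoothing (default `FALSE`: clamp then smooth).
#' @param alpha,n_perm,seed permutation threshold settings.
#' @param cutoff_mm seed mapping cutoff.
#' @return list(`fit`, `threshold`, `Y`, `mask`, `design`, `ns`).
#' @export
run_dysconnectome_pipeline <- function(graph, records, behaviour,
                                       fwhm_mm = 6, clamp = c(0.001, 0.999),
                                       clamp_after_smooth = FALSE,
                                       alpha = 0.05, n_perm = 2000,
                                       seed = NULL, cutoff_mm = 5) {
  stopifnot(inherits(records, "stim_table"))
  coords <- stim_coords(records)
  nv <- prod(graph$grid$shape)
  Y <- matrix(0, nrow(records), nv)
  for (r in seq_len(nrow(records))) {
    v <- project_stimulation(graph, coords[r, ], cutoff_mm = cutoff_mm)
    if (!is.null(clamp) && !clamp_after_smooth)
      v <- clamp_intensities(v, clamp[1], clamp[2])
    if (fwhm_mm > 0) v <- smooth_volume(v, fwhm_mm)
    if (!is.null(clamp) && clamp_after_smooth)
      v <- clamp_intensities(v, clamp[1], clamp[2])
    Y[r, ] <- v$values
  }
  mask_vec <- numeric(nv); mask_vec[graph$node_voxel] <- 1
  mask <- new_volume(graph$grid, mask_vec)
  design <- build_design(records, behaviour)
  ns <- estimate_nonsphericity(Y, design, mask_idx = which(mask_vec != 0))
  fit <- fit_glm(Y, design, ns, mask = mask, grid = graph$grid)
  thr <- fwe_threshold_maxT(Y, design, ns, mask = mask, alpha = alpha,
                            n_perm = n_perm, seed = seed, grid = graph$grid)
  list(fit = fit, threshold = thr, Y = Y, mask = mask, design = design,
       ns = ns)
}
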