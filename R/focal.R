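#' Focal density mapping
#'
#' Each stimulation locus becomes a one-hot image (intensity one at its
#' nearest voxel, zero elsewhere) convolved with a truncated Gaussian kernel.
#' The resulting density volume carries the locus's spatial uncertainty and is
#' the dependent variable of the voxel-wise GLM. The analysis mask keeps
#' voxels whose mean density across all stimulations exceeds a small floor,
#' excluding poorly sampled territory.
#'
#' @name focal
NULL

#' Density volume for one stimulation
#'
#' @param world_mm stimulation world coordinate (length-3, MNI mm), or a
#'   single-row `stim_table`.
#' @param grid target `vol_grid`.
#' @param kernel a `gaussian_kernel` (unnormalised weights, peak one).
#' @return a `vol_volume`: the kernel stencil centred at the nearest voxel.
#' @export
make_density_volume <- function(world_mm, grid, kernel) {
  if (inherits(world_mm, "stim_table")) {
    stopifnot(nrow(world_mm) == 1L)
    world_mm <- as.numeric(stim_coords(world_mm)[1, ])
  }
  centre <- grid_voxel(grid, world_mm)
  if (!in_grid(grid, centre))
    stop(sprintf("stimulation at (%s) mm maps outside the grid",
                 paste(signif(world_mm, 4), collapse = ", ")), call. = FALSE)
  vals <- array(0, grid$shape)
  tgt <- sweep(kernel$offsets, 2L, as.integer(centre), "+")
  keep <- in_grid(grid, tgt)
  vals[vox_linear(grid, tgt[keep, , drop = FALSE])] <- kernel$w[keep]
  new_volume(grid, vals)
}

#' Density stack for a cohort
#'
#' Builds one density image per stimulation and stores them as a dense
#' records-by-voxels matrix (the GLM's response matrix).
#'
#' @param records a `stim_table`.
#' @param grid a `vol_grid`.
#' @param kernel a `gaussian_kernel`.
#' @return a `density_stack`: `grid`, `records`, `Y` (n_records x n_voxels).
#' @export
make_density_stack <- function(records, grid, kernel) {
  stopifnot(inherits(records, "stim_table"), nrow(records) >= 1L)
  coords <- stim_coords(records)
  centres <- grid_voxel(grid, coords)
  centres <- matrix(centres, ncol = 3L)
  ok <- in_grid(grid, centres)
  if (!all(ok))
    stop(sprintf("stimulation row %d at (%s) mm maps outside the grid",
                 which(!ok)[1],
                 paste(signif(coords[which(!ok)[1], ], 4), collapse = ", ")),
         call. = FALSE)
  nv <- prod(grid$shape)
  Y <- matrix(0, nrow(records), nv)
  for (r in seq_len(nrow(records))) {
    tgt <- sweep(kernel$offsets, 2L, as.integer(centres[r, ]), "+")
    keep <- in_grid(grid, tgt)
    Y[r, vox_linear(grid, tgt[keep, , drop = FALSE])] <- kernel$w[keep]
  }
  structure(list(grid = grid, records = records, Y = Y, kernel = kernel),
            class = "density_stack")
}

#' Extract one volume from a density stack
#' @param stack a `density_stack`.
#' @param i record index.
#' @return a `vol_volume`.
#' @export
stack_volume <- function(stack, i) new_volume(stack$grid, stack$Y[i, ])

#' Analysis mask from mean stimulation density
#'
#' @param stack a `density_stack`.
#' @param density_threshold keep voxels with mean density strictly above this
#'   (default 1e-5, the focal pipeline's floor).
#' @param extra_mask optional binary `vol_volume` (e.g. an anatomical medial
#'   wall mask) intersected with the density mask.
#' @return binary `vol_volume`.
#' @export
build_density_mask <- function(stack, density_threshold = 1e-5,
                               extra_mask = NULL) {
  stopifnot(inherits(stack, "density_stack"))
  if (nrow(stack$Y) == 0L) stop("empty density stack", call. = FALSE)
  if (density_threshold < 0)
    stop("`density_threshold` must be >= 0", call. = FALSE)
  m <- as.numeric(colMeans(stack$Y) > density_threshold)
  if (!is.null(extra_mask)) {
    stopifnot(grids_equal(stack$grid, extra_mask$grid))
    m <- m * as.numeric(extra_mask$values != 0)
  }
  if (!any(m > 0))
    warning("density mask is empty at threshold ", density_threshold,
            call. = FALSE)
  new_volume(stack$grid, m)
}

#' Behaviour counts and percentages
#'
#' @param records a `stim_table`.
#' @return data.frame with columns `behaviour`, `count`, `percent`
#'   (100 * count / total, rounded to the nearest integer).
#' @examples
#' # 153 positive-motor of 477 stimulations -> 32%
#' @export
behaviour_counts <- function(records) {
  stopifnot(inherits(records, "stim_table"), nrow(records) >= 1L)
  beh <- stim_behaviours(records)
  counts <- vapply(beh, function(b) sum(records[[b]] == 1L), 1L)
  data.frame(behaviour = beh, count = as.integer(counts),
             percent = as.integer(round(100 * counts / nrow(records))),
             row.names = NULL)
}
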