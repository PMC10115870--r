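#' Voxel grids and volumes
#'
#' A `vol_grid` couples a 3D array shape with a 4x4 voxel-index -> world-mm
#' affine. Voxel indices are 0-based throughout; world coordinates are MNI mm.
#' A `vol_volume` is a scalar field on such a grid.
#'
#' @name grid
NULL

#' Create an axis-aligned voxel grid
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param voxel_size_mm positive real triple (a scalar is recycled).
#' @param origin_mm world coordinate of voxel index (0,0,0).
#' @return a `vol_grid` with fields `shape`, `voxel_size_mm`, `affine`.
#' @examples
#' g <- make_grid(c(10, 10, 10), 1.5, c(0, 0, 0))
#' grid_world(g, c(2, 0, 0))  # (3, 0, 0) mm
#' @export
make_grid <- function(shape, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be an integer triple with entries >= 1", call. = FALSE)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel sizes must be positive reals", call. = FALSE)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_size_mm
  affine[1:3, 4] <- origin_mm
  new_grid(shape, affine)
}

## internal constructor: derives voxel sizes from the affine columns so that
## grids read from NIfTI (possibly rotated) share the same representation
new_grid <- function(shape, affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("grid affine is singular", call. = FALSE)
  structure(
    list(shape = as.integer(shape),
         voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)),
         affine = affine),
    class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

#' Voxel index to world coordinate
#'
#' @param grid a `vol_grid`.
#' @param idx 0-based voxel indices: length-3 vector or n x 3 matrix.
#' @return world mm coordinates, same shape as `idx`.
#' @export
grid_world <- function(grid, idx) {
  idx <- rbind_coords(idx)
  w <- idx %*% t(grid$affine[1:3, 1:3]) +
    matrix(grid$affine[1:3, 4], nrow(idx), 3, byrow = TRUE)
  drop_coords(w, idx)
}

#' World coordinate to nearest 0-based voxel index
#'
#' A world point is assigned to its nearest voxel center; exact half-way ties
#' break toward the lower index.
#'
#' @param grid a `vol_grid`.
#' @param world world mm coordinates: length-3 vector or n x 3 matrix.
#' @param continuous if `TRUE`, return unrounded voxel coordinates.
#' @return 0-based voxel indices.
#' @export
grid_voxel <- function(grid, world, continuous = FALSE) {
  world <- rbind_coords(world)
  inv <- solve(grid$affine)
  v <- world %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(world), 3, byrow = TRUE)
  if (!continuous) v <- ceiling(v - 0.5)  # round half toward lower index
  drop_coords(v, world)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  else {
    stopifnot(ncol(x) == 3L)
    matrix(as.numeric(x), ncol = 3L)
  }
}

drop_coords <- function(out, template) {
  if (nrow(out) == 1L && nrow(template) == 1L) drop(out) else out
}

in_grid <- function(grid, idx) {
  idx <- rbind_coords(idx)
  apply(idx >= 0 & sweep(idx, 2, grid$shape, "<"), 1L, all)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' Create a volume on a grid
#'
#' @param grid a `vol_grid`.
#' @param values scalar per voxel: an array of dim `grid$shape`, a vector of
#'   matching length (column-major), or a scalar to fill with.
#' @return a `vol_volume` with fields `grid`, `values` (3D array).
#' @export
new_volume <- function(grid, values = 0) {
  nv <- prod(grid$shape)
  if (length(values) == 1L) values <- rep(as.numeric(values), nv)
  if (length(values) != nv)
    stop("`values` length does not match grid", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(list(grid = grid, values = array(as.numeric(values), grid$shape)),
            class = "vol_volume")
}

#' @export
print.vol_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<vol_volume> %s voxels, range [%g, %g]\n",
              paste(x$grid$shape, collapse = "x"), rng[1], rng[2]))
  invisible(x)
}

## 0-based (i,j,k) matrix -> 1-based linear index into the value array
vox_linear <- function(grid, idx) {
  idx <- rbind_coords(idx)
  as.integer(1 + idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3]))
}

## 1-based linear index -> 0-based (i,j,k) matrix
linear_vox <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% grid$shape[1]
  j <- (lin0 %/% grid$shape[1]) %% grid$shape[2]
  k <- lin0 %/% (grid$shape[1] * grid$shape[2])
  cbind(i, j, k)
}
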