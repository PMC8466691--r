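#' Image grid: shape, voxel size and voxel-to-world affine
#'
#' An `image_grid` ties a voxel lattice to world (scanner) space. Voxel
#' indices are 0-based; voxel `(i, j, k)` owns the half-open world cube
#' centred on `affine %*% c(i, j, k, 1)`. All world coordinates are in mm.
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param voxel_size numeric length 3, voxel edge lengths in mm (all > 0).
#'   Ignored when `affine` is supplied (then derived from it).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal scaling by
#'   `voxel_size` with the origin at voxel (0,0,0).
#' @return An object of class `image_grid` with elements `shape`,
#'   `voxel_size` and `affine`.
#' @examples
#' g <- image_grid(c(64, 64, 40), c(3, 3, 6))
#' voxel_to_world(g, c(1, 0, 0))  # 3 0 0
#' @export
image_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("'shape' must be three positive integers")
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(voxel_size <= 0))
      stop("'voxel_size' must be three positive lengths (mm)")
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- unname(as.matrix(affine))
    if (!all(dim(affine) == c(4L, 4L)))
      stop("'affine' must be a 4x4 matrix")
    if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
      stop("'affine' is singular: not a valid voxel-to-world map")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(voxel_size <= 0)) stop("degenerate voxel size in affine")
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(format(x$voxel_size, digits = 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Map 0-based voxel indices to world mm (and back)
#'
#' @param grid an [image_grid()].
#' @param vox numeric matrix (n x 3) or vector of 0-based voxel indices
#'   (continuous values allowed).
#' @return n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, vox) {
  v <- if (is.matrix(vox)) vox else matrix(vox, ncol = 3L)
  w <- cbind(v, 1) %*% t(grid$affine)
  out <- w[, 1:3, drop = FALSE]
  if (!is.matrix(vox)) out <- drop(out)
  out
}

#' @rdname voxel_to_world
#' @param world numeric matrix (n x 3) or vector of world mm coordinates.
#' @export
world_to_voxel <- function(grid, world) {
  w <- if (is.matrix(world)) world else matrix(world, ncol = 3L)
  v <- cbind(w, 1) %*% t(solve(grid$affine))
  out <- v[, 1:3, drop = FALSE]
  if (!is.matrix(world)) out <- drop(out)
  out
}

#' Do two grids describe the same sampling lattice?
#'
#' Shapes must be identical and affines must agree element-wise within `tol`.
#' Pipeline stages receiving mismatched grids refuse to proceed.
#'
#' @param a,b [image_grid()] objects.
#' @param tol absolute tolerance on affine entries (mm).
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs", tol = 1e-4) {
  if (!same_grid(a, b, tol))
    stop(sprintf(paste0("grid mismatch between %s: shapes %s vs %s ",
                        "(affines must agree within %g)"),
                 what, paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x"), tol))
  invisible(TRUE)
}

#' Voxel volume in cubic millimetres
#' @param grid an [image_grid()].
#' @export
voxel_volume_mm3 <- function(grid) abs(det(grid$affine[1:3, 1:3]))
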