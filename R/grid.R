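#' Reference grid for a co-registered lesion cohort
#'
#' All lesion masks of a cohort must live on one common grid (for real data,
#' typically the 1 mm MNI-152 template grid). The grid records the array
#' shape, voxel size in mm, a 4x4 voxel-to-world affine kept for NIfTI
#' round-tripping, and a free-text space label.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3, mm per axis (recycled if
#'   length 1).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal affine
#'   built from `voxel_size` with the origin at voxel (1,1,1).
#' @param space free-text space label, e.g. `"MNI152-1mm"`.
#' @return An object of class `reference_grid`.
#' @export
reference_grid <- function(shape, voxel_size = c(1, 1, 1),
                           affine = NULL, space = "unspecified") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop_mlsmap("grid shape must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_mlsmap("voxel_size must be 3 positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    stop_mlsmap("affine must be a 4x4 matrix")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine, space = as.character(space)),
            class = "reference_grid")
}

#' @export
print.reference_grid <- function(x, ...) {
  cat(sprintf("<reference_grid> %s: %s voxels, %s mm\n", x$space,
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' @export
format.reference_grid <- function(x, ...) {
  sprintf("%s [%s]", paste(x$shape, collapse = "x"), x$space)
}

voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

n_voxels <- function(grid) prod(grid$shape)

grids_compatible <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

# flat index (1-based, column-major; R's native array order) <-> 3-D coords
flat_to_coord <- function(index, grid) {
  arrayInd(as.integer(index), .dim = grid$shape)
}

coord_to_flat <- function(coords, grid) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  s <- grid$shape
  if (any(coords < 1L) || any(coords[, 1] > s[1]) ||
      any(coords[, 2] > s[2]) || any(coords[, 3] > s[3]))
    stop_mlsmap("coordinates outside the grid")
  coords[, 1] + s[1] * (coords[, 2] - 1L) + s[1] * s[2] * (coords[, 3] - 1L)
}

coord_to_world <- function(coords, grid) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  # NIfTI voxel indices are 0-based in world mapping
  h <- cbind(coords - 1, 1)
  t(grid$affine %*% t(h))[, 1:3, drop = FALSE]
}
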