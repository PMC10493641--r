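#' Volumetric image with a world-space affine
#'
#' The basic spatial container of the package: a 3-D (or 4-D, for time
#' series) numeric array together with a 4x4 affine matrix mapping 0-based
#' voxel indices `(i, j, k)` to world coordinates in millimetres,
#' `world = affine %*% c(i, j, k, 1)`. All user-facing coordinates in the
#' package are world mm; voxel indices are an internal detail.
#'
#' @param data numeric or logical array, 3 or 4 dimensions.
#' @param affine 4x4 numeric matrix; last row must be `c(0, 0, 0, 1)`.
#' @return An object of class `image3d`.
#' @export
image3d <- function(data, affine = diag(4)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("image3d requires a 3-D or 4-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0, 0, 0, 1)")
  structure(list(data = data, affine = affine), class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat("<image3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(img_spacing(x), 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' @rdname image3d
#' @param x object to test.
#' @export
is_image3d <- function(x) inherits(x, "image3d")

#' Voxel spacing of an image (mm per voxel, one value per spatial axis)
#' @param img an [image3d].
#' @return numeric length 3.
#' @export
img_spacing <- function(img) {
  sqrt(colSums(img$affine[1:3, 1:3]^2))
}

#' Volume of one voxel in mm^3
#' @param img an [image3d].
#' @export
voxel_volume <- function(img) abs(det(img$affine[1:3, 1:3]))

#' Spatial dimensions of an image
#' @param img an [image3d].
#' @return integer length 3 (time dimension, if any, is dropped).
#' @export
img_dim <- function(img) dim(img$data)[1:3]

#' Construct an empty image on a regular grid
#'
#' @param shape integer length 3, voxels per axis.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param centre world coordinate (mm) of the grid centre.
#' @param value fill value.
#' @return an [image3d] with a diagonal RAS affine.
#' @export
make_grid <- function(shape, spacing = 1, centre = c(0, 0, 0), value = 0) {
  shape <- as.integer(shape)
  spacing <- rep_len(spacing, 3L)
  origin <- centre - spacing * (shape - 1L) / 2
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  image3d(array(value, dim = shape), aff)
}

#' Convert voxel indices to world coordinates
#'
#' @param img an [image3d].
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(img, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(img$affine[1:3, 1:3] %*% t(ijk)) +
    matrix(img$affine[1:3, 4], nrow(ijk), 3L, byrow = TRUE)
}

#' Convert world coordinates to (continuous, 0-based) voxel indices
#'
#' @param img an [image3d].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(img, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(img$affine)
  t(inv[1:3, 1:3] %*% t(xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3L, byrow = TRUE)
}

#' World coordinates of every voxel centre
#'
#' @param img an [image3d].
#' @return (n_voxels x 3) matrix in the array's linear (column-major) order.
#' @export
voxel_centres <- function(img) {
  shp <- img_dim(img)
  ijk <- arrayInd(seq_len(prod(shp)), shp) - 1L
  voxel_to_world(img, ijk)
}

#' Test that two images live on the same grid
#' @param a,b [image3d] objects.
#' @param tol tolerance on affine entries.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(img_dim(a) == img_dim(b)) && max(abs(a$affine - b$affine)) <= tol
}

#' Replace the data of an image, keeping its grid
#' @param img an [image3d].
#' @param data array matching the grid shape.
#' @export
img_like <- function(img, data) {
  data <- array(data, dim = if (length(dim(data)) == 4L) dim(data) else img_dim(img))
  image3d(data, img$affine)
}

#' Look up image values at world coordinates (nearest neighbour)
#'
#' Points falling outside the grid return `outside`.
#'
#' @param img an [image3d] (3-D).
#' @param xyz n x 3 matrix of mm coordinates.
#' @param outside value returned for out-of-grid points.
#' @export
sample_at <- function(img, xyz, outside = NA) {
  shp <- img_dim(img)
  ijk <- round(world_to_voxel(img, xyz))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
        ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
        ijk[, 3] >= 0 & ijk[, 3] < shp[3]
  out <- rep(outside, nrow(ijk))
  if (any(ok)) {
    lin <- 1L + ijk[ok, 1] + shp[1] * (ijk[ok, 2] + shp[2] * ijk[ok, 3])
    out[ok] <- img$data[lin]
  }
  out
}

#' Resample a binary mask onto another grid (nearest neighbour)
#'
#' Each target voxel is marked if its centre falls inside a TRUE voxel of
#' the source mask.
#'
#' @param mask an [image3d] with logical/0-1 data.
#' @param target an [image3d] defining the output grid.
#' @return logical array with the target's spatial dimensions.
#' @export
mask_on_grid <- function(mask, target) {
  v <- sample_at(mask, voxel_centres(target), outside = 0)
  array(!is.na(v) & v > 0, dim = img_dim(target))
}
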