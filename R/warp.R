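#' Displacement warp fields and mask resampling
#'
#' A `warp_field` stores, on the *target* grid, a per-voxel displacement vector
#' (mm) mapping each target-space world point to the source-space world point
#' it samples — the pull-back/resampling convention used by FSL-style warps,
#' which never leaves holes in the output.
#'
#' @param displacement 4-D array (X, Y, Z, 3) of displacement components in mm.
#' @param affine 4x4 voxel-to-world affine of the target grid.
#' @return A `warp_field` object.
#' @export
warp_field <- function(displacement, affine = NULL) {
  if (!is.array(displacement) || length(dim(displacement)) != 4L ||
      dim(displacement)[4L] != 3L) {
    abort("`displacement` must be a 4-D array with 3 components")
  }
  if (!all(is.finite(displacement))) abort("displacement magnitudes must be finite")
  dims <- dim(displacement)[1:3]
  if (is.null(affine)) affine <- diag(4)
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    abort("`affine` must be an invertible 4x4 matrix")
  }
  structure(list(displacement = displacement, affine = affine, dims = dims),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  mags <- sqrt(rowSums(matrix(x$displacement, ncol = 3L)^2))
  cat(sprintf("<warp_field> target %s; |d| max %.3f mm\n",
              paste(x$dims, collapse = "x"), max(mags)))
  invisible(x)
}

#' @rdname warp_field
#' @param dims Target grid shape for `identity_warp()`.
#' @export
identity_warp <- function(dims, affine = NULL) {
  warp_field(array(0, c(dims, 3L)), affine = affine %||% diag(4))
}

#' Read/write warp fields as 3-volume NIfTI vector images
#' @param path File path.
#' @param w A [warp_field()].
#' @return `read_warp()` returns a [warp_field()].
#' @export
read_warp <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  storage.mode(a) <- "double"
  if (length(dim(a)) != 4L || dim(a)[4L] != 3L) {
    abort(sprintf("expected a 3-volume vector image: %s", path))
  }
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  warp_field(a, affine = aff)
}

#' @rdname read_warp
#' @export
write_warp <- function(w, path) {
  img <- RNifti::asNifti(w$displacement, datatype = "double")
  RNifti::sform(img) <- structure(w$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Warp a binary mask onto a new grid
#'
#' Resamples `mask` onto the warp's target grid: each target voxel's world
#' point is displaced into source space, the source mask is sampled there with
#' trilinear interpolation (points outside the source grid read 0), and the
#' result is re-binarised at `interpolation_threshold`.
#'
#' @param mask A [binary_mask()] on the source grid.
#' @param warp A [warp_field()] whose grid defines the output.
#' @param interpolation_threshold Fraction in (0, 1]; a target voxel is set
#'   when the interpolated source value is `>=` this (default 0.5).
#' @return A [binary_mask()] on the warp target grid.
#' @export
apply_warp_to_mask <- function(mask, warp, interpolation_threshold = 0.5) {
  stopifnot(is_binary_mask(mask), inherits(warp, "warp_field"))
  assert_scalar_number(interpolation_threshold, "interpolation_threshold",
                       lower = 1e-12, upper = 1)
  dims <- warp$dims
  ijk <- all_voxel_indices(dims)
  world <- cbind(ijk, 1) %*% t(warp$affine)
  disp <- matrix(warp$displacement, ncol = 3L)
  src_world <- world[, 1:3, drop = FALSE] + disp
  src_vox <- cbind(src_world, 1) %*% t(solve(mask$affine))
  sampled <- trilinear_sample(mask$values, src_vox[, 1:3, drop = FALSE])
  out <- array((sampled >= interpolation_threshold) + 0, dims)
  binary_mask(out, affine = warp$affine)
}

#' Mirror a mask across an axis-aligned world plane
#'
#' Reflects the mask across the plane `axis = coordinate` (world mm) and
#' resamples onto the same grid with the trilinear + 0.5 threshold rule. Used
#' for left-right symmetry QC and the "mirror from contralateral" protocol
#' revision.
#'
#' @param mask A [binary_mask()].
#' @param axis Axis index (1, 2 or 3) the plane is perpendicular to.
#' @param coordinate World-mm coordinate of the plane along `axis`.
#' @param interpolation_threshold Re-binarisation threshold (default 0.5).
#' @return A [binary_mask()] on the same grid.
#' @export
mirror_mask <- function(mask, axis, coordinate, interpolation_threshold = 0.5) {
  stopifnot(is_binary_mask(mask), axis %in% 1:3)
  dims <- dim(mask$values)
  ijk <- all_voxel_indices(dims)
  world <- cbind(ijk, 1) %*% t(mask$affine)
  rng <- range(world[, axis])
  if (coordinate < rng[1L] - 1e-9 || coordinate > rng[2L] + 1e-9) {
    abort(sprintf("mirror plane %g lies outside the grid extent [%g, %g] on axis %d",
                  coordinate, rng[1L], rng[2L], axis))
  }
  refl <- world[, 1:3, drop = FALSE]
  refl[, axis] <- 2 * coordinate - refl[, axis]
  src_vox <- cbind(refl, 1) %*% t(solve(mask$affine))
  sampled <- trilinear_sample(mask$values, src_vox[, 1:3, drop = FALSE])
  out <- array((sampled >= interpolation_threshold) + 0, dims)
  binary_mask(out, affine = mask$affine)
}
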