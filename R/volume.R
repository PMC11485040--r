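#' Volumetric grid with world-space geometry
#'
#' A `volume_grid` couples a 3-D array of scalars with a voxel-to-world affine
#' (4x4, homogeneous, acting on 0-based voxel indices) so that every volumetric
#' quantity in the pipeline — path distributions, FA/MD maps, ROI masks —
#' carries its geometry. `binary_mask` is a `volume_grid` whose values are
#' restricted to \{0, 1\}.
#'
#' @param values 3-D numeric array of finite values.
#' @param affine 4x4 voxel-index-to-world-mm matrix; defaults to a diagonal
#'   affine built from `voxel_size` with origin at voxel (0, 0, 0).
#' @param voxel_size length-3 positive voxel edge lengths in mm (ignored when
#'   `affine` is supplied; then derived from the affine columns).
#' @return A `volume_grid` object (list with `values`, `affine`, `voxel_size`).
#' @examples
#' v <- volume_grid(array(1, c(4, 4, 4)))
#' v$voxel_size
#' @export
volume_grid <- function(values, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite value at voxel index (%d, %d, %d) [0-based]",
                  bad[1L] - 1L, bad[2L] - 1L, bad[3L] - 1L))
  }
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    abort("`affine` must be an invertible 4x4 matrix")
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(
    list(values = values, affine = affine, voxel_size = voxel_size),
    class = "volume_grid"
  )
}

#' @rdname volume_grid
#' @export
binary_mask <- function(values, affine = NULL, voxel_size = c(1, 1, 1)) {
  v <- volume_grid(values, affine, voxel_size)
  if (!all(v$values %in% c(0, 1))) abort("mask values must be 0 or 1")
  storage.mode(v$values) <- "double"
  class(v) <- c("binary_mask", class(v))
  v
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm; values in [%.4g, %.4g]\n",
              class(x)[1L], paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size, digits = 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_binary_mask <- function(x) inherits(x, "binary_mask")

as_binary_mask <- function(v) {
  if (is_binary_mask(v)) return(v)
  binary_mask(v$values, v$affine)
}

# Two grids are "the same" when shapes and affines agree to float tolerance.
same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) && max(abs(a$affine - b$affine)) < tol
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) abort(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

n_active <- function(mask) sum(mask$values != 0)

# World coordinates (n x 3 mm) of 0-based voxel indices, and the inverse.
voxel_to_world <- function(v, ijk) {
  p <- cbind(ijk, 1) %*% t(v$affine)
  p[, 1:3, drop = FALSE]
}

world_to_voxel <- function(v, xyz) {
  p <- cbind(xyz, 1) %*% t(solve(v$affine))
  p[, 1:3, drop = FALSE]
}

#' Read and write single 3-D NIfTI volumes
#'
#' Thin wrappers over \pkg{RNifti} that enforce the package's contract: a file
#' holds exactly one 3-D volume, all values are finite, and integer data
#' round-trip bit-exactly. Gzipped files (`.nii.gz`) are handled transparently.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param v A [volume_grid()] (or [binary_mask()]) to write.
#' @return `read_volume()` returns a [volume_grid()]; a volume whose values are
#'   all 0/1 is promoted to [binary_mask()]. `write_volume()` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a)) # drop NIfTI header attributes
  storage.mode(a) <- "double"
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) a <- array(a, dim(a)[1:3])
  if (length(dim(a)) != 3L) {
    abort(sprintf("expected a 3-D volume, got %d-D: %s", length(dim(a)), path))
  }
  if (!all(is.finite(a))) {
    bad <- which(!is.finite(a), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite voxel at index (%d, %d, %d) [0-based] in %s",
                  bad[1L] - 1L, bad[2L] - 1L, bad[3L] - 1L, path))
  }
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  v <- volume_grid(a, affine = aff)
  if (all(a %in% c(0, 1))) v <- as_binary_mask(v)
  v
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  int_like <- all(v$values == round(v$values)) && max(abs(v$values)) < 2^31
  dt <- if (int_like) "int32" else "double"
  img <- RNifti::asNifti(v$values, datatype = dt)
  # sform only: the quaternion form cannot carry anisotropic scalings exactly
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Downsample a volume to a coarser grid
#'
#' Decimates by an integer factor per axis, either block-averaging scalars
#' (`rule = "mean"`) or activating a coarse voxel when any fine voxel in its
#' block is active (`rule = "any"`, the conservative choice for visitation
#' counting with masks). The affine is updated so the world extent of the
#' volume is preserved: coarse voxel centres sit at the centres of their fine
#' blocks.
#'
#' @param v A [volume_grid()] or [binary_mask()].
#' @param target_voxel_mm Target voxel size (scalar or length 3); must be an
#'   integer multiple of the source voxel size on every axis.
#' @param rule Aggregation rule, `"mean"` (default) or `"any"`.
#' @return A [volume_grid()] (or [binary_mask()] for `rule = "any"` on a mask).
#' @export
downsample_volume <- function(v, target_voxel_mm, rule = c("mean", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(v, "volume_grid"))
  target_voxel_mm <- rep_len(as.numeric(target_voxel_mm), 3L)
  f <- target_voxel_mm / v$voxel_size
  if (any(f < 1 - 1e-9)) abort("target voxel size must be >= source voxel size")
  fi <- round(f)
  if (max(abs(f - fi)) > 1e-6) {
    abort(sprintf("non-integer decimation factor (%s); only integer factors are supported",
                  paste(format(f, digits = 4), collapse = ", ")))
  }
  fi <- as.integer(pmax(fi, 1L))
  dims <- dim(v$values)
  if (any(dims %% fi != 0L)) {
    abort(sprintf("grid shape (%s) is not divisible by decimation factor (%s)",
                  paste(dims, collapse = "x"), paste(fi, collapse = "x")))
  }
  if (all(fi == 1L)) return(v)
  nd <- dims %/% fi
  a6 <- array(v$values, c(fi[1L], nd[1L], fi[2L], nd[2L], fi[3L], nd[3L]))
  agg <- if (rule == "mean") {
    apply(a6, c(2L, 4L, 6L), mean)
  } else {
    (apply(a6, c(2L, 4L, 6L), max) > 0) + 0
  }
  new_aff <- v$affine
  new_aff[1:3, 1:3] <- v$affine[1:3, 1:3] %*% diag(fi)
  new_aff[1:3, 4L] <- (v$affine %*% c((fi - 1) / 2, 1))[1:3]
  out <- volume_grid(agg, affine = new_aff)
  if (rule == "any" && is_binary_mask(v)) out <- as_binary_mask(out)
  out
}

# Map each fine-grid linear voxel index to its coarse-grid linear index after
# integer decimation by `fi` (both 1-based, column-major).
fine_to_coarse_index <- function(dims, fi) {
  ijk <- all_voxel_indices(dims)
  cijk <- cbind(ijk[, 1L] %/% fi[1L], ijk[, 2L] %/% fi[2L], ijk[, 3L] %/% fi[3L])
  vox_linear_index(cijk, dims %/% fi)
}
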