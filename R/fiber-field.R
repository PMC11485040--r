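#' Multi-fibre orientation fields
#'
#' Per-voxel sets of up to three unit fibre orientations with volume fractions,
#' the input a probabilistic tracker consumes (the shape of BEDPOSTX output,
#' without posterior uncertainty). Orientations are stored as a 5-D array
#' `(X, Y, Z, component, fibre)` and fractions as `(X, Y, Z, fibre)`.
#'
#' @param orientations 5-D array `(X, Y, Z, 3, n_fibres <= 3)`; each vector
#'   with positive fraction must be unit-norm (orientations are sign-invariant).
#' @param fractions 4-D array `(X, Y, Z, n_fibres)`; non-negative, per-voxel
#'   sum at most 1.
#' @param affine 4x4 voxel-to-world affine of the grid.
#' @return A `fiber_orientation_field` object.
#' @export
fiber_orientation_field <- function(orientations, fractions, affine = NULL) {
  do <- dim(orientations); df <- dim(fractions)
  if (length(do) != 5L || do[4L] != 3L || do[5L] > 3L) {
    abort("`orientations` must be (X, Y, Z, 3, n_fibres <= 3)")
  }
  if (length(df) != 4L || !all(df == do[c(1:3, 5L)])) {
    abort("`fractions` must be (X, Y, Z, n_fibres) matching `orientations`")
  }
  if (any(fractions < 0)) abort("volume fractions must be non-negative")
  fsum <- apply(fractions, 1:3, sum)
  if (any(fsum > 1 + 1e-9)) abort("per-voxel volume fractions must sum to at most 1")
  nf <- do[5L]
  for (k in seq_len(nf)) {
    frk <- fractions[, , , k]
    nrm <- sqrt(orientations[, , , 1L, k]^2 + orientations[, , , 2L, k]^2 +
                  orientations[, , , 3L, k]^2)
    active <- frk > 0
    if (any(abs(nrm[active] - 1) > 1e-6)) {
      abort(sprintf("fibre %d has non-unit orientations where fraction > 0", k))
    }
  }
  dims <- do[1:3]
  if (is.null(affine)) affine <- diag(4)
  structure(
    list(orientations = orientations, fractions = fractions,
         affine = unname(as.matrix(affine)), dims = dims),
    class = "fiber_orientation_field"
  )
}

#' @export
print.fiber_orientation_field <- function(x, ...) {
  fsum <- apply(x$fractions, 1:3, sum)
  cat(sprintf("<fiber_orientation_field> %s, %d fibre slots, %d voxels with fibres\n",
              paste(x$dims, collapse = "x"), dim(x$fractions)[4L], sum(fsum > 0)))
  invisible(x)
}

#' Write/read a fibre field as per-fibre NIfTI volumes
#'
#' One vector image (`dyads<k>`) plus one fraction volume (`mean_f<k>samples`)
#' per fibre, mirroring the on-disk layout trackers expect.
#' @param field A [fiber_orientation_field()].
#' @param dir Output directory.
#' @return `read_fiber_field()` returns a [fiber_orientation_field()].
#' @export
write_fiber_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(field$fractions)[4L]
  for (k in seq_len(nf)) {
    w <- warp_field(field$orientations[, , , , k, drop = TRUE] |>
                      array(c(field$dims, 3L)), affine = field$affine)
    write_warp(w, file.path(dir, sprintf("dyads%d.nii.gz", k)))
    write_volume(volume_grid(array(field$fractions[, , , k], field$dims),
                             affine = field$affine),
                 file.path(dir, sprintf("mean_f%dsamples.nii.gz", k)))
  }
  invisible(dir)
}

#' @rdname write_fiber_field
#' @export
read_fiber_field <- function(dir) {
  ks <- 1L
  while (file.exists(file.path(dir, sprintf("dyads%d.nii.gz", ks + 1L)))) ks <- ks + 1L
  d1 <- read_warp(file.path(dir, "dyads1.nii.gz"))
  dims <- d1$dims
  ori <- array(0, c(dims, 3L, ks)); fr <- array(0, c(dims, ks))
  for (k in seq_len(ks)) {
    dk <- read_warp(file.path(dir, sprintf("dyads%d.nii.gz", k)))
    fk <- read_volume(file.path(dir, sprintf("mean_f%dsamples.nii.gz", k)))
    ori[, , , , k] <- dk$displacement
    fr[, , , k] <- fk$values
  }
  fiber_orientation_field(ori, fr, affine = d1$affine)
}
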