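#' Vectorised tract matrix on a coarse whole-brain grid
#'
#' Downsamples each normalised path distribution to the coarse grid (block
#' average), restricts it to the in-brain coarse voxels (brain mask
#' downsampled with the any-voxel rule, matching the connectivity matrix), and
#' unwraps it in the fixed column-major voxel order — one column per tract.
#'
#' @param npds Named list of `normalised_path_distribution`s on one fine grid
#'   (names = tract abbreviations; unnamed lists use each `$tract`).
#' @param brain_mask [binary_mask()] on the fine grid.
#' @param coarse_voxel_mm Coarse voxel size (integer multiple of fine).
#' @return A `tract_matrix`: `matrix` (coarse in-brain voxels x tracts),
#'   `tracts`, and the coarse grid description.
#' @export
build_tract_matrix <- function(npds, brain_mask, coarse_voxel_mm = 2) {
  stopifnot(is.list(npds), length(npds) >= 1L)
  nms <- names(npds) %||% vapply(npds, function(x) x$tract, character(1))
  if (is.null(names(npds))) names(npds) <- nms
  if (anyDuplicated(nms)) abort("tract name collision in `npds`")
  coarse <- downsample_volume(brain_mask, coarse_voxel_mm, rule = "any")
  active <- which(coarse$values != 0)
  cols <- lapply(npds, function(npd) {
    assert_same_grid(npd$fractions, brain_mask, "distribution and brain mask")
    dv <- downsample_volume(npd$fractions, coarse_voxel_mm, rule = "mean")
    dv$values[active]
  })
  structure(list(
    matrix = do.call(cbind, cols), tracts = nms,
    coarse_dims = dim(coarse$values), coarse_affine = coarse$affine,
    coarse_cols = active
  ), class = "tract_matrix")
}

#' @export
print.tract_matrix <- function(x, ...) {
  cat(sprintf("<tract_matrix> %d coarse voxels x %d tracts (%s)\n",
              nrow(x$matrix), length(x$tracts), paste(x$tracts, collapse = ", ")))
  invisible(x)
}

# Order-pinned contraction: entry (v, t) = sum over coarse voxels j (ascending,
# long-double accumulation) of conn[v, j] * tm[j, t]. Both build_blueprint and
# the streamline oracle contract through this, so agreement is bitwise and any
# discrepancy isolates to the visitation counting.
blueprint_product <- function(conn, tmat) {
  V <- nrow(conn)
  out <- vapply(seq_len(ncol(tmat)), function(t) {
    rowSums(conn * matrix(tmat[, t], nrow = V, ncol = nrow(tmat), byrow = TRUE))
  }, numeric(V))
  matrix(out, nrow = V)
}

new_blueprint <- function(mat, tracts, excluded, normalised, row_sums = NULL) {
  rownames(mat) <- NULL
  structure(list(matrix = mat, tracts = tracts, excluded = excluded,
                 normalised = normalised, row_sums = row_sums),
            class = "connectivity_blueprint")
}

#' Build a connectivity blueprint
#'
#' The product of the (vertices x coarse voxels) whole-brain connectivity
#' matrix with the (coarse voxels x tracts) tract matrix gives the
#' (vertices x tracts) blueprint: each row is a cortical location's projection
#' profile onto the tract repertoire. Rows with zero sum (vertices the tract
#' set does not represent) are excluded rather than renormalised; remaining
#' rows are divided by their sums so each is a probability profile.
#'
#' @param conn A `visitation_matrix` (or plain vertices x voxels matrix on the
#'   same coarse frame).
#' @param tm A [build_tract_matrix()] result.
#' @param normalise Row-normalise to probability profiles (default TRUE).
#' @return A `connectivity_blueprint`: `matrix` (vertices x tracts), `tracts`,
#'   `excluded` (logical per vertex), `normalised`.
#' @export
build_blueprint <- function(conn, tm, normalise = TRUE) {
  stopifnot(inherits(tm, "tract_matrix"))
  if (inherits(conn, "visitation_matrix")) {
    if (!all(conn$coarse_dims == tm$coarse_dims) ||
        !identical(conn$coarse_cols, tm$coarse_cols)) {
      abort("connectivity and tract matrices use different coarse grids")
    }
    conn <- conn$matrix
  }
  if (ncol(conn) != nrow(tm$matrix)) {
    abort(sprintf("inner dimensions disagree: %d voxels vs %d", ncol(conn), nrow(tm$matrix)))
  }
  raw <- blueprint_product(conn, tm$matrix)
  rs <- rowSums(raw)
  excluded <- rs == 0
  if (normalise) {
    raw[!excluded, ] <- raw[!excluded, , drop = FALSE] / rs[!excluded]
  }
  new_blueprint(raw, tm$tracts, excluded, normalise, row_sums = rs)
}

#' @export
print.connectivity_blueprint <- function(x, ...) {
  cat(sprintf("<connectivity_blueprint> %d vertices x %d tracts, %d excluded%s\n",
              nrow(x$matrix), length(x$tracts), sum(x$excluded),
              if (x$normalised) ", row-stochastic" else ""))
  invisible(x)
}

#' Per-streamline blueprint oracle
#'
#' Independent construction of the blueprint that never forms the connectivity
#' matrix: it re-runs the identical (deterministic, same seed) surface-seeded
#' tracking, then accumulates each vertex's coarse-voxel visitation vector one
#' streamline at a time from the raw per-streamline visit sets, and contracts
#' against the tract matrix with the same order-pinned product. It must equal
#' [build_blueprint()] bit-for-bit on the same inputs; it exists as the
#' correctness oracle for the matrix route.
#'
#' @param field,surface,brain_mask,config As for
#'   [run_surface_seeded_tractography()].
#' @param tm A [build_tract_matrix()] result (also fixes the coarse grid).
#' @param normalise Row-normalise (default TRUE).
#' @return A `connectivity_blueprint`.
#' @export
streamline_oracle_blueprint <- function(field, surface, tm, brain_mask,
                                        config = tracking_config(),
                                        seed_jitter_mm = 1.5,
                                        normalise = TRUE) {
  stopifnot(inherits(tm, "tract_matrix"))
  coarse_mm <- sqrt(colSums(tm$coarse_affine[1:3, 1:3]^2))
  vm <- run_surface_seeded_tractography(field, surface, brain_mask,
                                        coarse_voxel_mm = coarse_mm,
                                        config = config,
                                        seed_jitter_mm = seed_jitter_mm,
                                        keep_streamline_visits = TRUE)
  if (!identical(vm$coarse_cols, tm$coarse_cols)) {
    abort("tract matrix coarse grid does not match the tracking coarse grid")
  }
  V <- n_vertices(surface)
  C <- nrow(tm$matrix)
  w <- matrix(0, nrow = V, ncol = C)
  visits <- vm$streamline_visits
  vert <- vm$vertex_of_streamline
  for (s in seq_along(visits)) {
    cv <- visits[[s]]
    if (length(cv)) w[vert[s], cv] <- w[vert[s], cv] + 1
  }
  raw <- blueprint_product(w, tm$matrix)
  rs <- rowSums(raw)
  excluded <- rs == 0
  if (normalise) raw[!excluded, ] <- raw[!excluded, , drop = FALSE] / rs[!excluded]
  new_blueprint(raw, tm$tracts, excluded, normalise, row_sums = rs)
}

assert_same_frame <- function(a, b) {
  if (!identical(a$tracts, b$tracts)) abort("blueprints use different tract frames")
  if (nrow(a$matrix) != nrow(b$matrix)) abort("blueprints use different vertex frames")
  invisible(TRUE)
}

#' Group-average connectivity blueprints
#'
#' Element-wise mean across subjects on identical vertex/tract frames; a
#' vertex excluded in some subjects is averaged over the remaining ones and
#' only excluded when excluded everywhere. Rows are renormalised after
#' averaging by default.
#'
#' @param blueprints List of `connectivity_blueprint`s on one frame.
#' @param renormalise Renormalise rows after averaging (default TRUE).
#' @return A `connectivity_blueprint`.
#' @export
group_average_blueprints <- function(blueprints, renormalise = TRUE) {
  stopifnot(length(blueprints) >= 1L)
  for (b in blueprints[-1L]) assert_same_frame(blueprints[[1L]], b)
  V <- nrow(blueprints[[1L]]$matrix)
  acc <- matrix(0, V, ncol(blueprints[[1L]]$matrix))
  nsub <- numeric(V)
  for (b in blueprints) {
    inc <- !b$excluded
    acc[inc, ] <- acc[inc, , drop = FALSE] + b$matrix[inc, , drop = FALSE]
    nsub <- nsub + inc
  }
  excluded <- nsub == 0
  acc[!excluded, ] <- acc[!excluded, , drop = FALSE] / nsub[!excluded]
  if (renormalise) {
    rs <- rowSums(acc)
    ok <- !excluded & rs > 0
    acc[ok, ] <- acc[ok, , drop = FALSE] / rs[ok]
    excluded <- excluded | (rs == 0)
  }
  new_blueprint(acc, blueprints[[1L]]$tracts, excluded,
                blueprints[[1L]]$normalised)
}

#' Exclude a vertex region from a blueprint
#'
#' Marks the region's vertices excluded so they drop out of every downstream
#' divergence computation — the mechanism for removing cortex poorly
#' represented by the tract repertoire.
#'
#' @param bp A `connectivity_blueprint`.
#' @param region_vertex_mask Logical vector (length = vertices) or integer
#'   vertex indices.
#' @return The updated `connectivity_blueprint`.
#' @export
exclude_region <- function(bp, region_vertex_mask) {
  stopifnot(inherits(bp, "connectivity_blueprint"))
  V <- nrow(bp$matrix)
  sel <- if (is.logical(region_vertex_mask)) {
    if (length(region_vertex_mask) != V) abort("region mask is not on the blueprint's vertex frame")
    region_vertex_mask
  } else {
    if (length(region_vertex_mask) && max(region_vertex_mask) > V) {
      abort("region mask is not on the blueprint's vertex frame")
    }
    seq_len(V) %in% region_vertex_mask
  }
  bp$excluded <- bp$excluded | sel
  bp
}

#' Exclude cortex poorly represented by the tract repertoire
#'
#' Marks as excluded every vertex whose total (pre-normalisation) blueprint
#' signal falls below `frac` of the median over currently included vertices.
#' Such vertices sit over cortex the tract set barely reaches (their few
#' streamlines die almost immediately), so their profiles are degenerate
#' one-hot rows that carry no positional information — the same reasoning
#' under which whole regions poorly served by a tract repertoire are dropped
#' from cross-brain comparisons.
#'
#' @param bp A `connectivity_blueprint` carrying `row_sums` (as produced by
#'   [build_blueprint()]).
#' @param frac Fraction of the median row signal below which a vertex is
#'   excluded (default 0.05).
#' @return The updated `connectivity_blueprint`.
#' @export
exclude_low_signal <- function(bp, frac = 0.05) {
  stopifnot(inherits(bp, "connectivity_blueprint"))
  if (is.null(bp$row_sums)) abort("blueprint carries no row sums")
  med <- stats::median(bp$row_sums[!bp$excluded])
  bp$excluded <- bp$excluded | bp$row_sums < frac * med
  bp
}

#' Average connectivity profile of a vertex region
#'
#' Mean of the region's non-excluded normalised rows, renormalised to sum 1 —
#' the profile used to hunt for homologues of a named region in another brain.
#'
#' @inheritParams exclude_region
#' @return Numeric tract-probability profile (sums to 1), named by tract.
#' @export
average_region_profile <- function(bp, region_vertex_mask) {
  stopifnot(inherits(bp, "connectivity_blueprint"))
  V <- nrow(bp$matrix)
  sel <- if (is.logical(region_vertex_mask)) which(region_vertex_mask) else as.integer(region_vertex_mask)
  sel <- setdiff(sel, which(bp$excluded))
  if (length(sel) == 0L) abort("region is empty after exclusions")
  prof <- colMeans(bp$matrix[sel, , drop = FALSE])
  if (sum(prof) == 0) abort("region profile is all-zero")
  prof <- prof / sum(prof)
  names(prof) <- bp$tracts
  prof
}

#' Write a blueprint as a TSV matrix plus a JSON frame manifest
#' @param bp A `connectivity_blueprint`.
#' @param path Output TSV path; manifest written alongside as `.json`.
#' @return `read_blueprint()` returns a `connectivity_blueprint`.
#' @export
write_blueprint <- function(bp, path) {
  df <- as.data.frame(bp$matrix)
  names(df) <- bp$tracts
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(tracts = bp$tracts, excluded = which(bp$excluded),
         normalised = bp$normalised, n_vertices = nrow(bp$matrix)),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  mat <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path), simplifyVector = TRUE)
  excluded <- rep(FALSE, nrow(mat))
  excluded[meta$excluded] <- TRUE
  new_blueprint(unname(mat), colnames(mat) %||% meta$tracts, excluded,
                isTRUE(meta$normalised))
}
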