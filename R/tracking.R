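#' Tracking configuration
#'
#' Parameters of the probabilistic streamline tracker. Defaults follow
#' standard XTRACT-style settings: 0.2 mm steps, an 80 degree curvature
#' threshold, at most 2000 steps per direction, subsidiary fibres considered
#' above a 1% volume fraction, and 1000 streamlines per surface vertex for
#' whole-brain seeding. `streamlines_per_seed_voxel` (volume seeding) defaults
#' to 50.
#'
#' @param step_size_mm Step length in mm (> 0).
#' @param curvature_limit_deg Maximum turn between consecutive steps, in
#'   degrees (0, 180].
#' @param max_steps Maximum steps per direction (>= 1).
#' @param min_volume_fraction Fibres with volume fraction strictly above this
#'   are candidate orientations (0 <= x < 1).
#' @param streamlines_per_seed_voxel Streamlines seeded per active seed voxel.
#' @param streamlines_per_surface_vertex Streamlines seeded per surface vertex.
#' @param seed Integer RNG seed for seed placement and orientation sampling.
#' @return A `tracking_config` object.
#' @export
tracking_config <- function(step_size_mm = 0.2, curvature_limit_deg = 80,
                            max_steps = 2000L, min_volume_fraction = 0.01,
                            streamlines_per_seed_voxel = 50L,
                            streamlines_per_surface_vertex = 1000L,
                            seed = 1L) {
  assert_scalar_number(step_size_mm, "step_size_mm", lower = 1e-9)
  assert_scalar_number(curvature_limit_deg, "curvature_limit_deg",
                       lower = 1e-9, upper = 180)
  assert_scalar_number(max_steps, "max_steps", lower = 1)
  assert_scalar_number(min_volume_fraction, "min_volume_fraction",
                       lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(streamlines_per_seed_voxel, "streamlines_per_seed_voxel", lower = 0)
  assert_scalar_number(streamlines_per_surface_vertex, "streamlines_per_surface_vertex", lower = 0)
  assert_scalar_number(seed, "seed", lower = -2^31, upper = 2^31)
  structure(list(step_size_mm = step_size_mm,
                 curvature_limit_deg = curvature_limit_deg,
                 max_steps = as.integer(max_steps),
                 min_volume_fraction = min_volume_fraction,
                 streamlines_per_seed_voxel = as.integer(streamlines_per_seed_voxel),
                 streamlines_per_surface_vertex = as.integer(streamlines_per_surface_vertex),
                 seed = as.integer(seed)),
            class = "tracking_config")
}

reason_labels <- c("left_mask", "stop", "max_steps", "curvature", "no_fibre",
                   "exclusion")

as_int_mask <- function(mask) {
  if (is.null(mask)) return(NULL)
  as.integer(mask$values != 0)
}

track_call <- function(field, brain_mask, seeds, config, waypoints = list(),
                       exclusion = NULL, stop = NULL, rng_seed = config$seed,
                       store_paths = FALSE, coarse_map = NULL,
                       count_visits = FALSE) {
  stopifnot(inherits(field, "fiber_orientation_field"))
  cpp_track(
    dims = as.integer(field$dims),
    orient = as.numeric(field$orientations),
    vf = as.numeric(field$fractions),
    inv_affine = solve(field$affine),
    brain = as.integer(brain_mask$values != 0),
    stop_mask = as_int_mask(stop),
    excl_mask = as_int_mask(exclusion),
    waypoint_masks = lapply(waypoints, as_int_mask),
    seeds = seeds,
    step_mm = config$step_size_mm,
    curvature_limit_deg = config$curvature_limit_deg,
    max_steps = config$max_steps,
    min_vf = config$min_volume_fraction,
    rng_seed = as.numeric(rng_seed) %% 2^31,
    store_paths = store_paths,
    coarse_map = coarse_map,
    count_visits = count_visits
  )
}

#' Propagate a single streamline
#'
#' Tracks both directions from `start_point` through the fibre field and
#' concatenates them. Candidate orientations at each step are the fibres of
#' the current voxel (nearest-voxel lookup) with volume fraction above the
#' configured threshold, sampled with probability proportional to fraction;
#' the sign is aligned with the previous direction and a turn beyond the
#' curvature limit terminates the streamline. Propagation also ends on leaving
#' the brain mask, entering the stop mask, or exhausting `max_steps`. A voxel
#' with no admissible fibre terminates with reason `"no_fibre"` (not an
#' error).
#'
#' @param field A [fiber_orientation_field()].
#' @param start_point Length-3 world-mm start position (inside the brain mask).
#' @param config A [tracking_config()].
#' @param brain_mask [binary_mask()] bounding propagation.
#' @param stop_mask Optional [binary_mask()] terminating streamlines.
#' @return A `streamline`: list with `path` (n x 3 mm polyline), `termination`
#'   (named reasons for the forward/backward directions) and `visited`
#'   (1-based linear voxel indices, unique).
#' @export
propagate_streamline <- function(field, start_point, config = tracking_config(),
                                 brain_mask, stop_mask = NULL) {
  seeds <- matrix(as.numeric(start_point), nrow = 1L)
  res <- track_call(field, brain_mask, seeds, config, stop = stop_mask,
                    store_paths = TRUE)
  structure(list(
    path = res$paths[[1L]],
    termination = c(forward = reason_labels[res$reason_fwd[1L] + 1L],
                    backward = reason_labels[res$reason_bwd[1L] + 1L]),
    visited = NULL
  ), class = "streamline")
}

#' Protocol-constrained probabilistic tractography
#'
#' Seeds `streamlines_per_seed_voxel` streamlines uniformly inside every
#' active seed voxel. A streamline is *valid* iff it intersects every waypoint
#' mask (and the target, when present) and never touches the exclusion mask;
#' only valid streamlines contribute visitation counts, each incrementing a
#' voxel at most once. Deterministic given the config seed.
#'
#' @param field A [fiber_orientation_field()].
#' @param protocol A [protocol_rois()] or [tract_protocol()].
#' @param brain_mask [binary_mask()] on the field grid.
#' @param config A [tracking_config()].
#' @return A `path_distribution`: visitation-count [volume_grid()] plus
#'   `n_valid`, `n_seeded`, the config and seed, and the tract abbreviation
#'   when a [tract_protocol()] was given.
#' @export
run_protocol_tractography <- function(field, protocol, brain_mask,
                                      config = tracking_config()) {
  tract <- NA_character_
  if (inherits(protocol, "tract_protocol")) {
    tract <- protocol$abbreviation
    protocol <- protocol$rois
  }
  stopifnot(inherits(protocol, "protocol_rois"))
  if (!all(dim(brain_mask$values) == field$dims) ||
      max(abs(brain_mask$affine - field$affine)) > 1e-6) {
    abort("brain mask and fibre field are not on the same grid")
  }
  assert_same_grid(brain_mask, protocol$seed, "seed mask and brain mask")
  seed_idx <- which(protocol$seed$values != 0) - 1L
  if (length(seed_idx) == 0L) abort("empty seed mask")
  dims <- field$dims
  ijk <- cbind(seed_idx %% dims[1L],
               (seed_idx %/% dims[1L]) %% dims[2L],
               seed_idx %/% (dims[1L] * dims[2L]))
  K <- config$streamlines_per_seed_voxel
  if (K == 0L) {
    return(structure(list(
      counts = volume_grid(array(0, dims), affine = field$affine),
      n_valid = 0L, n_seeded = 0L, tract = tract, config = config,
      seed = config$seed
    ), class = "path_distribution"))
  }
  ijk_rep <- ijk[rep(seq_len(nrow(ijk)), each = K), , drop = FALSE]
  jitter <- with_seed(derive_seed(config$seed, "protocol-seeds"),
                      matrix(stats::runif(length(ijk_rep), -0.5, 0.5), ncol = 3L))
  seeds <- voxel_to_world(brain_mask, ijk_rep + jitter)

  ways <- unname(protocol$waypoints)
  if (!is.null(protocol$target)) ways <- c(ways, list(protocol$target))
  res <- track_call(field, brain_mask, seeds, config, waypoints = ways,
                    exclusion = protocol$exclusion, stop = protocol$stop,
                    rng_seed = derive_seed(config$seed, "protocol-track"),
                    count_visits = TRUE)
  counts <- array(as.numeric(res$counts), dims)
  structure(list(
    counts = volume_grid(counts, affine = field$affine),
    n_valid = res$n_valid, n_seeded = res$n_seeded,
    tract = tract, config = config, seed = config$seed
  ), class = "path_distribution")
}

#' @export
print.path_distribution <- function(x, ...) {
  cat(sprintf("<path_distribution>%s %d/%d valid streamlines, %d voxels visited\n",
              if (is.na(x$tract)) "" else paste0(" [", x$tract, "]"),
              x$n_valid, x$n_seeded, sum(x$counts$values > 0)))
  invisible(x)
}

#' Surface-seeded whole-brain connectivity matrix
#'
#' Seeds `streamlines_per_surface_vertex` streamlines at every surface vertex
#' and counts, per vertex, visitations of coarse whole-brain voxels (the brain
#' mask down-sampled to `coarse_voxel_mm`, default 2 mm), each streamline
#' incrementing a coarse voxel at most once. Rows with zero total — vertices
#' outside the brain mask or with no supported fibre — are flagged, not
#' errors.
#'
#' @param field A [fiber_orientation_field()].
#' @param surface A [surface_mesh()] with vertices inside the brain mask.
#' @param brain_mask [binary_mask()] on the field grid.
#' @param coarse_voxel_mm Coarse grid voxel size (integer multiple of the fine
#'   voxel size).
#' @param config A [tracking_config()].
#' @param seed_jitter_mm Radius of the ball over which each vertex's seeds are
#'   distributed (uniform). A vertex stands for a cortical patch of roughly
#'   half the vertex spacing, so its streamlines sample that patch rather
#'   than a single point (default 1.5 mm).
#' @param keep_streamline_visits Keep per-streamline coarse-visit sets (needed
#'   by the streamline blueprint oracle); memory scales with streamlines.
#' @return A `visitation_matrix`: `matrix` (vertices x coarse in-brain
#'   voxels), the coarse grid description (`coarse_dims`, `coarse_affine`,
#'   `coarse_cols` = 1-based linear indices of in-brain coarse voxels),
#'   `flagged` rows, and optionally the per-streamline visit sets.
#' @export
run_surface_seeded_tractography <- function(field, surface, brain_mask,
                                            coarse_voxel_mm = 2,
                                            config = tracking_config(),
                                            seed_jitter_mm = 1.5,
                                            keep_streamline_visits = FALSE) {
  stopifnot(inherits(surface, "surface_mesh"))
  coarse <- downsample_volume(brain_mask, coarse_voxel_mm, rule = "any")
  cdims <- dim(coarse$values)
  active <- which(coarse$values != 0)
  col_of <- integer(prod(cdims))
  col_of[active] <- seq_along(active)
  fi <- as.integer(round(coarse$voxel_size / brain_mask$voxel_size))
  cmap <- col_of[fine_to_coarse_index(dim(brain_mask$values), fi)]

  V <- n_vertices(surface)
  K <- config$streamlines_per_surface_vertex
  C <- length(active)
  vox_at_vertex <- round(world_to_voxel(brain_mask, surface$vertices))
  dims <- dim(brain_mask$values)
  in_grid <- apply(vox_at_vertex >= 0 & sweep(vox_at_vertex, 2L, dims, "<"), 1L, all)
  in_brain <- rep(FALSE, V)
  in_brain[in_grid] <- brain_mask$values[vox_linear_index(
    vox_at_vertex[in_grid, , drop = FALSE], dims)] != 0

  conn <- matrix(0, nrow = V, ncol = C)
  visits <- NULL
  vertex_of <- integer(0)
  if (K > 0L && V > 0L) {
    seeds <- surface$vertices[rep(seq_len(V), each = K), , drop = FALSE]
    vertex_of <- rep(seq_len(V), each = K)
    if (seed_jitter_mm > 0) {
      # uniform in a ball: rejection-free via radius ~ U^(1/3)
      seeds <- seeds + with_seed(derive_seed(config$seed, "surface-jitter"), {
        dir <- matrix(stats::rnorm(3L * nrow(seeds)), ncol = 3L)
        dir <- dir / sqrt(rowSums(dir^2))
        dir * (seed_jitter_mm * stats::runif(nrow(seeds))^(1 / 3))
      })
    }
    res <- track_call(field, brain_mask, seeds, config,
                      rng_seed = derive_seed(config$seed, "surface-track"),
                      coarse_map = as.integer(cmap))
    lens <- lengths(res$coarse_visits)
    ii <- rep.int(vertex_of, lens)
    jj <- unlist(res$coarse_visits, use.names = FALSE)
    if (length(jj)) {
      tab <- tabulate((jj - 1L) * V + ii, nbins = V * C)
      conn <- matrix(tab, nrow = V, ncol = C)
    }
    if (keep_streamline_visits) visits <- res$coarse_visits
  }
  flagged <- rowSums(conn) == 0 | !in_brain
  structure(list(
    matrix = conn, coarse_dims = cdims, coarse_affine = coarse$affine,
    coarse_cols = active, flagged = flagged, in_brain = in_brain,
    config = config, seed = config$seed,
    streamline_visits = visits,
    vertex_of_streamline = if (keep_streamline_visits) vertex_of else NULL
  ), class = "visitation_matrix")
}

#' @export
print.visitation_matrix <- function(x, ...) {
  cat(sprintf("<visitation_matrix> %d vertices x %d coarse voxels, %d flagged rows\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$flagged)))
  invisible(x)
}

#' Write a path distribution as NIfTI counts plus a JSON sidecar
#' @param pd A `path_distribution`.
#' @param path Output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_path_distribution <- function(pd, path) {
  write_volume(pd$counts, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(n_valid = pd$n_valid, n_seeded = pd$n_seeded, tract = pd$tract,
         config = unclass(pd$config), seed = pd$seed),
    side, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_path_distribution
#' @export
read_path_distribution <- function(path) {
  counts <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side)
  structure(list(
    counts = volume_grid(counts$values + 0, affine = counts$affine),
    n_valid = meta$n_valid, n_seeded = meta$n_seeded,
    tract = meta$tract %||% NA_character_,
    config = do.call(tracking_config, meta$config), seed = meta$seed
  ), class = "path_distribution")
}
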