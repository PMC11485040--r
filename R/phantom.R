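#' Specify a synthetic phantom brain
#'
#' A phantom brain is a fully known test object: an ellipsoidal brain mask, a
#' set of tube-shaped tracts following cubic Bezier curves whose tangents
#' define the fibre-orientation field, FA/MD maps, a cortical-shell surface
#' mesh (the WGB analogue) with a parcellation and a ground-truth "myelin"
#' scalar map, and a matching tractography protocol per tract. Two hemispheres
#' share a sagittal midline plane so bilateral tracts, commissural tracts and
#' symmetry QC are all exercisable.
#'
#' Tubes meet the cortical shell radially at anchor points. Association-type
#' tracts are U-fibres whose two ends lie inside one surface parcel;
#' commissural tracts share one anchor per hemisphere with a U-fibre (their
#' fibre fractions mix in the shared corridor) and end recessed below the
#' cortex. This attachment pattern is what makes blueprint rows
#' parcel-distinctive: the two ends of a tract are indistinguishable by
#' connectivity alone, so the U-fibres keep that ambiguity inside a single
#' parcel while the shared corridors lateralise the commissures.
#'
#' @param grid_shape Grid shape in voxels (default 40 x 48 x 40).
#' @param voxel_mm Isotropic voxel size in mm (default 1).
#' @param tracts Tract blueprint table, see [default_tract_blueprints()].
#' @param brain_semiaxes Ellipsoid semi-axes of the brain mask in mm.
#' @param shell_scale Cortical shell as a fraction of the brain ellipsoid.
#' @param anchor_latitude Left-right component of anchor directions (0-1).
#' @param anchor_angle_offset_deg Rotation of anchor points within their
#'   sectors; the parcellation frame itself never rotates, so twin brains with
#'   different offsets keep vertex-parcel correspondence.
#' @param anchor_pair_half_angle_deg Half the angular separation of the two
#'   anchors a parcel hosts; small values keep endpoint catchment well inside
#'   the parcel.
#' @param depth_scale Multiplier on each tract's arc depth (the `depth` column
#'   of the tract table: Bezier control points sit at `depth * depth_scale` of
#'   the way from each tube tip toward the brain centre, so larger values arc
#'   deeper through the interior).
#' @param tube_radius Tract tube radius in mm (ground-truth mask extent).
#' @param field_margin Extra fibre-field support beyond the tube radius (mm),
#'   so streamlines seeded across the full tube cross-section stay supported.
#' @param end_offset_mm Tangential separation of coincident tract endpoints at
#'   a shared anchor (mm).
#' @param subdivisions Icosphere subdivision level for the surface
#'   (3 gives 642 vertices, the default desk scale).
#' @param n_parcels Number of surface parcels (hemisphere x angular parcels,
#'   two anchor sectors per parcel; must be even and >= 6 for the default
#'   tract repertoire).
#' @param seed_roi_radius,waypoint_radius Protocol ROI ball radii (mm).
#' @param end_roi_inset_mm Extra arc distance (beyond the tract's shared
#'   cortical stalk) from each tube tip to the seed/target ball centres:
#'   protocol end-ROIs sit in the tract-unique segment, past the stalk
#'   corridor where tracts terminating at the same anchor interdigitate.
#' @param noise Relative Gaussian noise level on FA/MD/myelin, truncated to
#'   valid ranges.
#' @param seed Integer RNG seed; generation is a pure function of (spec, seed).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(40L, 48L, 40L),
                         voxel_mm = 1,
                         tracts = default_tract_blueprints(),
                         brain_semiaxes = c(16, 20, 16),
                         shell_scale = 0.78,
                         anchor_latitude = 0.45,
                         anchor_angle_offset_deg = 0,
                         anchor_pair_half_angle_deg = 18,
                         depth_scale = 1,
                         tube_radius = 2.5,
                         field_margin = 1,
                         end_offset_mm = 0,
                         subdivisions = 3L,
                         n_parcels = 8L,
                         seed_roi_radius = 3,
                         waypoint_radius = 3,
                         end_roi_inset_mm = 2.5,
                         noise = 0.02,
                         seed = 42L) {
  assert_scalar_number(voxel_mm, "voxel_mm", lower = 1e-6)
  assert_scalar_number(tube_radius, "tube_radius", lower = voxel_mm)
  assert_scalar_number(noise, "noise", lower = 0, upper = 1)
  if (n_parcels < 2L || n_parcels %% 2L != 0L) {
    abort("`n_parcels` must be an even number >= 2 (hemisphere x sectors)")
  }
  max_sector <- max(as.integer(sub("^[LR]", "", c(tracts$from, tracts$to))))
  if (n_parcels < max_sector) {
    abort(sprintf("tract repertoire uses anchor sector %d; need n_parcels >= %d",
                  max_sector, max_sector))
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
         tracts = tracts, brain_semiaxes = brain_semiaxes,
         shell_scale = shell_scale, anchor_latitude = anchor_latitude,
         anchor_angle_offset_deg = anchor_angle_offset_deg,
         anchor_pair_half_angle_deg = anchor_pair_half_angle_deg,
         depth_scale = depth_scale, tube_radius = tube_radius,
         field_margin = field_margin, end_offset_mm = end_offset_mm,
         subdivisions = as.integer(subdivisions), n_parcels = as.integer(n_parcels),
         seed_roi_radius = seed_roi_radius, waypoint_radius = waypoint_radius,
         end_roi_inset_mm = end_roi_inset_mm,
         noise = noise, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom tract repertoire
#'
#' Six tracts mirroring the field's bilateral/commissural split: two bilateral
#' association-type U-fibres (left/right pairs, both ends in one parcel, like
#' a bundle arcing under a gyrus) plus two commissural tubes that cross the
#' midline and share one anchor with a U-fibre on each side. Endpoints are
#' anchor sectors named `L1..L8`, `R1..R8`; each surface parcel spans two
#' adjacent anchor sectors, so a U-fibre's two endpoint zones lie in a single
#' parcel while the commissural attachments inherit lateralised company from
#' the U-fibre sharing their anchor.
#'
#' @return A tibble with columns `name`, `abbreviation`, `category`,
#'   `hemisphere`, `from`, `to`.
#' @export
default_tract_blueprints <- function() {
  # `depth` sets how far each curve's control points sit from tip toward the
  # brain centre: tubes leave the cortex radially and arc through the interior,
  # commissures diving deeper than association bundles.
  tibble::tribble(
    ~name,                              ~abbreviation, ~category,      ~hemisphere, ~from, ~to, ~depth, ~tip_recess_mm,
    "phantom arcuate fasciculus (L)",      "paf_l",    "association",  "left",      "L1",  "L2", 0.45, 0,
    "phantom arcuate fasciculus (R)",      "paf_r",    "association",  "right",     "R1",  "R2", 0.45, 0,
    "phantom longitudinal fasciculus (L)", "plf_l",    "association",  "left",      "L5",  "L6", 0.45, 0,
    "phantom longitudinal fasciculus (R)", "plf_r",    "association",  "right",     "R5",  "R6", 0.45, 0,
    "phantom anterior commissure",         "pac",      "commissural",  "none",      "L2",  "R2", 0.60, 2,
    "phantom forceps",                     "pfm",      "commissural",  "none",      "L6",  "R6", 0.60, 2
  )
}

# --- geometry helpers --------------------------------------------------------

# Cubic Bezier: tangents at the ends point along (p1 - p0) / (p3 - p2), which
# the phantom uses to make tube tips meet the cortical shell radially.
bezier_point <- function(t, p0, p1, p2, p3) {
  outer((1 - t)^3, p0) + outer(3 * t * (1 - t)^2, p1) +
    outer(3 * t^2 * (1 - t), p2) + outer(t^3, p3)
}

bezier_tangent <- function(t, p0, p1, p2, p3) {
  d <- outer(3 * (1 - t)^2, p1 - p0) + outer(6 * t * (1 - t), p2 - p1) +
    outer(3 * t^2, p3 - p2)
  d / sqrt(rowSums(d^2))
}

# Anchor unit directions and shell points. Each parcel hosts a pair of
# anchors placed symmetrically about its angular centre, well inside the
# parcel so endpoint catchment zones stay within their parcel. The
# parcellation frame (parcel boundaries) is fixed; only anchor points honour
# the angular offset.
phantom_anchors <- function(spec, center) {
  n_sec <- spec$n_parcels
  n_par <- n_sec %/% 2L
  par_centers <- -pi + (rep(seq_len(n_par), each = 2L) - 0.5) * (2 * pi / n_par)
  half <- spec$anchor_pair_half_angle_deg * pi / 180
  sec_centers <- par_centers + rep(c(-half, half), n_par) +
    spec$anchor_angle_offset_deg * pi / 180
  axes_shell <- spec$shell_scale * spec$brain_semiaxes
  lat <- spec$anchor_latitude
  ryz <- sqrt(1 - lat^2)
  out <- list()
  for (hemi in c("L", "R")) {
    sx <- if (hemi == "L") -lat else lat
    for (s in seq_len(n_sec)) {
      u <- c(sx, ryz * cos(sec_centers[s]), ryz * sin(sec_centers[s]))
      out[[paste0(hemi, s)]] <- list(
        unit = u,
        point = center + u * axes_shell,
        tangent = c(0, -sin(sec_centers[s]), cos(sec_centers[s]))
      )
    }
  }
  out
}

# Per-anchor slot offsets so two tracts sharing an anchor end a little apart.
# Slots are ordered by the hemisphere-stripped abbreviation so mirrored
# anchors assign mirrored offsets (keeps the phantom left-right symmetric).
anchor_slots <- function(tracts) {
  ends <- rbind(
    data.frame(tract = seq_len(nrow(tracts)), end = "from", anchor = tracts$from),
    data.frame(tract = seq_len(nrow(tracts)), end = "to", anchor = tracts$to)
  )
  key <- sub("_[lr]$", "", tracts$abbreviation[ends$tract])
  ord <- order(ends$anchor, key)
  ends <- ends[ord, ]
  ends$slot <- stats::ave(seq_len(nrow(ends)), ends$anchor, FUN = seq_along)
  ends$n_slots <- stats::ave(seq_len(nrow(ends)), ends$anchor, FUN = length)
  ends
}

# Parcel label per unit-sphere direction: hemisphere x angular parcel in the
# fixed (unrotated) frame, labels 1..n_parcels (left hemisphere first). Each
# parcel spans two adjacent anchor sectors.
parcel_of_unit <- function(u, n_parcels) {
  n_par <- n_parcels %/% 2L
  ang <- atan2(u[, 3L], u[, 2L])
  parc <- pmin(1L + as.integer(floor((ang + pi) / (2 * pi / n_par))), n_par)
  ifelse(u[, 1L] > 0, n_par + parc, parc)
}

ball_mask_array <- function(world, dims, center_pt, radius) {
  d2 <- (world[, 1L] - center_pt[1L])^2 + (world[, 2L] - center_pt[2L])^2 +
    (world[, 3L] - center_pt[3L])^2
  array((d2 <= radius^2) + 0, dims)
}

# Min distance (and argmin curve parameter index) from points to a sampled
# polyline, computed blockwise to bound memory.
min_dist_to_samples <- function(pts, samples) {
  n <- nrow(pts); m <- nrow(samples)
  dmin <- rep(Inf, n); imin <- rep(1L, n)
  block <- max(1L, floor(2e6 / m))
  s2 <- rowSums(samples^2)
  for (start in seq(1L, n, by = block)) {
    ii <- start:min(start + block - 1L, n)
    d2 <- matrix(rowSums(pts[ii, , drop = FALSE]^2), length(ii), m) +
      matrix(s2, length(ii), m, byrow = TRUE) -
      2 * pts[ii, , drop = FALSE] %*% t(samples)
    j <- max.col(-d2, ties.method = "first")
    dmin[ii] <- sqrt(pmax(d2[cbind(seq_along(ii), j)], 0))
    imin[ii] <- j
  }
  list(dist = dmin, idx = imin)
}

# --- main generator ----------------------------------------------------------

#' Generate a phantom brain from a specification
#'
#' Deterministic given `(spec, spec$seed)`. Along each tract tube the dominant
#' fibre orientation is the curve tangent; where tubes cross, a voxel carries
#' both orientations with volume fractions proportional to tube membership.
#' FA is high (0.7 +- noise) inside tubes and low (0.2 +- noise) elsewhere in
#' the brain. Each tract gets a protocol with seed/target balls at the curve
#' endpoints, a mid-curve waypoint ball, and an off-tract exclusion slab.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_brain` object: brain mask, fibre field, FA/MD maps,
#'   surface mesh (with `parcel` and `myelin` scalars), ground-truth tract
#'   masks, curves, and a protocol set.
#' @export
make_phantom_brain <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  vox <- spec$voxel_mm
  affine <- diag(c(vox, vox, vox, 1))
  center <- (dims - 1) / 2 * vox
  nvox <- prod(dims)

  ijk <- all_voxel_indices(dims)
  world <- ijk * vox
  rel <- sweep(world, 2L, center)

  inside_brain <- rowSums(sweep(rel, 2L, spec$brain_semiaxes, "/")^2) <= 1
  brain_mask <- binary_mask(array(inside_brain + 0, dims), affine = affine)

  anchors <- phantom_anchors(spec, center)
  slots <- anchor_slots(spec$tracts)
  r_field <- spec$tube_radius + spec$field_margin

  end_point <- function(tract_row, which_end) {
    a <- if (which_end == "from") spec$tracts$from[tract_row] else spec$tracts$to[tract_row]
    sl <- slots[slots$tract == tract_row & slots$end == which_end, ]
    off <- (sl$slot - (sl$n_slots + 1) / 2) * 2 * spec$end_offset_mm
    p <- anchors[[a]]$point + off * anchors[[a]]$tangent
    # commissure-style tubes end below the cortex, merging into deep white
    # matter instead of reaching the surface
    rec <- spec$tracts$tip_recess_mm[tract_row]
    if (rec > 0) {
      inward <- center - p
      p <- p + rec * inward / sqrt(sum(inward^2))
    }
    p
  }

  n_tracts <- nrow(spec$tracts)
  curves <- vector("list", n_tracts)
  tract_masks <- vector("list", n_tracts)
  contribs <- vector("list", n_tracts)
  nts <- 160L
  ts <- seq(0, 1, length.out = nts)

  for (tr in seq_len(n_tracts)) {
    p0 <- end_point(tr, "from"); p3 <- end_point(tr, "to")
    # control points sit `depth` of the way from each tip toward the brain
    # centre: tubes leave the cortex radially (a shared stalk where tracts
    # terminate at the same anchor) and separate in the interior
    depth <- min(spec$tracts$depth[tr] * spec$depth_scale, 0.95)
    p1 <- p0 + depth * (center - p0)
    p2 <- p3 + depth * (center - p3)
    samp <- bezier_point(ts, p0, p1, p2, p3)
    tang <- bezier_tangent(ts, p0, p1, p2, p3)

    lo <- pmax(floor((apply(samp, 2L, min) - r_field) / vox) - 1L, 0L)
    hi <- pmin(ceiling((apply(samp, 2L, max) + r_field) / vox) + 1L, dims - 1L)
    bb <- as.matrix(expand.grid(lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]))
    bb_lin <- vox_linear_index(bb, dims)
    bb_world <- bb * vox

    md <- min_dist_to_samples(bb_world, samp)
    in_field <- md$dist <= r_field
    core <- md$dist <= spec$tube_radius

    mask_arr <- array(0, dims)
    mask_arr[bb_lin[core]] <- 1
    if (any(mask_arr[!inside_brain] != 0)) {
      abort(sprintf("tube '%s' exits the brain mask", spec$tracts$abbreviation[tr]))
    }
    tract_masks[[tr]] <- binary_mask(mask_arr, affine = affine)

    sel <- which(in_field)
    contribs[[tr]] <- data.frame(
      idx = bb_lin[sel],
      w = 1 - md$dist[sel] / r_field,
      tx = tang[md$idx[sel], 1L], ty = tang[md$idx[sel], 2L],
      tz = tang[md$idx[sel], 3L]
    )
    curves[[tr]] <- list(p0 = p0, p1 = p1, p2 = p2, p3 = p3, samples = samp, tangents = tang)
  }
  names(tract_masks) <- spec$tracts$abbreviation
  names(curves) <- spec$tracts$abbreviation

  # fold per-tract contributions into <= 3 fibre slots per voxel
  allc <- do.call(rbind, contribs)
  allc <- allc[order(allc$idx, -allc$w), ]
  rank_in_vox <- stats::ave(allc$w, allc$idx, FUN = function(x) seq_along(x))
  allc <- allc[rank_in_vox <= 3, ]
  # fractions split in proportion to tube membership at crossings
  wsum <- stats::ave(allc$w, allc$idx, FUN = sum)
  frac <- 0.85 * allc$w / pmax(wsum, 1)
  slot <- stats::ave(allc$w, allc$idx, FUN = function(x) seq_along(x))

  ori <- array(0, c(dims, 3L, 3L))
  fr <- array(0, c(dims, 3L))
  for (k in 1:3) {
    rows <- slot == k
    if (!any(rows)) next
    li <- allc$idx[rows]
    fr[li + (k - 1L) * nvox] <- frac[rows]
    ori[li + ((1L - 1L) + 3L * (k - 1L)) * nvox] <- allc$tx[rows]
    ori[li + ((2L - 1L) + 3L * (k - 1L)) * nvox] <- allc$ty[rows]
    ori[li + ((3L - 1L) + 3L * (k - 1L)) * nvox] <- allc$tz[rows]
  }
  field <- fiber_orientation_field(ori, fr, affine = affine)

  # FA/MD contrast follows the fibre-bearing support (tube plus margin),
  # not just the ground-truth core: anisotropy is high wherever fibres run
  in_tube <- apply(fr, 1:3, sum) > 0

  ico <- icosphere(spec$subdivisions)
  axes_shell <- spec$shell_scale * spec$brain_semiaxes
  verts <- sweep(ico$vertices %*% diag(axes_shell), 2L, center, "+")
  parcel <- parcel_of_unit(ico$vertices, spec$n_parcels)
  u <- ico$vertices
  # areal "myelin": per-parcel plateaus (the dominant structure of T1w/T2w
  # maps) plus a smooth within-parcel gradient
  areal <- rep(c(1.0, 1.5, 0.8, 1.3), length.out = spec$n_parcels) +
    rep(c(0, 0.25), each = spec$n_parcels %/% 2L)[seq_len(spec$n_parcels)]
  myelin_base <- areal[parcel] + 0.2 * u[, 1L] + 0.1 * u[, 2L] * u[, 3L]

  noisy <- with_seed(spec$seed, {
    fa <- ifelse(in_tube, 0.7, 0.2) + stats::rnorm(nvox, 0, spec$noise)
    fa <- pmin(pmax(fa, 0), 1) * inside_brain
    mdv <- (ifelse(in_tube, 0.7e-3, 1.0e-3) +
              stats::rnorm(nvox, 0, spec$noise * 1e-3))
    mdv <- pmax(mdv, 1e-5) * inside_brain
    myel <- myelin_base + stats::rnorm(length(myelin_base), 0, spec$noise * 0.3)
    list(fa = fa, md = mdv, myelin = myel)
  })

  surface <- surface_mesh(verts, ico$triangles,
                          scalars = list(parcel = unname(as.numeric(parcel)),
                                         myelin = unname(noisy$myelin)))

  protocols <- build_phantom_protocols(spec, curves, world, dims, affine,
                                       inside_brain, center)

  structure(
    list(spec = spec, affine = affine, dims = dims, center = center,
         brain_mask = brain_mask, field = field,
         fa = volume_grid(array(noisy$fa, dims), affine = affine),
         md = volume_grid(array(noisy$md, dims), affine = affine),
         surface = surface, parcel = parcel,
         tract_masks = tract_masks, curves = curves, anchors = anchors,
         protocols = protocols),
    class = "phantom_brain"
  )
}

# Protocol ROIs for every phantom tract: seed/target balls at the curve ends,
# a mid-curve waypoint ball, and a shared off-tract exclusion slab (a region
# the default repertoire never enters).
build_phantom_protocols <- function(spec, curves, world, dims, affine,
                                    inside_brain, center) {
  excl_arr <- array((inside_brain &
                       (world[, 2L] < center[2L] - 3) &
                       (world[, 3L] > center[3L] + 3)) + 0, dims)
  exclusion <- binary_mask(excl_arr, affine = affine)
  protos <- purrr::pmap(spec$tracts, function(name, abbreviation, category,
                                              hemisphere, from, to, ...) {
    cv <- curves[[abbreviation]]
    midpt <- as.numeric(bezier_point(0.5, cv$p0, cv$p1, cv$p2, cv$p3))
    # end-ROI centres inset along the curve by arc length
    seg <- sqrt(rowSums(diff(cv$samples)^2))
    arc <- c(0, cumsum(seg))
    dep <- spec$tracts$depth[spec$tracts$abbreviation == abbreviation] * spec$depth_scale
    # end-ROIs sit past the shared trunk only where the anchor hosts several
    # tract terminations; a private anchor needs no corridor clearance
    slot_tab <- table(c(spec$tracts$from, spec$tracts$to))
    shared0 <- slot_tab[[from]] > 1L
    shared3 <- slot_tab[[to]] > 1L
    inset0 <- spec$end_roi_inset_mm + if (shared0) dep * sqrt(sum((cv$p0 - center)^2)) else 0
    inset2 <- spec$end_roi_inset_mm + if (shared3) dep * sqrt(sum((cv$p3 - center)^2)) else 0
    i0 <- which.min(abs(arc - inset0))
    i2 <- which.min(abs(arc - (arc[length(arc)] - inset2)))
    seed_m <- binary_mask(ball_mask_array(world, dims, cv$samples[i0, ], spec$seed_roi_radius) *
                            array(inside_brain + 0, dims), affine = affine)
    target_m <- binary_mask(ball_mask_array(world, dims, cv$samples[i2, ], spec$seed_roi_radius) *
                              array(inside_brain + 0, dims), affine = affine)
    way_m <- binary_mask(ball_mask_array(world, dims, midpt, spec$waypoint_radius) *
                           array(inside_brain + 0, dims), affine = affine)
    tract_protocol(
      name = name, abbreviation = abbreviation, category = category,
      hemisphere = hemisphere,
      rois = protocol_rois(seed = seed_m, waypoints = list(mid = way_m),
                           exclusion = exclusion, target = target_m)
    )
  })
  names(protos) <- spec$tracts$abbreviation
  brain <- binary_mask(array(inside_brain + 0, dims), affine = affine)
  protocol_set(template = "phantomA", protocols = protos, brain_mask = brain)
}

#' @export
print.phantom_brain <- function(x, ...) {
  cat(sprintf("<phantom_brain> %s voxels, %d tracts, %d surface vertices, %d parcels\n",
              paste(x$dims, collapse = "x"), length(x$tract_masks),
              n_vertices(x$surface), length(unique(x$parcel))))
  invisible(x)
}

# --- twin pairs --------------------------------------------------------------

#' Default geometric perturbation for the second twin brain
#'
#' The twin differs in geometry — anisotropically scaled brain, deeper and
#' thinner tract curves, rotated anchor points, different endpoint spacing —
#' while keeping the tract repertoire and the tract-to-parcel attachment
#' pattern, emulating a cross-species pairing with shared tract definitions.
#'
#' @param spec A [phantom_spec()] for brain A.
#' @return A [phantom_spec()] for brain B.
#' @export
twin_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- spec
  out$brain_semiaxes <- spec$brain_semiaxes * c(0.85, 0.80, 0.88)
  out$depth_scale <- 1.25
  out$tube_radius <- 2.0
  # commissures reach much closer to the cortex in the twin, shifting the
  # association/commissural balance of every endpoint zone
  out$tracts$tip_recess_mm[out$tracts$tip_recess_mm > 0] <- 0.5
  out$end_offset_mm <- 0.5
  out$anchor_angle_offset_deg <- spec$anchor_angle_offset_deg + 6
  out$seed <- derive_seed(spec$seed, "twin-b")
  out
}

#' Generate a twin pair of phantom brains with known correspondence
#'
#' The two brains share the tract repertoire; geometry differs per the specs.
#' Both surfaces come from the same icosphere so the ground-truth vertex
#' correspondence is index-wise, and corresponding vertices share parcel
#' labels by construction (validated). Brain B's myelin map is the pull-back
#' of brain A's through the correspondence plus truncated Gaussian noise
#' (exact when `spec_b$noise == 0`).
#'
#' @param spec_a,spec_b [phantom_spec()]s; `spec_b` defaults to
#'   [twin_spec()]`(spec_a)`.
#' @param parcel_correspondence Integer vector mapping each A parcel label to
#'   its B counterpart (default identity).
#' @param seed Integer seed for the scalar-map noise and the warp field.
#' @return A `twin_pair`: brains `A`, `B`, `correspondence` (A vertex -> B
#'   vertex), and a [warp_field()] from grid B onto grid A samples.
#' @export
make_twin_pair <- function(spec_a, spec_b = NULL,
                           parcel_correspondence = NULL, seed = 1L) {
  stopifnot(inherits(spec_a, "phantom_spec"))
  spec_b <- spec_b %||% twin_spec(spec_a)
  if (!identical(sort(spec_a$tracts$abbreviation), sort(spec_b$tracts$abbreviation))) {
    abort("the two specs must share the same tract name repertoire")
  }
  if (spec_a$subdivisions != spec_b$subdivisions) {
    abort("twin surfaces must share the icosphere subdivision level")
  }
  a <- make_phantom_brain(spec_a)
  b <- make_phantom_brain(spec_b)
  corr <- seq_len(n_vertices(a$surface))
  parcel_correspondence <- parcel_correspondence %||% seq_len(spec_a$n_parcels)
  if (!all(b$parcel[corr] == parcel_correspondence[a$parcel])) {
    abort("corresponding vertices do not share parcel labels")
  }
  sd_noise <- spec_b$noise * stats::sd(a$surface$scalars$myelin)
  b$surface$scalars$myelin <- with_seed(derive_seed(seed, "twin-scalar"), {
    a$surface$scalars$myelin[corr] +
      stats::rnorm(length(corr), 0, sd_noise)
  })
  wf <- make_smooth_warp(a$brain_mask, b$brain_mask,
                         amplitude_mm = 1, smoothness_mm = 8,
                         seed = derive_seed(seed, "twin-warp"))
  # (warp target = grid B, pulling values from grid A)
  structure(list(A = a, B = b, correspondence = corr,
                 parcel_correspondence = parcel_correspondence, warp = wf),
            class = "twin_pair")
}

#' @export
print.twin_pair <- function(x, ...) {
  cat(sprintf("<twin_pair> %d corresponding vertices, %d shared tracts\n",
              length(x$correspondence), length(x$A$tract_masks)))
  invisible(x)
}

#' Smooth random warp between two grids
#'
#' Band-limited Gaussian displacement noise (control points every
#' `smoothness_mm`, trilinearly upsampled, max-norm scaled to `amplitude_mm`)
#' on top of the affine bridging the two grids. The field lives on the target
#' grid (`grid_b`) and maps target world points into source (`grid_a`) space.
#' With `amplitude_mm = 0` the warp is the pure affine bridge.
#'
#' @param grid_a,grid_b Source / target grids ([volume_grid()]s or anything
#'   with `$values` dims and `$affine`).
#' @param amplitude_mm Maximum displacement-noise magnitude (mm); must be
#'   below `smoothness_mm / 2` to keep the warp well-behaved.
#' @param smoothness_mm Control-point spacing of the noise (mm).
#' @param seed Integer RNG seed.
#' @return A [warp_field()] on `grid_b`.
#' @export
make_smooth_warp <- function(grid_a, grid_b, amplitude_mm = 1,
                             smoothness_mm = 8, seed = 1L) {
  assert_scalar_number(amplitude_mm, "amplitude_mm", lower = 0)
  assert_scalar_number(smoothness_mm, "smoothness_mm", lower = 1e-6)
  if (amplitude_mm >= smoothness_mm / 2) {
    abort("`amplitude_mm` must be smaller than `smoothness_mm` / 2")
  }
  dims_b <- dim(grid_b$values)
  aff_a <- grid_a$affine; aff_b <- grid_b$affine
  ijk <- all_voxel_indices(dims_b)
  world_b <- cbind(ijk, 1) %*% t(aff_b)
  src_world <- cbind(ijk, 1) %*% t(aff_a)
  disp <- src_world[, 1:3, drop = FALSE] - world_b[, 1:3, drop = FALSE]

  if (amplitude_mm > 0) {
    vox_b <- sqrt(colSums(aff_b[1:3, 1:3]^2))
    nc <- pmax(2L, as.integer(ceiling(dims_b * vox_b / smoothness_mm)) + 2L)
    noise <- with_seed(seed, array(stats::rnorm(prod(nc) * 3L), c(nc, 3L)))
    cc <- sweep(ijk, 2L, vox_b, "*") / smoothness_mm
    nz <- sapply(1:3, function(cmp) {
      trilinear_sample(array(noise[, , , cmp], nc), cc)
    })
    mags <- sqrt(rowSums(nz^2))
    if (max(mags) > 0) nz <- nz * (amplitude_mm / max(mags))
    disp <- disp + nz
  }
  warp_field(array(disp, c(dims_b, 3L)), affine = aff_b)
}

#' Export a phantom brain as a file-to-file test dataset
#'
#' Writes NIfTI volumes (brain mask, FA, MD, tract masks), GIFTI surface and
#' scalar files, the protocol directory tree, and a JSON manifest, so CLI
#' stages can run against it.
#'
#' @param brain A `phantom_brain`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_phantom <- function(brain, dir) {
  stopifnot(inherits(brain, "phantom_brain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(brain$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  write_volume(brain$fa, file.path(dir, "fa.nii.gz"))
  write_volume(brain$md, file.path(dir, "md.nii.gz"))
  dir.create(file.path(dir, "tracts"), showWarnings = FALSE)
  for (nm in names(brain$tract_masks)) {
    write_volume(brain$tract_masks[[nm]],
                 file.path(dir, "tracts", paste0(nm, ".nii.gz")))
  }
  write_fiber_field(brain$field, file.path(dir, "fibres"))
  write_surface(brain$surface, file.path(dir, "wgb.surf.gii"))
  write_surface_scalar(brain$surface$scalars$myelin, file.path(dir, "myelin.gii"))
  write_surface_scalar(brain$parcel, file.path(dir, "parcels.gii"))
  write_protocol_set(brain$protocols, file.path(dir, "protocols"))
  manifest <- list(
    grid_shape = brain$dims, voxel_mm = brain$spec$voxel_mm,
    tracts = brain$spec$tracts$abbreviation, n_parcels = brain$spec$n_parcels,
    n_vertices = n_vertices(brain$surface), seed = brain$spec$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
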