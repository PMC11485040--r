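test_that("a uniform straight field yields a straight streamline spanning the mask", {
  uf <- uniform_field(c(21L, 11L, 11L), dir = c(1, 0, 0))
  s <- propagate_streamline(uf$field, c(10, 5, 5), tracking_config(seed = 2), uf$brain)
  expect_identical(unname(s$termination), c("left_mask", "left_mask"))
  # straight: y and z never move
  expect_lt(max(abs(s$path[, 2] - 5)), 1e-9)
  expect_lt(max(abs(s$path[, 3] - 5)), 1e-9)
  # spans the mask in x (both directions from the centre)
  expect_lt(min(s$path[, 1]), 1)
  expect_gt(max(s$path[, 1]), 19)
})

test_that("max_steps bounds the streamline and is reported as the reason", {
  uf <- uniform_field()
  cfg <- tracking_config(max_steps = 1, seed = 2)
  s <- propagate_streamline(uf$field, c(10, 10, 10), cfg, uf$brain)
  expect_lte(nrow(s$path), 3) # at most one step in each direction plus the seed
  expect_identical(unname(s$termination), c("max_steps", "max_steps"))
})

test_that("an orientation flip beyond the curvature limit terminates with reason curvature", {
  dims <- c(21L, 11L, 11L)
  ori <- array(0, c(dims, 3L, 1L))
  ori[1:10, , , 1, 1] <- 1            # +x half
  ori[11:21, , , 3, 1] <- 1           # +z half: a 90 degree interface
  fr <- array(0.8, c(dims, 1L))
  field <- fiber_orientation_field(ori, fr)
  brain <- binary_mask(array(1, dims))
  s <- propagate_streamline(field, c(4, 5, 5), tracking_config(seed = 3), brain)
  expect_true("curvature" %in% s$termination)
})

test_that("voxels without admissible fibres terminate with no_fibre, not an error", {
  dims <- c(11L, 11L, 11L)
  ori <- array(0, c(dims, 3L, 1L))
  ori[, , , 1, 1] <- 1
  fr <- array(0.005, c(dims, 1L)) # below the 1% volume-fraction threshold
  field <- fiber_orientation_field(ori, fr)
  brain <- binary_mask(array(1, dims))
  s <- propagate_streamline(field, c(5, 5, 5), tracking_config(seed = 1), brain)
  expect_identical(unname(s$termination), c("no_fibre", "no_fibre"))
})

test_that("phantom protocol tracking recovers the tube with a healthy valid fraction", {
  b <- default_brain()
  cfg <- tracking_config(streamlines_per_seed_voxel = 30, seed = 7)
  pd <- run_protocol_tractography(b$field, b$protocols$protocols[["paf_l"]],
                                  b$brain_mask, cfg)
  expect_gte(pd$n_valid / pd$n_seeded, 0.5)
  gt <- b$tract_masks[["paf_l"]]
  coverage <- sum(pd$counts$values > 0 & gt$values > 0) / sum(gt$values)
  expect_gte(coverage, 0.8)
  # visitation counts are per-streamline-unique, so bounded by n_valid
  expect_lte(max(pd$counts$values), pd$n_valid)
})

test_that("validity criteria behave: vacuous criteria, determinism, exclusion monotonicity", {
  b <- default_brain()
  cfg <- tracking_config(streamlines_per_seed_voxel = 10, seed = 5)
  rois <- b$protocols$protocols[["plf_l"]]$rois

  free <- protocol_rois(seed = rois$seed)
  pd_free <- run_protocol_tractography(b$field, free, b$brain_mask, cfg)
  expect_identical(pd_free$n_valid, pd_free$n_seeded)

  pd1 <- run_protocol_tractography(b$field, rois, b$brain_mask, cfg)
  pd2 <- run_protocol_tractography(b$field, rois, b$brain_mask, cfg)
  expect_identical(pd1$counts$values, pd2$counts$values)
  expect_identical(pd1$n_valid, pd2$n_valid)

  # adding an exclusion mask can only lose streamlines
  with_excl <- protocol_rois(seed = rois$seed, waypoints = rois$waypoints,
                             exclusion = rois$target, target = NULL)
  pd_excl <- run_protocol_tractography(b$field, with_excl, b$brain_mask, cfg)
  base <- protocol_rois(seed = rois$seed, waypoints = rois$waypoints)
  pd_base <- run_protocol_tractography(b$field, base, b$brain_mask, cfg)
  expect_lte(pd_excl$n_valid, pd_base$n_valid)

  empty_seed <- binary_mask(array(0, dim(b$brain_mask$values)), affine = b$brain_mask$affine)
  expect_error(run_protocol_tractography(
    b$field, protocol_rois(seed = rois$seed, waypoints = list()), b$brain_mask,
    tracking_config(streamlines_per_seed_voxel = 0, seed = 1)), NA)
  expect_error(protocol_rois(seed = empty_seed), "empty")
})

test_that("surface-seeded visitation matrices behave at the edges", {
  b <- default_brain()
  cfg0 <- tracking_config(streamlines_per_surface_vertex = 0, seed = 1)
  vm0 <- run_surface_seeded_tractography(b$field, b$surface, b$brain_mask, 2, cfg0)
  expect_true(all(vm0$matrix == 0))
  expect_true(all(vm0$flagged))

  cfg <- tracking_config(streamlines_per_surface_vertex = 25, seed = 4)
  vm <- run_surface_seeded_tractography(b$field, b$surface, b$brain_mask, 2, cfg)
  expect_true(all(vm$matrix <= 25 * cfg$max_steps))
  expect_true(all(vm$matrix >= 0))
  # a vertex pushed outside the brain is flagged, not an error
  surf2 <- b$surface
  surf2$vertices[1, ] <- c(-50, -50, -50)
  vm2 <- run_surface_seeded_tractography(b$field, surf2, b$brain_mask, 2, cfg)
  expect_true(vm2$flagged[1])
})

test_that("tracking configuration validation names the offending field", {
  expect_error(tracking_config(curvature_limit_deg = 200), "curvature_limit_deg")
  expect_error(tracking_config(step_size_mm = 0), "step_size_mm")
  expect_error(tracking_config(min_volume_fraction = 1), "min_volume_fraction")
})

test_that("path distributions round trip with their JSON sidecar", {
  b <- default_brain()
  cfg <- tracking_config(streamlines_per_seed_voxel = 5, seed = 9)
  pd <- run_protocol_tractography(b$field, b$protocols$protocols[["pfm"]],
                                  b$brain_mask, cfg)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_path_distribution(pd, f)
  r <- read_path_distribution(f)
  expect_identical(r$counts$values, pd$counts$values)
  expect_identical(r$n_valid, pd$n_valid)
  expect_identical(r$tract, pd$tract)
})
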