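make_pd <- function(counts, n_valid, n_seeded = n_valid) {
  structure(list(counts = volume_grid(counts), n_valid = n_valid,
                 n_seeded = n_seeded, tract = "t",
                 config = tracking_config(), seed = 1L),
            class = "path_distribution")
}

test_that("normalisation divides by the valid-streamline count and flags degenerates", {
  counts <- array(0, c(2, 2, 2)); counts[1] <- 3
  npd <- normalise_path_distribution(make_pd(counts, 200L))
  expect_equal(npd$fractions$values[1], 0.015)
  expect_false(npd$degenerate)

  all_valid <- normalise_path_distribution(make_pd(array(7, c(2, 2, 2)), 7L))
  expect_true(all(all_valid$fractions$values == 1))

  degen <- normalise_path_distribution(make_pd(array(0, c(2, 2, 2)), 0L, 10L))
  expect_true(degen$degenerate)
  expect_true(all(degen$fractions$values == 0))
})

test_that("thresholding uses the >= tie rule at the 0.1% level", {
  counts <- array(0, c(2, 2, 2))
  counts[1:3] <- c(1, 2, 10) # fractions 0.001, 0.002, 0.01 at n_valid 1000
  npd <- normalise_path_distribution(make_pd(counts, 1000L))
  m <- threshold_binarise(npd) # default level 0.001
  expect_identical(as.vector(m$values)[1:4], c(1, 1, 1, 0)) # exact 0.001 survives

  uniform <- normalise_path_distribution(make_pd(array(1, c(2, 2, 2)), 2000L))
  expect_identical(sum(threshold_binarise(uniform, 0.001)$values), 0) # 0.0005 < level
  expect_identical(sum(threshold_binarise(uniform, 0)$values), 8)     # >= 0 catches all
})

test_that("path correlation matches the closed-form Pearson oracle and its invariances", {
  dims <- c(2L, 2L, 2L)
  a_vals <- c(0.1, 0.5, 0.2, 0.9, 0.0, 0.3, 0.7, 0.4)
  b_vals <- c(0.2, 0.4, 0.1, 1.0, 0.1, 0.2, 0.9, 0.3)
  npd_a <- normalise_path_distribution(make_pd(array(a_vals * 100, dims), 100L))
  npd_b <- normalise_path_distribution(make_pd(array(b_vals * 100, dims), 100L))
  mask <- binary_mask(array(1, dims))

  # textbook formula, written out independently of stats::cor
  r_oracle <- sum((a_vals - mean(a_vals)) * (b_vals - mean(b_vals))) /
    sqrt(sum((a_vals - mean(a_vals))^2) * sum((b_vals - mean(b_vals))^2))
  expect_equal(path_correlation(npd_a, npd_b, mask), r_oracle, tolerance = 1e-12)

  expect_equal(path_correlation(npd_a, npd_a, mask), 1)
  doubled <- npd_a; doubled$fractions$values <- 2 * doubled$fractions$values
  expect_equal(path_correlation(npd_a, doubled, mask), 1)
  # symmetry in the two distributions
  expect_equal(path_correlation(npd_a, npd_b, mask),
               path_correlation(npd_b, npd_a, mask))

  const <- normalise_path_distribution(make_pd(array(5, dims), 5L))
  expect_true(is.na(path_correlation(const, npd_b, mask)))
})

test_that("tract microstructure takes medians within the mask and flags empty masks", {
  dims <- c(3L, 1L, 1L)
  fa <- volume_grid(array(c(0.1, 0.2, 0.9), dims))
  md <- volume_grid(array(c(1e-3, 2e-3, 3e-3), dims))
  full <- binary_mask(array(1, dims))
  ms <- tract_microstructure(full, fa, md)
  expect_equal(ms$median_fa, 0.2)
  expect_equal(ms$median_md, 2e-3)

  one <- mask_from_voxels(dims, c(2L, 0L, 0L))
  expect_equal(tract_microstructure(one, fa, md)$median_fa, 0.9)

  none <- binary_mask(array(0, dims))
  empty <- tract_microstructure(none, fa, md)
  expect_true(is.na(empty$median_fa))
  expect_identical(empty$n_voxels, 0L)
})

test_that("percent difference is signed and exact", {
  expect_equal(percent_difference(0.5, 0.5), 0)
  expect_equal(percent_difference(0.51, 0.50), 2)
  expect_equal(percent_difference(0.49, 0.50), -2)
  expect_error(percent_difference(1, 0), "non-zero")
})

test_that("population atlases are percentages on the 100/N lattice", {
  dims <- c(2L, 2L, 1L)
  masks <- lapply(1:6, function(i) {
    m <- array(0, dims)
    if (i <= 1) m[1] <- 1 # voxel 1 active in exactly one subject
    m[2] <- 1             # voxel 2 active in all six
    binary_mask(m)
  })
  atlas <- population_atlas(masks)
  expect_equal(atlas$values[1], 100 / 6)
  expect_equal(atlas$values[2], 100)
  expect_true(all(atlas$values %in% (100 * (0:6) / 6)))

  empties <- lapply(1:3, function(i) binary_mask(array(0, dims)))
  expect_true(all(population_atlas(empties)$values == 0))
})

test_that("similarity and microstructure tables assemble and join correctly", {
  b <- default_brain()
  cfg1 <- tracking_config(streamlines_per_seed_voxel = 20, seed = 3)
  cfg2 <- tracking_config(streamlines_per_seed_voxel = 20, seed = 4)
  tracts <- c("paf_l", "pac")
  runs <- dplyr::bind_rows(lapply(tracts, function(ab) {
    tibble::tibble(
      tract = ab, subject = "s1",
      template = c("ref", "other"),
      npd = list(
        normalise_path_distribution(run_protocol_tractography(
          b$field, b$protocols$protocols[[ab]], b$brain_mask, cfg1)),
        normalise_path_distribution(run_protocol_tractography(
          b$field, b$protocols$protocols[[ab]], b$brain_mask, cfg2)))
    )
  }))
  sim <- tract_similarity_table(runs, "ref")
  expect_identical(nrow(sim), 2L)
  expect_true(all(sim$r > 0.9))

  ms <- microstructure_table(runs, b$fa, b$md, "ref")
  expect_identical(nrow(ms), 4L)
  ref_rows <- ms$template == "ref"
  expect_true(all(ms$pct_diff_fa[ref_rows] == 0))
  expect_true(all(abs(ms$pct_diff_fa[!ref_rows]) < 10))
  expect_true(all(ms$median_fa >= 0 & ms$median_fa <= 1))
  expect_true(all(ms$median_md > 0))
})
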