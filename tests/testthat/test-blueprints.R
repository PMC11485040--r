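toy_tm <- function(mat, tracts = paste0("t", seq_len(ncol(mat)))) {
  structure(list(matrix = mat, tracts = tracts,
                 coarse_dims = c(nrow(mat), 1L, 1L), coarse_affine = diag(4),
                 coarse_cols = seq_len(nrow(mat))),
            class = "tract_matrix")
}

test_that("tract matrices vectorise block averages in the fixed voxel order", {
  dims <- c(2L, 2L, 2L)
  brain <- binary_mask(array(1, dims))
  counts <- array(0, dims); counts[1] <- 8
  npd <- normalise_path_distribution(
    structure(list(counts = volume_grid(counts), n_valid = 10L, n_seeded = 10L,
                   tract = "a", config = tracking_config(), seed = 1L),
              class = "path_distribution"))
  tm <- build_tract_matrix(list(a = npd, b = npd), brain, 2)
  # single coarse voxel: block average of 8 fine voxels, one carrying 0.8
  expect_equal(as.vector(tm$matrix), c(0.1, 0.1))
  expect_identical(tm$tracts, c("a", "b"))
  expect_identical(unname(tm$matrix[, 1]), unname(tm$matrix[, 2]))

  zero <- npd; zero$fractions$values[] <- 0
  tmz <- build_tract_matrix(list(z = zero), brain, 2)
  expect_true(all(tmz$matrix == 0))

  expect_error(build_tract_matrix(list(a = npd, a = npd), brain, 2), "collision")
})

test_that("blueprint products equal manual arithmetic and unit-row pass-through", {
  tm <- toy_tm(matrix(c(0.5, 0.1, 0.4,
                        0.2, 0.6, 0.2), ncol = 2), c("x", "y"))
  # each vertex visits one distinct voxel once: rows of the blueprint = rows of tm
  conn_unit <- diag(3)
  bp <- build_blueprint(conn_unit, tm, normalise = FALSE)
  expect_equal(bp$matrix, tm$matrix)

  # 2 vertices x 3 voxels x 2 tracts, by hand
  conn <- matrix(c(1, 0, 2, 1, 0, 3), nrow = 2, byrow = TRUE)
  manual <- matrix(c(
    1 * 0.5 + 0 * 0.1 + 2 * 0.4, 1 * 0.2 + 0 * 0.6 + 2 * 0.2,
    1 * 0.5 + 0 * 0.1 + 3 * 0.4, 1 * 0.2 + 0 * 0.6 + 3 * 0.2
  ), nrow = 2, byrow = TRUE)
  bp2 <- build_blueprint(conn, tm, normalise = FALSE)
  expect_equal(bp2$matrix, manual, tolerance = 1e-15)

  # one tract covering all voxels uniformly: normalised blueprint is all ones
  tm1 <- toy_tm(matrix(0.25, nrow = 3, ncol = 1), "only")
  bp3 <- build_blueprint(conn, tm1)
  expect_true(all(bp3$matrix[!bp3$excluded, ] == 1))

  expect_error(build_blueprint(matrix(1, 2, 4), tm), "inner dimensions")
})

test_that("zero-sum rows are excluded and surviving rows are row-stochastic", {
  tm <- toy_tm(matrix(c(0.3, 0, 0.7, 0.1, 0, 0.9), ncol = 2))
  conn <- rbind(c(1, 0, 2), c(0, 5, 0), c(2, 0, 1)) # vertex 2 only visits the zero voxel
  bp <- build_blueprint(conn, tm)
  expect_identical(bp$excluded, c(FALSE, TRUE, FALSE))
  inc <- which(!bp$excluded)
  expect_lt(max(abs(rowSums(bp$matrix[inc, , drop = FALSE]) - 1)), 1e-9)
})

test_that("the streamline oracle reproduces build_blueprint bit-for-bit on a phantom", {
  b <- default_brain()
  cfg <- tracking_config(streamlines_per_surface_vertex = 25,
                         streamlines_per_seed_voxel = 15, seed = 12)
  npds <- lapply(b$protocols$protocols, function(p) {
    normalise_path_distribution(run_protocol_tractography(b$field, p, b$brain_mask, cfg))
  })
  tm <- build_tract_matrix(npds, b$brain_mask, 2)
  conn <- run_surface_seeded_tractography(b$field, b$surface, b$brain_mask, 2, cfg)
  bp <- build_blueprint(conn, tm)
  oracle <- streamline_oracle_blueprint(b$field, b$surface, tm, b$brain_mask, cfg)
  expect_identical(bp$matrix, oracle$matrix)
  expect_identical(bp$excluded, oracle$excluded)
})

test_that("column permutations of the tract matrix permute blueprint columns identically", {
  tm <- toy_tm(matrix(runif(12), ncol = 3), c("a", "b", "c"))
  conn <- matrix(rpois(8, 3), nrow = 2)
  perm <- c(3L, 1L, 2L)
  tm_p <- toy_tm(tm$matrix[, perm], tm$tracts[perm])
  bp <- build_blueprint(conn, tm)
  bp_p <- build_blueprint(conn, tm_p)
  expect_equal(bp_p$matrix, bp$matrix[, perm])
  expect_identical(bp_p$tracts, bp$tracts[perm])
})

test_that("group averaging handles exclusions with a masked mean and renormalises", {
  mk <- function(mat, excluded) {
    structure(list(matrix = mat, tracts = c("a", "b"), excluded = excluded,
                   normalised = TRUE, row_sums = rowSums(mat)),
              class = "connectivity_blueprint")
  }
  b1 <- mk(rbind(c(0.2, 0.8), c(0.5, 0.5)), c(FALSE, FALSE))
  b2 <- mk(rbind(c(0.4, 0.6), c(0, 0)), c(FALSE, TRUE))
  g <- group_average_blueprints(list(b1, b2))
  expect_equal(g$matrix[1, ], c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(g$matrix[2, ], c(0.5, 0.5), ignore_attr = TRUE) # vertex 2 from b1 alone
  expect_identical(g$excluded, c(FALSE, FALSE))
  expect_equal(rowSums(g$matrix), c(1, 1))

  same <- group_average_blueprints(list(b1, b1))
  expect_equal(same$matrix, b1$matrix)
})

test_that("region exclusion and average profiles follow the row arithmetic", {
  mk <- function(mat) {
    structure(list(matrix = mat, tracts = c("a", "b"),
                   excluded = rep(FALSE, nrow(mat)), normalised = TRUE,
                   row_sums = rowSums(mat)),
              class = "connectivity_blueprint")
  }
  bp <- mk(rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.9, 0.1)))

  expect_identical(exclude_region(bp, integer(0))$excluded, rep(FALSE, 3))
  ex <- exclude_region(bp, c(1L, 3L))
  expect_identical(sum(ex$excluded), 2L)
  all_ex <- exclude_region(bp, 1:3)
  klm_empty <- kl_matrix(all_ex, all_ex)
  expect_identical(dim(klm_empty$matrix), c(0L, 0L))
  expect_error(min_kl_summary(klm_empty), "empty")

  expect_equal(average_region_profile(bp, 2L), c(a = 0.4, b = 0.6))
  expect_equal(average_region_profile(bp, 1:2), c(a = 0.3, b = 0.7))
  expect_equal(sum(average_region_profile(bp, 1:3)), 1)
  expect_error(average_region_profile(ex, c(1L, 3L)), "empty")
})

test_that("low-signal vertices are excluded relative to the median row signal", {
  mk <- function(mat, rs) {
    structure(list(matrix = mat, tracts = c("a", "b"),
                   excluded = rep(FALSE, nrow(mat)), normalised = TRUE,
                   row_sums = rs),
              class = "connectivity_blueprint")
  }
  bp <- mk(matrix(0.5, 4, 2), c(10, 12, 9, 0.1))
  out <- exclude_low_signal(bp, 0.05)
  expect_identical(out$excluded, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("blueprints round trip through TSV plus manifest", {
  tm <- toy_tm(matrix(c(0.5, 0.1, 0.4, 0.2, 0.6, 0.2), ncol = 2), c("x", "y"))
  bp <- build_blueprint(rbind(c(1, 0, 2), c(0, 0, 0), c(2, 1, 1)), tm)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blueprint(bp, f)
  r <- read_blueprint(f)
  expect_equal(r$matrix, bp$matrix, tolerance = 1e-12)
  expect_identical(r$excluded, bp$excluded)
  expect_identical(r$tracts, bp$tracts)
})
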