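test_that("bilateral expansion of the reference inventory yields exactly 42 protocols", {
  inv <- xtract_inventory()
  stubs <- expand_tract_inventory(inv)
  n_bilateral <- sum(inv$category != "commissural")
  n_commissural <- sum(inv$category == "commissural")
  expect_identical(nrow(stubs), 2L * n_bilateral + n_commissural)
  expect_identical(nrow(stubs), 42L)
  expect_false(anyDuplicated(stubs$abbreviation) > 0)

  expect_identical(nrow(expand_tract_inventory(inv[0, ])), 0L)
  one <- expand_tract_inventory(
    tibble::tibble(name = "x", abbreviation = "x", category = "commissural"))
  expect_identical(nrow(one), 1L)
  expect_identical(one$hemisphere, "none")

  expect_error(expand_tract_inventory(
    tibble::tibble(name = c("a", "b"), abbreviation = c("z", "z"),
                   category = "limbic")), "duplicate")
  expect_error(expand_tract_inventory(
    tibble::tibble(name = "a", abbreviation = "a", category = "nonsense")),
    "invalid category")
})

test_that("warping a protocol set through the identity warp changes nothing", {
  pset <- default_brain()$protocols
  brain <- pset$brain_mask
  w <- identity_warp(dim(brain$values), affine = brain$affine)
  out <- warp_protocol_set(pset, w, brain, template_name = "same")
  for (ab in names(pset$protocols)) {
    expect_identical(out$protocols[[ab]]$rois$seed$values,
                     pset$protocols[[ab]]$rois$seed$values)
    expect_identical(out$protocols[[ab]]$rois$target$values,
                     pset$protocols[[ab]]$rois$target$values)
  }
  expect_length(attr(out, "empty_after_warp"), 0)
})

test_that("a warp that pushes an ROI off the grid flags that ROI and only it", {
  pset <- default_brain()$protocols
  brain <- pset$brain_mask
  dims <- dim(brain$values)
  disp <- array(0, c(dims, 3L))
  disp[, , , 1] <- 200 # samples far outside the source grid: everything reads 0
  out <- warp_protocol_set(pset, warp_field(disp, affine = brain$affine), brain)
  expect_true(length(attr(out, "empty_after_warp")) > 0)
})

test_that("the QC battery reports exact overlap, out-of-brain, and asymmetry values", {
  # the default phantom protocol set is mirror-symmetric and defect-free
  qc <- qc_protocol_set(default_brain()$protocols)
  tab <- tibble::as_tibble(qc)
  expect_true(all(tab$value[tab$metric == "asymmetry"] < 0.05))
  expect_true(all(tab$value[tab$metric == "out_of_brain"] == 0))
  hard_overlaps <- tab$value[tab$metric == "overlap" & tab$hard_fail]
  expect_true(all(hard_overlaps == 0))
  expect_length(attr(qc, "failing_tracts"), 0)

  # constructed defects are counted exactly
  dims <- c(12L, 12L, 12L)
  brain <- binary_mask(array(1, dims))
  brain$values[1, , ] <- 0 # a slab of "outside brain"
  seed <- mask_from_voxels(dims, rbind(c(5L, 5L, 5L), c(6L, 5L, 5L), c(7L, 5L, 5L)))
  excl <- mask_from_voxels(dims, rbind(c(6L, 5L, 5L), c(7L, 5L, 5L), c(8L, 5L, 5L)))
  oob <- mask_from_voxels(dims, rbind(c(0L, 3L, 3L), c(0L, 4L, 4L), c(5L, 5L, 6L)))
  p <- tract_protocol("defective", "bad", "commissural", "none",
                      rois = protocol_rois(seed = seed, exclusion = excl,
                                           target = oob))
  qc2 <- qc_protocol_set(protocol_set("t", list(p), brain))
  tab2 <- tibble::as_tibble(qc2)
  expect_identical(tab2$value[tab2$roi == "seed*exclusion" & tab2$metric == "overlap"], 2)
  expect_identical(tab2$value[tab2$roi == "target" & tab2$metric == "out_of_brain"], 2)
  expect_identical(attr(qc2, "failing_tracts"), "bad")

  # QC is invariant to protocol order
  ps <- default_brain()$protocols
  rev_set <- protocol_set(ps$template, rev(ps$protocols), ps$brain_mask)
  t1 <- tibble::as_tibble(qc_protocol_set(ps)) |> dplyr::arrange(tract, roi, metric)
  t2 <- tibble::as_tibble(qc_protocol_set(rev_set)) |> dplyr::arrange(tract, roi, metric)
  expect_equal(t1, t2)
})

test_that("bilateral tracts without a contralateral partner are an error", {
  ps <- default_brain()$protocols
  broken <- protocol_set(ps$template, ps$protocols[c("paf_l", "pac")], ps$brain_mask)
  expect_error(qc_protocol_set(broken), "contralateral")
})

test_that("revision operators are exact mask algebra with provenance", {
  dims <- c(10L, 10L, 10L)
  roi <- mask_from_voxels(dims, rbind(c(4L, 4L, 4L), c(5L, 4L, 4L), c(6L, 4L, 4L)))
  seed <- mask_from_voxels(dims, c(3L, 4L, 4L))
  p <- tract_protocol("t", "t", "association", "left",
                      rois = protocol_rois(seed = roi, target = seed))

  sub <- apply_revision(p, list(list(op = "subtract_mask", roi = "target",
                                     mask = seed)))
  expect_identical(sum(sub$rois$target$values), 0)
  expect_identical(sub$provenance, "subtract_mask(target)")

  # erode-1-along-interface removes exactly the ROI voxels 6-adjacent to the seed
  er <- apply_revision(p, list(list(op = "erode_interface", roi = "seed",
                                    interface = seed)))
  # the (4,4,4) voxel touches (3,4,4); (5,..) and (6,..) do not
  expect_identical(which(er$rois$seed$values != 0),
                   which(mask_from_voxels(dims, rbind(c(5L, 4L, 4L), c(6L, 4L, 4L)))$values != 0))

  # emptying the seed is refused
  expect_error(apply_revision(p, list(list(op = "subtract_mask", roi = "seed",
                                           mask = roi))), "empty the seed")

  # mirror-from-contralateral on a symmetric grid gives asymmetry 0
  right <- mask_from_voxels(dims, c(6L, 2L, 2L))
  p2 <- apply_revision(p, list(list(op = "mirror_from_contralateral", roi = "seed",
                                    contralateral = right, midline_axis = 1,
                                    midline_coordinate = 4.5)))
  expect_identical(which(p2$rois$seed$values != 0),
                   which(mask_from_voxels(dims, c(3L, 2L, 2L))$values != 0))
})

test_that("protocol sets round trip through the directory layout", {
  ps <- default_brain()$protocols
  dir <- withr::local_tempdir()
  write_protocol_set(ps, dir)
  r <- read_protocol_set(dir)
  expect_identical(r$template, ps$template)
  for (ab in names(ps$protocols)) {
    expect_identical(r$protocols[[ab]]$rois$seed$values,
                     ps$protocols[[ab]]$rois$seed$values)
    expect_identical(r$protocols[[ab]]$category, ps$protocols[[ab]]$category)
  }
})
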