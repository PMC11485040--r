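test_that("NIfTI round trip preserves geometry and integer data bit-exactly", {
  vals <- array(as.double(0:63), c(4, 4, 4))
  aff <- diag(c(1, 2, 1, 1)); aff[1:3, 4] <- c(10, -5, 2.5)
  v <- volume_grid(vals, affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(as.vector(r$values), as.vector(vals))
  expect_lt(max(abs(r$affine - aff)), 1e-5)

  # 0/1 volumes come back as binary masks regardless of on-disk width
  m <- binary_mask(array(c(0, 1), c(4, 4, 4)))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  rm_ <- read_volume(fm)
  expect_s3_class(rm_, "binary_mask")
  expect_identical(rm_$values, m$values)
})

test_that("read_volume rejects missing files, 4-D input, and non-finite voxels", {
  expect_error(read_volume("no/such/file.nii.gz"), "not found")

  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(3, 3, 3, 2))), f4)
  expect_error(read_volume(f4), "3-D")

  fn <- withr::local_tempfile(fileext = ".nii.gz")
  a <- array(1, c(3, 3, 3)); a[2, 3, 1] <- NaN
  RNifti::writeNifti(RNifti::asNifti(a), fn)
  expect_error(read_volume(fn), "\\(1, 2, 0\\)")
})

test_that("identity warp is a no-op and warped outputs stay binary on the target grid", {
  m <- default_brain()$protocols$protocols[[1]]$rois$seed
  w <- identity_warp(dim(m$values), affine = m$affine)
  out <- apply_warp_to_mask(m, w)
  expect_identical(out$values, m$values)
  expect_true(all(out$values %in% c(0, 1)))
  expect_identical(dim(out$values), w$dims)

  zero <- binary_mask(array(0, dim(m$values)), affine = m$affine)
  expect_identical(apply_warp_to_mask(zero, w)$values, zero$values)
})

test_that("a one-voxel translation warp matches the index-shift oracle", {
  dims <- c(12L, 10L, 10L)
  set.seed(31)
  m <- binary_mask(array(rbinom(prod(dims), 1, 0.3), dims))
  # displacement +1 mm along x pulls values from the next voxel: out[i] = in[i+1]
  disp <- array(0, c(dims, 3L)); disp[, , , 1L] <- 1
  out <- apply_warp_to_mask(m, warp_field(disp))
  oracle <- array(0, dims)
  oracle[1:(dims[1] - 1L), , ] <- m$values[2:dims[1], , ]
  expect_identical(out$values, oracle)
})

test_that("mirroring is an involution and moves voxels to reflected positions", {
  dims <- c(11L, 9L, 9L)
  plane <- 5 # world x of the central voxel column
  m <- mask_from_voxels(dims, c(8L, 4L, 4L))
  once <- mirror_mask(m, 1L, plane)
  expect_identical(which(once$values != 0),
                   which(mask_from_voxels(dims, c(2L, 4L, 4L))$values != 0))
  twice <- mirror_mask(once, 1L, plane)
  expect_identical(twice$values, m$values)

  sym <- mask_from_voxels(dims, rbind(c(4L, 4L, 4L), c(6L, 4L, 4L)))
  expect_identical(mirror_mask(sym, 1L, plane)$values, sym$values)

  expect_error(mirror_mask(m, 1L, 99), "outside the grid")
})

test_that("downsampling block-averages, honours the any rule, and preserves world extent", {
  ones <- volume_grid(array(1, c(4, 4, 4)))
  expect_identical(downsample_volume(ones, 1), ones)
  d <- downsample_volume(ones, 2)
  expect_identical(dim(d$values), c(2L, 2L, 2L))
  expect_true(all(d$values == 1))
  # coarse voxel 0 centre sits at the centre of its 2x2x2 fine block
  expect_equal(d$affine[1:3, 4], c(0.5, 0.5, 0.5))

  m <- mask_from_voxels(c(2L, 2L, 2L), c(1L, 0L, 1L))
  any_d <- downsample_volume(m, 2, rule = "any")
  expect_s3_class(any_d, "binary_mask")
  expect_identical(as.vector(any_d$values), 1)
  mean_d <- downsample_volume(volume_grid(m$values), 2, rule = "mean")
  expect_equal(as.vector(mean_d$values), 1 / 8)

  expect_error(downsample_volume(ones, 1.5), "non-integer decimation")
})

test_that("GIFTI surface and scalar files round trip", {
  mesh <- default_brain()$surface
  f <- withr::local_tempfile(fileext = ".surf.gii")
  write_surface(mesh, f)
  r <- read_surface(f)
  expect_equal(r$vertices, mesh$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(r$triangles, mesh$triangles)

  fs <- withr::local_tempfile(fileext = ".gii")
  write_surface_scalar(mesh$scalars$myelin, fs)
  expect_equal(read_surface_scalar(fs), mesh$scalars$myelin, tolerance = 1e-12)

  expect_error(surface_mesh(mesh$vertices, rbind(c(1L, 1L, 2L))), "degenerate")
  expect_error(surface_mesh(mesh$vertices, rbind(c(1L, 2L, nrow(mesh$vertices) + 1L))),
               "out of range")
})

test_that("warp fields round trip through 3-volume NIfTI vector images", {
  w <- make_smooth_warp(default_brain()$brain_mask, default_brain()$brain_mask,
                        amplitude_mm = 0.5, smoothness_mm = 8, seed = 3)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_warp(w, f)
  r <- read_warp(f)
  expect_equal(r$displacement, w$displacement, tolerance = 1e-12)
  expect_lt(max(abs(r$affine - w$affine)), 1e-5)
})
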