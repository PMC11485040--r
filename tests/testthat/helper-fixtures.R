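# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default desk-scale phantom brain (deterministic; shared read-only)
default_brain <- function() fixture("brain", make_phantom_brain(phantom_spec()))

# a uniform single-fibre field along `dir` inside a box brain mask
uniform_field <- function(dims = c(21L, 21L, 21L), dir = c(1, 0, 0), fraction = 0.8) {
  dir <- dir / sqrt(sum(dir^2))
  ori <- array(0, c(dims, 3L, 1L))
  for (c in 1:3) ori[, , , c, 1L] <- dir[c]
  fr <- array(fraction, c(dims, 1L))
  list(field = fiber_orientation_field(ori, fr),
       brain = binary_mask(array(1, dims)))
}

# tract matrix + connectivity + blueprint for a phantom brain, one call
build_phantom_blueprint <- function(brain, config, coarse_mm = 2,
                                    low_signal_frac = 0.05) {
  npds <- lapply(brain$protocols$protocols, function(p) {
    normalise_path_distribution(
      run_protocol_tractography(brain$field, p, brain$brain_mask, config))
  })
  tm <- build_tract_matrix(npds, brain$brain_mask, coarse_mm)
  conn <- run_surface_seeded_tractography(brain$field, brain$surface,
                                          brain$brain_mask, coarse_mm, config)
  bp <- build_blueprint(conn, tm)
  if (low_signal_frac > 0) bp <- exclude_low_signal(bp, low_signal_frac)
  bp
}

# small binary mask on a given grid with listed active 0-based voxel triples
mask_from_voxels <- function(dims, ijk, affine = NULL) {
  a <- array(0, dims)
  if (length(ijk)) {
    if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3L, byrow = TRUE)
    a[ijk[, 1L] + dims[1L] * (ijk[, 2L] + dims[2L] * ijk[, 3L]) + 1L] <- 1
  }
  binary_mask(a, affine = affine %||% diag(4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
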