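#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import Rcpp
#' @useDynLib tractblue, .registration = TRUE
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards, so generators are pure functions of (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 17) %% 2147483587)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Linear (column-major) index helpers for 3-D arrays, 1-based.
vox_linear_index <- function(ijk, dims) {
  1L + ijk[, 1L] + dims[1L] * (ijk[, 2L] + dims[2L] * ijk[, 3L])
}

# All voxel indices of a grid as an n x 3 matrix of 0-based (i, j, k).
all_voxel_indices <- function(dims) {
  cbind(
    rep.int(seq_len(dims[1L]) - 1L, dims[2L] * dims[3L]),
    rep.int(rep(seq_len(dims[2L]) - 1L, each = dims[1L]), dims[3L]),
    rep(seq_len(dims[3L]) - 1L, each = dims[1L] * dims[2L])
  )
}

# Trilinear interpolation of a 3-D array at continuous 0-based voxel coordinates.
# Coordinates outside the grid sample `outside` (default 0): warped ROIs near
# boundaries degrade gracefully instead of erroring.
trilinear_sample <- function(values, coords, outside = 0) {
  dims <- dim(values)
  n <- nrow(coords)
  x <- coords[, 1L]; y <- coords[, 2L]; z <- coords[, 3L]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0

  get_at <- function(i, j, k) {
    ok <- i >= 0 & i <= dims[1L] - 1L & j >= 0 & j <= dims[2L] - 1L &
      k >= 0 & k <= dims[3L] - 1L
    out <- rep(outside, n)
    if (any(ok)) {
      idx <- 1L + i[ok] + dims[1L] * (j[ok] + dims[2L] * k[ok])
      out[ok] <- values[idx]
    }
    out
  }

  v000 <- get_at(x0,      y0,      z0)
  v100 <- get_at(x0 + 1L, y0,      z0)
  v010 <- get_at(x0,      y0 + 1L, z0)
  v110 <- get_at(x0 + 1L, y0 + 1L, z0)
  v001 <- get_at(x0,      y0,      z0 + 1L)
  v101 <- get_at(x0 + 1L, y0,      z0 + 1L)
  v011 <- get_at(x0,      y0 + 1L, z0 + 1L)
  v111 <- get_at(x0 + 1L, y0 + 1L, z0 + 1L)

  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}
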