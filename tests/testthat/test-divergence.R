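mk_bp <- function(mat, tracts = paste0("t", seq_len(ncol(mat))),
                  excluded = rep(FALSE, nrow(mat))) {
  structure(list(matrix = mat, tracts = tracts, excluded = excluded,
                 normalised = TRUE, row_sums = rowSums(mat)),
            class = "connectivity_blueprint")
}

test_that("symmetric KL matches direct term-by-term summation on the hand pair", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  direct <- 0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  expect_equal(symmetric_kl(p, q, epsilon = 1e-300), direct, tolerance = 1e-12)
  expect_equal(direct, 0.1373265, tolerance = 1e-6)
})

test_that("symmetric KL is zero on identity, symmetric, and non-negative", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    p <- runif(n); q <- runif(n)
    expect_identical(symmetric_kl(p, p), 0)
    expect_equal(symmetric_kl(p, q), symmetric_kl(q, p))
    expect_gte(symmetric_kl(p, q), 0)
  }
  expect_error(symmetric_kl(c(0, 0), c(1, 1)), "all-zero")
  expect_error(symmetric_kl(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(symmetric_kl(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("the KL matrix equals the element-wise loop oracle and drops excluded rows", {
  set.seed(9)
  A <- matrix(runif(9), 3); A <- A / rowSums(A)
  B <- matrix(runif(9), 3); B <- B / rowSums(B)
  bpa <- mk_bp(A); bpb <- mk_bp(B)
  klm <- kl_matrix(bpa, bpb, epsilon = 1e-8)
  oracle <- outer(1:3, 1:3, Vectorize(function(i, j) {
    symmetric_kl(A[i, ], B[j, ], epsilon = 1e-8)
  }))
  expect_equal(klm$matrix, oracle, tolerance = 1e-12)

  self <- kl_matrix(bpa, bpa)
  expect_lt(max(diag(self$matrix)), 1e-12)
  expect_true(all(self$matrix[upper.tri(self$matrix)] > 1e-6))

  one_out <- mk_bp(A, excluded = c(TRUE, FALSE, FALSE))
  expect_identical(nrow(kl_matrix(one_out, bpb)$matrix), 2L)
  expect_identical(kl_matrix(one_out, bpb)$rows_a, 2:3)

  expect_error(kl_matrix(bpa, mk_bp(B, tracts = c("u", "v", "w"))), "frame")
})

test_that("min-KL summaries find row minima with flagged lowest-index ties", {
  m <- rbind(c(0.5, 0.1, 0.9),
             c(0.2, 0.2, 0.7))
  klm <- structure(list(matrix = m, rows_a = c(4L, 7L), cols_b = c(1L, 2L, 3L),
                        epsilon = 1e-8, tracts = "t"), class = "kl_matrix")
  s <- min_kl_summary(klm)
  expect_equal(s$min_kl, c(0.1, 0.2))
  expect_identical(s$argmin, c(2L, 1L)) # tie in row 2 broken by lowest index
  expect_identical(s$tie, c(FALSE, TRUE))
  expect_identical(s$vertex, c(4L, 7L))

  sc <- min_kl_summary(klm, "cols")
  expect_equal(sc$min_kl, c(0.2, 0.1, 0.7))

  g <- glance(s)
  expect_identical(g$n, 2L)
  expect_equal(g$median, 0.15)
})

test_that("homologue search honours self-matches and the percentile cut", {
  set.seed(4)
  M <- matrix(runif(24), 8); M <- M / rowSums(M)
  bp <- mk_bp(M)
  hom <- find_homologue(bp, M[3, ], percentile_cut = 5)
  expect_equal(min(hom$kl), 0)
  expect_true(hom$in_mask[hom$vertex == 3])
  expect_identical(attr(hom, "argmin"), 3L)

  all_in <- find_homologue(bp, M[3, ], percentile_cut = 100)
  expect_true(all(all_in$in_mask))

  expect_error(find_homologue(bp, M[3, 1:2]), "tract frame")
  expect_error(find_homologue(bp, 2 * M[3, ]), "sum to 1")
})

test_that("argmin projection through identical blueprints returns the source map exactly", {
  set.seed(6)
  M <- matrix(runif(30), 10); M <- M / rowSums(M)
  bp <- mk_bp(M)
  klm <- kl_matrix(bp, bp)
  src <- rnorm(10)
  proj <- project_scalar_map(klm, src, mode = "argmin")
  expect_identical(proj$value, src)
})

test_that("softmax projection approaches the unweighted mean as temperature grows", {
  set.seed(8)
  M <- matrix(runif(30), 10); M <- M / rowSums(M)
  bp <- mk_bp(M)
  klm <- kl_matrix(bp, bp)
  src <- rnorm(10)
  proj <- project_scalar_map(klm, src, mode = "softmax", temperature = 1e12)
  expect_equal(proj$value, rep(mean(src), 10), tolerance = 1e-9)
  expect_error(project_scalar_map(klm, src, "softmax", temperature = -1),
               "temperature")
})

test_that("map comparison matches the closed-form Pearson oracle", {
  x <- c(1.2, -0.4, 0.8, 2.0)
  y <- c(0.9, -0.1, 1.1, 1.7)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cmp <- compare_maps(x, y)
  expect_equal(cmp$r, r_oracle, tolerance = 1e-12)
  expect_equal(cmp$abs_difference$abs_diff, abs(x - y))

  expect_equal(compare_maps(x, x)$r, 1)
  expect_true(all(compare_maps(x, x)$abs_difference$abs_diff == 0))
  centred <- x - mean(x)
  expect_equal(compare_maps(centred, -centred)$r, -1)
  const <- compare_maps(rep(1, 4), y)
  expect_true(is.na(const$r))
  expect_true(const$constant_input)
})

test_that("tidiers and glance summaries stay consistent with their objects", {
  set.seed(2)
  M <- matrix(runif(12), 4); M <- M / rowSums(M)
  bp <- mk_bp(M, tracts = c("a", "b", "c"))
  td <- tidy(bp)
  expect_identical(nrow(td), 12L)
  expect_equal(sum(td$value[td$vertex == 2]), 1)
  g <- glance(bp)
  expect_identical(g$n_vertices, 4L)
  expect_lt(g$max_row_sum_error, 1e-9)

  klm <- kl_matrix(bp, bp)
  expect_identical(nrow(tidy(klm)), 16L)
  expect_equal(glance(klm)$median_min_kl, 0)
})
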