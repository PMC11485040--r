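#' Symmetric Kullback-Leibler divergence between probability profiles
#'
#' Both profiles are floored at `epsilon`, renormalised, and compared with the
#' arithmetic mean of the two directed divergences,
#' `0.5 * (KL(p || q) + KL(q || p))`, in nats. Zero iff the floored,
#' renormalised profiles coincide; flooring keeps the divergence finite when
#' blueprints legitimately contain zeros.
#'
#' @param p,q Non-negative numeric vectors of equal length, each with positive
#'   sum.
#' @param epsilon Floor applied before the logs (default 1e-8).
#' @return Non-negative scalar (nats).
#' @examples
#' symmetric_kl(c(0.5, 0.5), c(0.25, 0.75)) # about 0.137
#' @export
symmetric_kl <- function(p, q, epsilon = 1e-8) {
  if (length(p) != length(q)) abort("profiles must have equal length")
  if (any(p < 0) || any(q < 0)) abort("profiles must be non-negative")
  if (sum(p) <= 0 || sum(q) <= 0) abort("all-zero profile")
  p <- pmax(p / sum(p), epsilon); p <- p / sum(p)
  q <- pmax(q / sum(q), epsilon); q <- q / sum(q)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

# Floor + renormalise all non-excluded blueprint rows at once.
floored_rows <- function(bp, epsilon) {
  rows <- which(!bp$excluded)
  m <- bp$matrix[rows, , drop = FALSE]
  rs <- rowSums(m)
  if (any(rs <= 0)) abort("non-excluded blueprint row with zero sum")
  m <- pmax(m / rs, epsilon)
  m <- m / rowSums(m)
  list(rows = rows, m = m)
}

#' All-pairs symmetric KL between two blueprints
#'
#' Computes the symmetric KL divergence between every non-excluded row of
#' blueprint A and every non-excluded row of blueprint B (identical tract
#' frames required). Excluded vertices are omitted from the matrix frame.
#'
#' @param bp_a,bp_b `connectivity_blueprint`s sharing the tract list/order.
#' @param epsilon Floor before the logs (default 1e-8, recorded in the result).
#' @return A `kl_matrix`: `matrix` (A vertices x B vertices), `rows_a` /
#'   `cols_b` (original vertex indices), `epsilon`, `tracts`.
#' @export
kl_matrix <- function(bp_a, bp_b, epsilon = 1e-8) {
  stopifnot(inherits(bp_a, "connectivity_blueprint"),
            inherits(bp_b, "connectivity_blueprint"))
  if (!identical(bp_a$tracts, bp_b$tracts)) abort("tract frame mismatch")
  fa <- floored_rows(bp_a, epsilon)
  fb <- floored_rows(bp_b, epsilon)
  P <- fa$m; Q <- fb$m
  # KL(p_i || q_j) = sum_t p_it log p_it - sum_t p_it log q_jt
  self_p <- rowSums(P * log(P))
  self_q <- rowSums(Q * log(Q))
  cross_pq <- P %*% t(log(Q))
  cross_qp <- Q %*% t(log(P))
  kl_ab <- matrix(self_p, nrow(P), nrow(Q)) - cross_pq
  kl_ba <- t(matrix(self_q, nrow(Q), nrow(P)) - cross_qp)
  m <- 0.5 * (kl_ab + kl_ba)
  m[m < 0] <- 0 # numerical floor; true divergences are non-negative
  structure(list(matrix = m, rows_a = fa$rows, cols_b = fb$rows,
                 epsilon = epsilon, tracts = bp_a$tracts),
            class = "kl_matrix")
}

#' @export
print.kl_matrix <- function(x, ...) {
  cat(sprintf("<kl_matrix> %d x %d vertices, median %.4g nats (epsilon %.1g)\n",
              nrow(x$matrix), ncol(x$matrix), stats::median(x$matrix), x$epsilon))
  invisible(x)
}

#' Per-vertex minimum divergence and best match
#'
#' Row-wise (or column-wise) minima of a KL matrix: for each vertex of one
#' brain, the divergence to its best-matching vertex in the other brain and
#' that vertex's index. Ties are broken by the lowest index and flagged.
#'
#' @param klm A [kl_matrix()].
#' @param direction `"rows"` (per A vertex, default) or `"cols"` (per B
#'   vertex).
#' @return A `min_kl_summary` tibble: `vertex` (original index), `min_kl`,
#'   `argmin` (original index in the other frame), `tie`.
#' @export
min_kl_summary <- function(klm, direction = c("rows", "cols")) {
  stopifnot(inherits(klm, "kl_matrix"))
  direction <- match.arg(direction)
  m <- if (direction == "rows") klm$matrix else t(klm$matrix)
  own <- if (direction == "rows") klm$rows_a else klm$cols_b
  other <- if (direction == "rows") klm$cols_b else klm$rows_a
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty KL matrix frame")
  arg <- max.col(-m, ties.method = "first")
  mn <- m[cbind(seq_len(nrow(m)), arg)]
  tie <- rowSums(m == mn) > 1L
  out <- tibble(vertex = own, min_kl = mn, argmin = other[arg], tie = tie)
  structure(out, class = c("min_kl_summary", class(out)), direction = direction)
}

#' Find homologue vertices for a source connectivity profile
#'
#' Computes the symmetric KL divergence of every non-excluded target vertex's
#' profile to a source region's average profile, and returns the set of
#' lowest-divergence vertices (below the `percentile_cut` percentile of the
#' divergence distribution) as the homologue mask.
#'
#' @param bp_target Target `connectivity_blueprint`.
#' @param source_profile Probability profile over the same tract frame
#'   (sums to 1; see [average_region_profile()]).
#' @param percentile_cut Percentile in (0, 100] defining the mask (default 5).
#' @param epsilon Floor before the logs.
#' @return A `homologue_result`: tibble (`vertex`, `kl`, `in_mask`) with
#'   attributes `cut_value` and `argmin` (best-matching vertex).
#' @export
find_homologue <- function(bp_target, source_profile, percentile_cut = 5,
                           epsilon = 1e-8) {
  stopifnot(inherits(bp_target, "connectivity_blueprint"))
  if (length(source_profile) != length(bp_target$tracts)) {
    abort("source profile is not on the blueprint's tract frame")
  }
  if (abs(sum(source_profile) - 1) > 1e-6) abort("source profile must sum to 1")
  assert_scalar_number(percentile_cut, "percentile_cut", lower = 1e-12, upper = 100)
  fb <- floored_rows(bp_target, epsilon)
  if (length(fb$rows) == 0L) abort("all target vertices are excluded")
  p <- pmax(source_profile / sum(source_profile), epsilon); p <- p / sum(p)
  Q <- fb$m
  lp <- log(p)
  kl_pq <- sum(p * lp) - as.vector(log(Q) %*% p)
  kl_qp <- rowSums(Q * log(Q)) - as.vector(Q %*% lp)
  d <- 0.5 * (kl_pq + kl_qp)
  d[d < 0] <- 0
  cut <- stats::quantile(d, percentile_cut / 100, names = FALSE, type = 7)
  out <- tibble(vertex = fb$rows, kl = d, in_mask = d <= cut)
  structure(out, class = c("homologue_result", class(out)),
            cut_value = cut, argmin = fb$rows[which.min(d)])
}

#' Project a per-vertex scalar map through a KL matrix
#'
#' Transfers a scalar map from the column frame (source brain) onto the row
#' frame (target brain) using blueprint divergences as the correspondence:
#' `mode = "argmin"` copies the value of each target vertex's
#' minimum-divergence source vertex; `mode = "softmax"` takes a weighted mean
#' with weights proportional to `exp(-KL / temperature)` (rows of weights sum
#' to 1). The default temperature is the median of the KL matrix, an adaptive
#' smoothing scale.
#'
#' @param klm A [kl_matrix()] (rows = target brain A, columns = source brain
#'   B).
#' @param source_map Numeric scalar map on the full source vertex frame (the
#'   matrix's `cols_b` index into it).
#' @param mode `"softmax"` (default) or `"argmin"`.
#' @param temperature Softmax temperature (> 0); default `median(klm$matrix)`.
#' @return A `projected_map` tibble: `vertex` (target index), `value`.
#' @export
project_scalar_map <- function(klm, source_map,
                               mode = c("softmax", "argmin"),
                               temperature = NULL) {
  stopifnot(inherits(klm, "kl_matrix"))
  mode <- match.arg(mode)
  if (max(klm$cols_b) > length(source_map)) {
    abort("source map is not on the KL matrix's source frame")
  }
  src <- source_map[klm$cols_b]
  vals <- if (mode == "argmin") {
    arg <- max.col(-klm$matrix, ties.method = "first")
    src[arg]
  } else {
    temperature <- temperature %||% stats::median(klm$matrix)
    assert_scalar_number(temperature, "temperature", lower = 1e-300)
    w <- exp(-klm$matrix / temperature)
    as.vector((w %*% src) / rowSums(w))
  }
  out <- tibble(vertex = klm$rows_a, value = vals)
  structure(out, class = c("projected_map", class(out)), mode = mode)
}

#' Compare a predicted scalar map with a measured one
#'
#' Pearson correlation over shared (non-excluded) vertices plus the per-vertex
#' absolute difference map. The correlation of a constant map is undefined and
#' returned as `NA` with a flag.
#'
#' @param predicted,measured Numeric vectors on one vertex frame, or
#'   `projected_map`s (matched on `vertex`).
#' @return A `map_comparison`: list with `r`, `constant_input` flag and
#'   `abs_difference` tibble (`vertex`, `abs_diff`).
#' @export
compare_maps <- function(predicted, measured) {
  if (inherits(predicted, "projected_map")) {
    vert <- predicted$vertex
    pv <- predicted$value
    mv <- if (inherits(measured, "projected_map")) {
      measured$value[match(vert, measured$vertex)]
    } else {
      measured[vert]
    }
  } else {
    if (length(predicted) != length(measured)) abort("maps are not on the same frame")
    vert <- seq_along(predicted)
    pv <- as.numeric(predicted); mv <- as.numeric(measured)
  }
  constant <- stats::sd(pv) == 0 || stats::sd(mv) == 0
  r <- if (constant) NA_real_ else stats::cor(pv, mv)
  structure(list(r = r, constant_input = constant,
                 abs_difference = tibble(vertex = vert, abs_diff = abs(pv - mv))),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> r = %s over %d vertices, mean |diff| = %.4g\n",
              if (is.na(x$r)) "NA (constant input)" else sprintf("%.4f", x$r),
              nrow(x$abs_difference), mean(x$abs_difference$abs_diff)))
  invisible(x)
}
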