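#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for tractblue result objects
#'
#' `tidy()` returns one row per elementary observation (blueprint entry, KL
#' pair, visited voxel, ...); `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tractblue-tidiers
NULL

#' @rdname tractblue-tidiers
#' @export
tidy.connectivity_blueprint <- function(x, ...) {
  tibble(
    vertex = rep(seq_len(nrow(x$matrix)), times = length(x$tracts)),
    tract = rep(x$tracts, each = nrow(x$matrix)),
    value = as.vector(x$matrix),
    excluded = rep(x$excluded, times = length(x$tracts))
  )
}

#' @rdname tractblue-tidiers
#' @export
glance.connectivity_blueprint <- function(x, ...) {
  inc <- !x$excluded
  tibble(n_vertices = nrow(x$matrix), n_tracts = length(x$tracts),
         n_excluded = sum(x$excluded),
         max_row_sum_error = if (x$normalised && any(inc)) {
           max(abs(rowSums(x$matrix[inc, , drop = FALSE]) - 1))
         } else NA_real_)
}

#' @rdname tractblue-tidiers
#' @export
tidy.kl_matrix <- function(x, ...) {
  tibble(vertex_a = rep(x$rows_a, times = ncol(x$matrix)),
         vertex_b = rep(x$cols_b, each = nrow(x$matrix)),
         kl = as.vector(x$matrix))
}

#' @rdname tractblue-tidiers
#' @export
glance.kl_matrix <- function(x, ...) {
  mins <- apply(x$matrix, 1L, min)
  tibble(n_a = nrow(x$matrix), n_b = ncol(x$matrix),
         median_kl = stats::median(x$matrix),
         median_min_kl = stats::median(mins), epsilon = x$epsilon)
}

#' @rdname tractblue-tidiers
#' @export
glance.min_kl_summary <- function(x, ...) {
  q <- stats::quantile(x$min_kl, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(n = nrow(x), q1 = q[1L], median = q[2L], q3 = q[3L],
         n_ties = sum(x$tie))
}

#' @rdname tractblue-tidiers
#' @export
tidy.path_distribution <- function(x, ...) {
  sel <- which(x$counts$values > 0)
  dims <- dim(x$counts$values)
  sel0 <- sel - 1L
  tibble(i = sel0 %% dims[1L],
         j = (sel0 %/% dims[1L]) %% dims[2L],
         k = sel0 %/% (dims[1L] * dims[2L]),
         count = x$counts$values[sel],
         fraction = x$counts$values[sel] / max(x$n_valid, 1L))
}

#' @rdname tractblue-tidiers
#' @export
glance.path_distribution <- function(x, ...) {
  tibble(tract = x$tract, n_seeded = x$n_seeded, n_valid = x$n_valid,
         valid_fraction = x$n_valid / max(x$n_seeded, 1L),
         n_voxels_visited = sum(x$counts$values > 0))
}

#' @rdname tractblue-tidiers
#' @export
glance.qc_report <- function(x, ...) {
  tibble(template = attr(x, "set_template"), n_checks = nrow(x),
         n_failing_checks = sum(!x$pass),
         n_failing_tracts = length(attr(x, "failing_tracts")))
}

#' @rdname tractblue-tidiers
#' @export
glance.map_comparison <- function(x, ...) {
  tibble(r = x$r, constant_input = x$constant_input,
         mean_abs_diff = mean(x$abs_difference$abs_diff),
         max_abs_diff = max(x$abs_difference$abs_diff))
}

# --- autoplot methods --------------------------------------------------------

#' Plot methods for tractblue results
#'
#' `autoplot()` gives the conventional view of each result type: blueprints as
#' vertex-by-tract heat maps, KL matrices as rasters, min-KL summaries as
#' boxplots, QC reports as metric tiles, and similarity tables as per-tract
#' mean +- sd dot ranges.
#'
#' @param object A tractblue result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tractblue-autoplot
NULL

#' @rdname tractblue-autoplot
#' @export
autoplot.connectivity_blueprint <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tract, y = .data$vertex,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "probability") +
    ggplot2::labs(x = "tract", y = "cortical vertex",
                  title = "Connectivity blueprint") +
    ggplot2::theme_minimal()
}

#' @rdname tractblue-autoplot
#' @export
autoplot.kl_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vertex_b, y = .data$vertex_a,
                                   fill = .data$kl)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "sym. KL (nats)", trans = "log10") +
    ggplot2::labs(x = "vertex (brain B)", y = "vertex (brain A)",
                  title = "Blueprint divergence matrix") +
    ggplot2::theme_minimal()
}

#' @rdname tractblue-autoplot
#' @export
autoplot.min_kl_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$min_kl)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "minimum symmetric KL (nats)",
                  title = "Best-match divergence distribution") +
    ggplot2::theme_minimal()
}

#' @rdname tractblue-autoplot
#' @export
autoplot.qc_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$tract,
                                   fill = .data$pass)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#4daf4a", `FALSE` = "#e41a1c")) +
    ggplot2::labs(x = "ROI (pair)", y = "tract", title = "Protocol QC battery") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname tractblue-autoplot
#' @export
autoplot.tract_similarity_table <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::group_by(.data$tract, .data$template) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = stats::sd(.data$r),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tract, y = .data$mean_r,
                                   colour = .data$template)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_r - dplyr::coalesce(.data$sd_r, 0),
      ymax = .data$mean_r + dplyr::coalesce(.data$sd_r, 0)),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "tract", y = "Pearson r vs reference template",
                  title = "Cross-template tract similarity") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
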