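#' Normalise a path distribution by its valid-streamline count
#'
#' Divides visitation counts by the total number of valid streamlines so each
#' voxel carries the fraction of valid streamlines visiting it. A distribution
#' with zero valid streamlines normalises to all zeros and is flagged.
#'
#' @param pd A `path_distribution` (from [run_protocol_tractography()]).
#' @return A `normalised_path_distribution`: fraction [volume_grid()] plus
#'   provenance (`tract`, `n_valid`, `degenerate` flag).
#' @export
normalise_path_distribution <- function(pd) {
  stopifnot(inherits(pd, "path_distribution"))
  if (any(pd$counts$values < 0)) abort("negative visitation counts")
  degenerate <- pd$n_valid == 0L
  vals <- if (degenerate) array(0, dim(pd$counts$values)) else pd$counts$values / pd$n_valid
  structure(list(
    fractions = volume_grid(vals, affine = pd$counts$affine),
    tract = pd$tract, n_valid = pd$n_valid, degenerate = degenerate
  ), class = "normalised_path_distribution")
}

#' @export
print.normalised_path_distribution <- function(x, ...) {
  cat(sprintf("<normalised_path_distribution>%s max fraction %.4g%s\n",
              if (is.na(x$tract)) "" else paste0(" [", x$tract, "]"),
              max(x$fractions$values),
              if (x$degenerate) " (degenerate: n_valid = 0)" else ""))
  invisible(x)
}

#' Threshold a normalised path distribution into a binary tract mask
#'
#' A voxel is active iff its visitation fraction is `>= level`; the default
#' level 0.001 is the standard 0.1% cut applied to valid-streamline-normalised
#' distributions. The `>=` tie rule means a voxel at exactly the threshold
#' survives.
#'
#' @param npd A `normalised_path_distribution`.
#' @param level Fraction threshold (default 0.001).
#' @return A [binary_mask()].
#' @export
threshold_binarise <- function(npd, level = 0.001) {
  stopifnot(inherits(npd, "normalised_path_distribution"))
  assert_scalar_number(level, "level", lower = 0)
  binary_mask(array((npd$fractions$values >= level) + 0, dim(npd$fractions$values)),
              affine = npd$fractions$affine)
}

#' Pearson correlation of two path distributions within a reference mask
#'
#' Both volumes are vectorised over the reference-mask voxels in the fixed
#' column-major voxel order and correlated. The reference mask is convention-
#' ally the thresholded reference-template distribution, so templates are
#' compared where the reference tract lives. Returns `NA` (with a warning
#' condition attribute) when either vector is constant.
#'
#' @param npd_a,npd_b `normalised_path_distribution`s on one grid.
#' @param reference_mask Non-empty [binary_mask()] on the same grid.
#' @return Pearson r (scalar; `NA` if undefined).
#' @export
path_correlation <- function(npd_a, npd_b, reference_mask) {
  assert_same_grid(npd_a$fractions, npd_b$fractions, "path distributions")
  assert_same_grid(npd_a$fractions, reference_mask, "distribution and reference mask")
  sel <- which(reference_mask$values != 0)
  if (length(sel) == 0L) abort("reference mask is empty")
  a <- npd_a$fractions$values[sel]
  b <- npd_b$fractions$values[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(NA_real_, constant_input = TRUE))
  }
  stats::cor(a, b)
}

#' Median FA / MD within a tract mask
#'
#' @param mask A non-empty [binary_mask()] (e.g. from [threshold_binarise()]).
#' @param fa,md [volume_grid()]s of FA and MD on the same grid.
#' @return A one-row tibble: `median_fa`, `median_md`, `n_voxels`. An empty
#'   mask yields `NA` medians with `n_voxels = 0` (flagged missing, not an
#'   error).
#' @export
tract_microstructure <- function(mask, fa, md) {
  assert_same_grid(mask, fa, "mask and FA")
  assert_same_grid(mask, md, "mask and MD")
  sel <- which(mask$values != 0)
  if (length(sel) == 0L) {
    return(tibble(median_fa = NA_real_, median_md = NA_real_, n_voxels = 0L))
  }
  tibble(median_fa = stats::median(fa$values[sel]),
         median_md = stats::median(md$values[sel]),
         n_voxels = length(sel))
}

#' Signed percent difference against a reference value
#'
#' `100 * (value - reference) / reference`, the convention used when comparing
#' per-tract FA/MD medians between template spaces.
#'
#' @param value,reference Numeric (vectorised); `reference` must be non-zero.
#' @return Signed percent difference.
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) abort("`reference` must be non-zero")
  100 * (value - reference) / reference
}

#' Population percentage atlas from per-subject tract masks
#'
#' Averages binarised tract masks across subjects and scales to percent: each
#' voxel carries the percentage of subjects in which the tract is present
#' there. Values are multiples of `100 / N` in `[0, 100]`.
#'
#' @param masks List of [binary_mask()]s on a shared grid (N >= 1).
#' @return A [volume_grid()] of percentages.
#' @export
population_atlas <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  for (m in masks[-1L]) assert_same_grid(masks[[1L]], m, "atlas masks")
  acc <- Reduce(`+`, lapply(masks, function(m) m$values))
  volume_grid(100 * acc / length(masks), affine = masks[[1L]]$affine)
}

#' Cross-template tract similarity table
#'
#' Convenience builder for the per-(tract, subject, template-pair) Pearson
#' correlation table: takes a tibble of normalised path distributions and
#' correlates each non-reference template against the reference within the
#' reference tract mask (the reference distribution thresholded at `level`).
#'
#' @param runs Tibble with columns `tract`, `subject`, `template`, `npd`
#'   (list-column of `normalised_path_distribution`s).
#' @param reference_template Name of the reference template space.
#' @param level Threshold defining the reference mask (default 0.001).
#' @param threshold_values Correlate thresholded values (values below `level`
#'   set to zero) rather than raw fractions (default TRUE).
#' @return A `tract_similarity_table` tibble: `tract`, `subject`, `template`,
#'   `r`.
#' @export
tract_similarity_table <- function(runs, reference_template, level = 0.001,
                                   threshold_values = TRUE) {
  runs <- as_tibble(runs)
  stopifnot(all(c("tract", "subject", "template", "npd") %in% names(runs)))
  refs <- dplyr::filter(runs, .data$template == reference_template)
  others <- dplyr::filter(runs, .data$template != reference_template)
  out <- purrr::pmap_dfr(others, function(tract, subject, template, npd) {
    ref <- refs$npd[refs$tract == tract & refs$subject == subject][[1L]]
    mask <- threshold_binarise(ref, level)
    a <- ref; b <- npd
    if (threshold_values) {
      a$fractions$values[a$fractions$values < level] <- 0
      b$fractions$values[b$fractions$values < level] <- 0
    }
    tibble(tract = tract, subject = subject, template = template,
           r = as.numeric(path_correlation(a, b, mask)))
  })
  structure(out, class = c("tract_similarity_table", class(out)),
            reference_template = reference_template)
}

#' Cross-template microstructure table
#'
#' Median FA/MD per (tract, subject, template) from thresholded tract masks,
#' with signed percent differences against the reference template.
#'
#' @inheritParams tract_similarity_table
#' @param fa,md [volume_grid()]s shared by all runs (per-subject maps can be
#'   passed by calling per subject).
#' @return A `microstructure_table` tibble: tract, subject, template,
#'   median_fa, median_md, pct_diff_fa, pct_diff_md.
#' @export
microstructure_table <- function(runs, fa, md, reference_template, level = 0.001) {
  runs <- as_tibble(runs)
  vals <- purrr::pmap_dfr(runs, function(tract, subject, template, npd) {
    ms <- tract_microstructure(threshold_binarise(npd, level), fa, md)
    tibble(tract = tract, subject = subject, template = template,
           median_fa = ms$median_fa, median_md = ms$median_md)
  })
  ref <- dplyr::filter(vals, .data$template == reference_template) |>
    dplyr::select("tract", "subject", ref_fa = "median_fa", ref_md = "median_md")
  out <- vals |>
    dplyr::left_join(ref, by = c("tract", "subject")) |>
    dplyr::mutate(pct_diff_fa = percent_difference(.data$median_fa, .data$ref_fa),
                  pct_diff_md = percent_difference(.data$median_md, .data$ref_md)) |>
    dplyr::select(-"ref_fa", -"ref_md")
  structure(out, class = c("microstructure_table", class(out)),
            reference_template = reference_template)
}
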