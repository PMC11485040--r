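#' Pipeline configuration
#'
#' One flat container for every stage parameter: the tracking settings, the
#' 0.1% path-distribution threshold, the 2 mm coarse grid, the KL epsilon and
#' projection settings, and the master seed. Validation reports the offending
#' field by name. Configs round-trip through a plain-text file
#' (`[section]` / `key = value`) unchanged.
#'
#' @param tracking A [tracking_config()].
#' @param threshold_level Path-distribution binarisation level (default 0.001).
#' @param coarse_voxel_mm Coarse grid voxel size for blueprints (default 2).
#' @param epsilon KL floor (default 1e-8).
#' @param projection_mode `"softmax"` or `"argmin"`.
#' @param projection_temperature Softmax temperature (`NA` = median of the KL
#'   matrix).
#' @param percentile_cut Homologue mask percentile (default 5).
#' @param seed Master seed; stage seeds derive from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(tracking = tracking_config(),
                            threshold_level = 0.001,
                            coarse_voxel_mm = 2,
                            epsilon = 1e-8,
                            projection_mode = "softmax",
                            projection_temperature = NA_real_,
                            percentile_cut = 5,
                            seed = 1L) {
  stopifnot(inherits(tracking, "tracking_config"))
  assert_scalar_number(threshold_level, "threshold_level", lower = 0, upper = 1)
  assert_scalar_number(coarse_voxel_mm, "coarse_voxel_mm", lower = 1e-9)
  assert_scalar_number(epsilon, "epsilon", lower = 1e-300, upper = 1e-2)
  if (!projection_mode %in% c("softmax", "argmin")) {
    abort("`projection_mode` must be 'softmax' or 'argmin'")
  }
  if (!is.na(projection_temperature)) {
    assert_scalar_number(projection_temperature, "projection_temperature", lower = 1e-300)
  }
  assert_scalar_number(percentile_cut, "percentile_cut", lower = 1e-12, upper = 100)
  assert_scalar_number(seed, "seed", lower = -2^31, upper = 2^31)
  structure(list(tracking = tracking, threshold_level = threshold_level,
                 coarse_voxel_mm = coarse_voxel_mm, epsilon = epsilon,
                 projection_mode = projection_mode,
                 projection_temperature = projection_temperature,
                 percentile_cut = percentile_cut, seed = as.integer(seed)),
            class = "pipeline_config")
}

fmt_cfg_value <- function(v) {
  if (is.character(v)) v else format(v, digits = 17, scientific = TRUE)
}

#' Write / read a pipeline config as plain text
#'
#' `[section]` headers with `key = value` lines; the `[tracking]` section maps
#' onto [tracking_config()], everything else lives under `[analysis]`.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  tr <- unclass(config$tracking)
  an <- unclass(config)[setdiff(names(unclass(config)), "tracking")]
  lines <- c(
    "[tracking]",
    sprintf("%s = %s", names(tr), vapply(tr, fmt_cfg_value, character(1))),
    "",
    "[analysis]",
    sprintf("%s = %s", names(an), vapply(an, fmt_cfg_value, character(1)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  vals <- list(tracking = list(), analysis = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) abort(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1L])
    raw <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(raw))
    vals[[section]][[key]] <- if (is.na(num) && raw != "NA") raw else num
  }
  tracking <- do.call(tracking_config, vals$tracking)
  do.call(pipeline_config, c(list(tracking = tracking), vals$analysis))
}

input_digest <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
    return(rlang::hash(lapply(files, function(f) rlang::hash_file(f))))
  }
  rlang::hash_file(path)
}

pipeline_stages <- c("phantom", "track", "protoqc", "tractcompare", "atlas",
                     "blueprint", "compare", "homologue", "project")

#' Run one pipeline stage file-to-file
#'
#' Thin orchestration over the package's functions: each stage reads only its
#' declared input files, writes new files under `out_dir` (inputs are never
#' mutated), and appends a provenance record (stage, config hash, seed, input
#' digests, outputs) to `manifest.json` in `out_dir`. Identical invocations
#' produce identical outputs.
#'
#' Stages and their inputs (all paths):
#' \describe{
#'   \item{phantom}{none (optional `seed` override) — exports a twin pair.}
#'   \item{track}{`fibres` dir, `protocols` dir — per-tract path distributions.}
#'   \item{protoqc}{`protocols` dir — QC report TSV/JSON.}
#'   \item{tractcompare}{`reference` and `other` track dirs — similarity TSV.}
#'   \item{atlas}{`tracks` = character vector of track dirs (subjects) —
#'     population percentage atlas per tract.}
#'   \item{blueprint}{`fibres`, `surface`, `brain_mask`, `tracks` dir —
#'     blueprint TSV.}
#'   \item{compare}{`blueprint_a`, `blueprint_b` TSVs — min-KL summary TSV.}
#'   \item{homologue}{`blueprint_a`, `blueprint_b` TSVs, `parcels` scalar GIFTI
#'     for brain A, `parcel` id — homologue TSV for the parcel's profile.}
#'   \item{project}{`blueprint_a`, `blueprint_b` TSVs, `scalar` GIFTI on B —
#'     projected map GIFTI + TSV on A.}
#' }
#'
#' @param name Stage name (see above).
#' @param config A [pipeline_config()].
#' @param inputs Named list of input paths / values.
#' @param out_dir Output directory (created if needed).
#' @param log Log connection behaviour: messages go to `stderr` and to
#'   `<out_dir>/<stage>.log`.
#' @return Named list of output paths, invisibly.
#' @export
run_stage <- function(name, config = pipeline_config(), inputs = list(),
                      out_dir = ".") {
  if (!name %in% pipeline_stages) {
    abort(sprintf("unknown stage '%s' (expected one of: %s)", name,
                  paste(pipeline_stages, collapse = ", ")))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, paste0(name, ".log"))
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", name, sprintf(fmt, ...))
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  logf("start; config hash %s; seed %d", rlang::hash(config), config$seed)

  outputs <- switch(name,
    phantom = stage_phantom(config, inputs, out_dir, logf),
    track = stage_track(config, inputs, out_dir, logf),
    protoqc = stage_protoqc(config, inputs, out_dir, logf),
    tractcompare = stage_tractcompare(config, inputs, out_dir, logf),
    atlas = stage_atlas(config, inputs, out_dir, logf),
    blueprint = stage_blueprint(config, inputs, out_dir, logf),
    compare = stage_compare(config, inputs, out_dir, logf),
    homologue = stage_homologue(config, inputs, out_dir, logf),
    project = stage_project(config, inputs, out_dir, logf)
  )

  digests <- lapply(Filter(function(x) is.character(x) && length(x) == 1L &&
                             (file.exists(x) || dir.exists(x)), inputs),
                    input_digest)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  manifest[[length(manifest) + 1L]] <- list(
    stage = name, config_hash = rlang::hash(config), seed = config$seed,
    inputs = digests, outputs = unname(unlist(outputs))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  logf("done; %d output(s)", length(unlist(outputs)))
  invisible(outputs)
}

stage_phantom <- function(config, inputs, out_dir, logf) {
  seed <- inputs$seed %||% config$seed
  spec <- phantom_spec(seed = seed)
  tp <- make_twin_pair(spec, seed = derive_seed(seed, "stage-phantom"))
  da <- file.path(out_dir, "brainA"); db <- file.path(out_dir, "brainB")
  export_phantom(tp$A, da)
  export_phantom(tp$B, db)
  write_warp(tp$warp, file.path(out_dir, "warp_B_to_A.nii.gz"))
  jsonlite::write_json(list(correspondence = tp$correspondence),
                       file.path(out_dir, "correspondence.json"))
  logf("exported twin pair (%d vertices)", length(tp$correspondence))
  list(brainA = da, brainB = db)
}

stage_track <- function(config, inputs, out_dir, logf) {
  field <- read_fiber_field(inputs$fibres)
  pset <- read_protocol_set(inputs$protocols)
  cfg <- config$tracking
  out <- list()
  for (p in pset$protocols) {
    pd <- run_protocol_tractography(field, p, pset$brain_mask, cfg)
    f <- file.path(out_dir, paste0(p$abbreviation, "_paths.nii.gz"))
    write_path_distribution(pd, f)
    logf("tract %s: %d/%d valid", p$abbreviation, pd$n_valid, pd$n_seeded)
    out[[p$abbreviation]] <- f
  }
  out
}

stage_protoqc <- function(config, inputs, out_dir, logf) {
  pset <- read_protocol_set(inputs$protocols)
  rep <- qc_protocol_set(pset)
  tsv <- file.path(out_dir, "protocol_qc.tsv")
  utils::write.table(as_tibble(rep), tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(failing_tracts = attr(rep, "failing_tracts"),
                            thresholds = attr(rep, "thresholds")),
                       file.path(out_dir, "protocol_qc.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("%d failing tract(s)", length(attr(rep, "failing_tracts")))
  list(tsv = tsv)
}

read_track_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "_paths\\.nii\\.gz$", full.names = TRUE))
  pds <- lapply(files, read_path_distribution)
  names(pds) <- vapply(pds, function(p) p$tract, character(1))
  pds
}

stage_tractcompare <- function(config, inputs, out_dir, logf) {
  ref <- read_track_dir(inputs$reference)
  oth <- read_track_dir(inputs$other)
  runs <- dplyr::bind_rows(
    tibble(tract = names(ref), subject = "s1", template = "reference",
           npd = lapply(ref, normalise_path_distribution)),
    tibble(tract = names(oth), subject = "s1", template = "other",
           npd = lapply(oth, normalise_path_distribution))
  )
  tab <- tract_similarity_table(runs, "reference", level = config$threshold_level)
  tsv <- file.path(out_dir, "tract_similarity.tsv")
  utils::write.table(as_tibble(tab), tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  logf("median r = %.3f", stats::median(tab$r))
  list(tsv = tsv)
}

stage_atlas <- function(config, inputs, out_dir, logf) {
  dirs <- inputs$tracks
  per_subj <- lapply(dirs, read_track_dir)
  tracts <- names(per_subj[[1L]])
  out <- list()
  for (tr in tracts) {
    masks <- lapply(per_subj, function(pds) {
      threshold_binarise(normalise_path_distribution(pds[[tr]]),
                         config$threshold_level)
    })
    atl <- population_atlas(masks)
    f <- file.path(out_dir, paste0(tr, "_atlas.nii.gz"))
    write_volume(atl, f)
    out[[tr]] <- f
  }
  logf("%d tract atlases over %d subjects", length(tracts), length(dirs))
  out
}

stage_blueprint <- function(config, inputs, out_dir, logf) {
  field <- read_fiber_field(inputs$fibres)
  surface <- read_surface(inputs$surface)
  brain <- as_binary_mask(read_volume(inputs$brain_mask))
  pds <- read_track_dir(inputs$tracks)
  npds <- lapply(pds, normalise_path_distribution)
  tmx <- build_tract_matrix(npds, brain, config$coarse_voxel_mm)
  conn <- run_surface_seeded_tractography(field, surface, brain,
                                          config$coarse_voxel_mm, config$tracking)
  bp <- build_blueprint(conn, tmx)
  tsv <- file.path(out_dir, "blueprint.tsv")
  write_blueprint(bp, tsv)
  logf("blueprint %d x %d, %d excluded", nrow(bp$matrix), length(bp$tracts),
       sum(bp$excluded))
  list(tsv = tsv)
}

stage_compare <- function(config, inputs, out_dir, logf) {
  a <- read_blueprint(inputs$blueprint_a)
  b <- read_blueprint(inputs$blueprint_b)
  klm <- kl_matrix(a, b, epsilon = config$epsilon)
  summ <- min_kl_summary(klm)
  tsv <- file.path(out_dir, "min_kl.tsv")
  utils::write.table(as_tibble(summ), tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- glance(summ)
  jsonlite::write_json(as.list(g), file.path(out_dir, "min_kl_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("median min-KL %.4g nats", g$median)
  list(tsv = tsv)
}

stage_homologue <- function(config, inputs, out_dir, logf) {
  a <- read_blueprint(inputs$blueprint_a)
  b <- read_blueprint(inputs$blueprint_b)
  parcels <- read_surface_scalar(inputs$parcels)
  region <- which(parcels == inputs$parcel)
  prof <- average_region_profile(a, region)
  hom <- find_homologue(b, prof, percentile_cut = config$percentile_cut,
                        epsilon = config$epsilon)
  tsv <- file.path(out_dir, sprintf("homologue_parcel%s.tsv", inputs$parcel))
  utils::write.table(as_tibble(hom), tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  logf("homologue mask: %d vertices below %.4g nats", sum(hom$in_mask),
       attr(hom, "cut_value"))
  list(tsv = tsv)
}

stage_project <- function(config, inputs, out_dir, logf) {
  a <- read_blueprint(inputs$blueprint_a)
  b <- read_blueprint(inputs$blueprint_b)
  scalar_b <- read_surface_scalar(inputs$scalar)
  klm <- kl_matrix(a, b, epsilon = config$epsilon)
  temp <- if (is.na(config$projection_temperature)) NULL else config$projection_temperature
  pm <- project_scalar_map(klm, scalar_b, mode = config$projection_mode,
                           temperature = temp)
  full <- rep(NA_real_, nrow(a$matrix))
  full[pm$vertex] <- pm$value
  full[is.na(full)] <- 0
  gii <- file.path(out_dir, "projected_map.gii")
  write_surface_scalar(full, gii)
  tsv <- file.path(out_dir, "projected_map.tsv")
  utils::write.table(as_tibble(pm), tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  logf("projected %d vertices (%s mode)", nrow(pm), config$projection_mode)
  list(gii = gii, tsv = tsv)
}
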