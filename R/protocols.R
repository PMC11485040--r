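#' Tractography protocol containers
#'
#' A `protocol_rois` bundle holds the masks constraining one tract's
#' tractography: a seed, zero or more waypoint masks (unordered by default), an
#' optional exclusion mask (touching it rejects the streamline), an optional
#' stop mask (entering it terminates propagation) and an optional target mask
#' (an inclusion criterion like the waypoints). A `tract_protocol` adds tract
#' identity (name, abbreviation, category, hemisphere); a `protocol_set`
#' collects protocols defined on one template grid together with that
#' template's brain mask.
#'
#' @param seed A [binary_mask()]; must be non-empty.
#' @param waypoints Named list of [binary_mask()]s (may be empty).
#' @param exclusion,stop,target Optional [binary_mask()]s.
#' @return A `protocol_rois` object.
#' @export
protocol_rois <- function(seed, waypoints = list(), exclusion = NULL,
                          stop = NULL, target = NULL) {
  stopifnot(is_binary_mask(seed))
  if (n_active(seed) == 0L) abort("seed mask is empty")
  for (m in waypoints) assert_same_grid(seed, m, "protocol ROIs")
  for (m in Filter(Negate(is.null), list(exclusion, stop, target))) {
    assert_same_grid(seed, m, "protocol ROIs")
  }
  structure(list(seed = seed, waypoints = waypoints, exclusion = exclusion,
                 stop = stop, target = target),
            class = "protocol_rois")
}

#' @rdname protocol_rois
#' @param name,abbreviation,category,hemisphere Tract identity; `category` is
#'   one of association/commissural/limbic/projection and commissural tracts
#'   must have `hemisphere = "none"`.
#' @param rois A `protocol_rois` (may be `NULL` for an inventory stub).
#' @param provenance Character vector of applied-edit descriptions.
#' @export
tract_protocol <- function(name, abbreviation, category, hemisphere,
                           rois = NULL, provenance = character()) {
  category <- match.arg(category, c("association", "commissural", "limbic", "projection"))
  hemisphere <- match.arg(hemisphere, c("left", "right", "none"))
  if ((category == "commissural") != (hemisphere == "none")) {
    abort("commissural tracts (and only those) must have hemisphere 'none'")
  }
  structure(list(name = name, abbreviation = abbreviation, category = category,
                 hemisphere = hemisphere, rois = rois, provenance = provenance),
            class = "tract_protocol")
}

#' @rdname protocol_rois
#' @param template Template-space name.
#' @param protocols Named list of `tract_protocol`s (names = abbreviations).
#' @param brain_mask [binary_mask()] of the template grid.
#' @export
protocol_set <- function(template, protocols, brain_mask) {
  abbrevs <- vapply(protocols, function(p) p$abbreviation, character(1))
  if (anyDuplicated(abbrevs)) abort("duplicate abbreviation in protocol set")
  names(protocols) <- abbrevs
  structure(list(template = template, protocols = protocols,
                 brain_mask = brain_mask),
            class = "protocol_set")
}

#' @export
print.protocol_set <- function(x, ...) {
  cats <- table(vapply(x$protocols, function(p) p$category, character(1)))
  cat(sprintf("<protocol_set> template '%s': %d protocols (%s)\n",
              x$template, length(x$protocols),
              paste(names(cats), cats, sep = "=", collapse = ", ")))
  invisible(x)
}

#' The 42-tract reference inventory
#'
#' The standard XTRACT white-matter tract inventory: 23 tract types of which
#' 19 are bilateral (separate left/right protocols) and 4 commissural, giving
#' 42 protocols after bilateral expansion.
#'
#' @return A tibble with columns `name`, `abbreviation`, `category`.
#' @export
xtract_inventory <- function() {
  tibble::tribble(
    ~name,                                        ~abbreviation, ~category,
    "Arcuate fasciculus",                          "af",    "association",
    "Frontal aslant tract",                        "fa",    "association",
    "Inferior fronto-occipital fasciculus",        "ifo",   "association",
    "Inferior longitudinal fasciculus",            "ilf",   "association",
    "Middle longitudinal fasciculus",              "mdlf",  "association",
    "Superior longitudinal fasciculus I",          "slf1",  "association",
    "Superior longitudinal fasciculus II",         "slf2",  "association",
    "Superior longitudinal fasciculus III",        "slf3",  "association",
    "Uncinate fasciculus",                         "uf",    "association",
    "Vertical occipital fasciculus",               "vof",   "association",
    "Anterior commissure",                         "ac",    "commissural",
    "Forceps major",                               "fma",   "commissural",
    "Forceps minor",                               "fmi",   "commissural",
    "Middle cerebellar peduncle",                  "mcp",   "commissural",
    "Cingulum bundle: dorsal section",             "cbd",   "limbic",
    "Cingulum bundle: perigenual section",         "cbp",   "limbic",
    "Cingulum bundle: temporal section",           "cbt",   "limbic",
    "Fornix",                                      "fx",    "limbic",
    "Acoustic radiation",                          "ar",    "projection",
    "Anterior thalamic radiation",                 "atr",   "projection",
    "Corticospinal tract",                         "cst",   "projection",
    "Optic radiation",                             "or",    "projection",
    "Superior thalamic radiation",                 "str",   "projection"
  )
}

#' Expand a tract-type inventory into per-hemisphere protocol stubs
#'
#' Every non-commissural tract type yields a left and a right protocol stub;
#' commissural types yield a single stub with hemisphere `"none"`. The
#' expansion is deterministic and count-exact:
#' `2 * n_bilateral + n_commissural`.
#'
#' @param table Data frame with columns `name`, `abbreviation`, `category`.
#' @return A tibble of stubs: `name`, `abbreviation` (suffixed `_l`/`_r` for
#'   bilateral tracts), `category`, `hemisphere`, `type_abbreviation`.
#' @examples
#' nrow(expand_tract_inventory(xtract_inventory())) # 42
#' @export
expand_tract_inventory <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("name", "abbreviation", "category") %in% names(table)))
  if (nrow(table) == 0L) {
    return(tibble(name = character(), abbreviation = character(),
                  category = character(), hemisphere = character(),
                  type_abbreviation = character()))
  }
  bad <- setdiff(unique(table$category),
                 c("association", "commissural", "limbic", "projection"))
  if (length(bad)) abort(sprintf("invalid category: %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(table$abbreviation)) abort("duplicate abbreviation in inventory")
  out <- purrr::pmap_dfr(table, function(name, abbreviation, category) {
    if (category == "commissural") {
      tibble(name = name, abbreviation = abbreviation, category = category,
             hemisphere = "none", type_abbreviation = abbreviation)
    } else {
      tibble(
        name = paste0(name, c(" (left)", " (right)")),
        abbreviation = paste0(abbreviation, c("_l", "_r")),
        category = category, hemisphere = c("left", "right"),
        type_abbreviation = abbreviation
      )
    }
  })
  out
}

# --- warp transfer -----------------------------------------------------------

roi_slots <- function(p) {
  slots <- list(seed = p$rois$seed)
  if (length(p$rois$waypoints)) {
    wp <- p$rois$waypoints
    names(wp) <- paste0("waypoint_", names(wp) %||% seq_along(wp))
    slots <- c(slots, wp)
  }
  for (nm in c("exclusion", "stop", "target")) {
    if (!is.null(p$rois[[nm]])) slots[[nm]] <- p$rois[[nm]]
  }
  slots
}

set_roi_slot <- function(rois, slot, mask) {
  if (startsWith(slot, "waypoint_")) {
    rois$waypoints[[sub("^waypoint_", "", slot)]] <- mask
  } else {
    rois[[slot]] <- mask
  }
  rois
}

#' Transfer a protocol set to a new template grid through a warp
#'
#' Every ROI of every protocol is resampled with [apply_warp_to_mask()]; ROIs
#' that come out empty are flagged (`empty_after_warp` attribute) rather than
#' dropped, mirroring the QC-first workflow for protocol transfer between
#' template spaces.
#'
#' @param set A [protocol_set()] on the source grid.
#' @param warp A [warp_field()] whose target grid is the new template.
#' @param target_brain_mask [binary_mask()] of the new template grid.
#' @param template_name Name for the new template space.
#' @return A [protocol_set()] on the target grid.
#' @export
warp_protocol_set <- function(set, warp, target_brain_mask,
                              template_name = paste0(set$template, "_warped")) {
  stopifnot(inherits(set, "protocol_set"), inherits(warp, "warp_field"))
  if (!all(dim(target_brain_mask$values) == warp$dims)) {
    abort("target brain mask is not on the warp target grid")
  }
  empties <- character()
  protos <- lapply(set$protocols, function(p) {
    slots <- roi_slots(p)
    rois <- p$rois
    for (nm in names(slots)) {
      wm <- apply_warp_to_mask(slots[[nm]], warp)
      if (n_active(wm) == 0L && n_active(slots[[nm]]) > 0L) {
        empties <<- c(empties, paste0(p$abbreviation, ":", nm))
      }
      rois <- set_roi_slot(rois, nm, wm)
    }
    # keep the (possibly empty-after-warp) ROIs; QC decides what to do
    p$rois <- structure(list(seed = rois$seed, waypoints = rois$waypoints,
                             exclusion = rois$exclusion, stop = rois$stop,
                             target = rois$target),
                        class = "protocol_rois")
    p
  })
  out <- protocol_set(template = template_name, protocols = protos,
                      brain_mask = target_brain_mask)
  attr(out, "empty_after_warp") <- empties
  out
}

# --- QC ----------------------------------------------------------------------

#' Quality-control battery for a protocol set
#'
#' Computes, per tract, the three QC families that decide whether a protocol
#' needs revision after transfer between template spaces: pairwise ROI overlap
#' voxel counts, out-of-brain voxel counts per ROI, and a left-right asymmetry
#' score per ROI of bilateral pairs (1 - Dice between the mirrored left ROI
#' and its right counterpart). A protocol fails when any metric exceeds its
#' threshold; by default only seed-exclusion and target-exclusion overlaps are
#' hard failures (waypoints may legitimately touch other ROIs).
#'
#' @param set A [protocol_set()].
#' @param midline_axis,midline_coordinate Axis-aligned world mirror plane for
#'   asymmetry scoring (defaults to the sagittal mid-plane of the grid).
#' @param thresholds Named list: `overlap` (max allowed seed/target-exclusion
#'   overlap voxels, default 0), `out_of_brain` (max voxels outside the brain
#'   mask, default 0), `asymmetry` (max 1 - Dice, default 0.5).
#' @return A `qc_report`: a tibble (tract, roi, metric, value, threshold,
#'   hard_fail, pass) with attributes `failing_tracts` and `set_template`.
#' @export
qc_protocol_set <- function(set, midline_axis = 1L, midline_coordinate = NULL,
                            thresholds = list()) {
  stopifnot(inherits(set, "protocol_set"))
  thr <- utils::modifyList(list(overlap = 0, out_of_brain = 0, asymmetry = 0.5),
                           thresholds)
  brain <- set$brain_mask
  if (is.null(midline_coordinate)) {
    dims <- dim(brain$values)
    midline_coordinate <- (voxel_to_world(brain, matrix(c(0, 0, 0), 1L)) +
                             voxel_to_world(brain, matrix(dims - 1L, 1L)))[midline_axis] / 2
  }
  rows <- list()
  add_row <- function(tract, roi, metric, value, threshold, hard_fail) {
    rows[[length(rows) + 1L]] <<- tibble(
      tract = tract, roi = roi, metric = metric, value = value,
      threshold = threshold, hard_fail = hard_fail,
      pass = value <= threshold | !hard_fail
    )
  }

  by_abbrev <- set$protocols
  for (p in by_abbrev) {
    slots <- roi_slots(p)
    nms <- names(slots)
    # overlap counts for every ROI pair; only *-exclusion pairs hard-fail
    if (length(nms) >= 2L) {
      prs <- utils::combn(nms, 2L)
      for (cix in seq_len(ncol(prs))) {
        a <- prs[1L, cix]; b <- prs[2L, cix]
        ov <- sum(slots[[a]]$values * slots[[b]]$values)
        hard <- ("exclusion" %in% c(a, b)) && any(c(a, b) %in% c("seed", "target"))
        add_row(p$abbreviation, paste(a, b, sep = "*"), "overlap", ov,
                thr$overlap, hard)
      }
    }
    for (nm in nms) {
      oob <- sum(slots[[nm]]$values * (1 - brain$values))
      add_row(p$abbreviation, nm, "out_of_brain", oob, thr$out_of_brain, TRUE)
    }
  }

  # asymmetry for bilateral pairs, matched by hemisphere field
  lefts <- Filter(function(p) p$hemisphere == "left", by_abbrev)
  for (p in lefts) {
    partner_ab <- sub("_l$", "_r", p$abbreviation)
    q <- by_abbrev[[partner_ab]]
    if (is.null(q) || q$hemisphere != "right") {
      abort(sprintf("bilateral tract '%s' has no contralateral partner", p$abbreviation))
    }
    sl <- roi_slots(p); sr <- roi_slots(q)
    for (nm in intersect(names(sl), names(sr))) {
      ml <- mirror_mask(sl[[nm]], midline_axis, midline_coordinate)
      inter <- sum(ml$values * sr[[nm]]$values)
      denom <- n_active(ml) + n_active(sr[[nm]])
      asym <- if (denom == 0) 0 else 1 - 2 * inter / denom
      add_row(p$abbreviation, nm, "asymmetry", asym, thr$asymmetry, TRUE)
    }
  }

  report <- dplyr::bind_rows(rows)
  failing <- sort(unique(report$tract[!report$pass]))
  structure(report, class = c("qc_report", class(report)),
            failing_tracts = failing, set_template = set$template,
            thresholds = thr)
}

#' @export
print.qc_report <- function(x, ...) {
  failing <- attr(x, "failing_tracts")
  cat(sprintf("<qc_report> template '%s': %d checks, %d failing tract(s)%s\n",
              attr(x, "set_template"), nrow(x), length(failing),
              if (length(failing)) paste0(" [", paste(failing, collapse = ", "), "]") else ""))
  NextMethod()
}

# --- revision operators ------------------------------------------------------

# 6-connectivity binary dilation by one voxel.
dilate1 <- function(values) {
  d <- dim(values)
  out <- values
  out[-1, , ] <- pmax(out[-1, , ], values[-d[1L], , ])
  out[-d[1L], , ] <- pmax(out[-d[1L], , ], values[-1, , ])
  out[, -1, ] <- pmax(out[, -1, ], values[, -d[2L], ])
  out[, -d[2L], ] <- pmax(out[, -d[2L], ], values[, -1, ])
  out[, , -1] <- pmax(out[, , -1], values[, , -d[3L]])
  out[, , -d[3L]] <- pmax(out[, , -d[3L]], values[, , -1])
  out
}

#' Apply deterministic revision edits to a tract protocol
#'
#' Mask-algebra operators covering the manual protocol revisions used when a
#' warped protocol fails QC: adding or subtracting a mask from an ROI,
#' replacing an ROI with the mirrored contralateral ROI, and eroding an ROI by
#' one voxel along its interface with another mask. Every edit is recorded in
#' the protocol's provenance.
#'
#' @param protocol A [tract_protocol()].
#' @param edits List of edits; each is a list with `op` (one of `"add_mask"`,
#'   `"subtract_mask"`, `"mirror_from_contralateral"`,
#'   `"erode_interface"`), `roi` (slot name: `"seed"`, `"target"`,
#'   `"exclusion"`, `"stop"`, or `"waypoint_<name>"`), plus per-op fields:
#'   `mask` (add/subtract), `contralateral` + `midline_axis` +
#'   `midline_coordinate` (mirror), `interface` (erode: the mask whose border
#'   voxels are shaved off the ROI).
#' @return The revised [tract_protocol()] (provenance updated).
#' @export
apply_revision <- function(protocol, edits) {
  stopifnot(inherits(protocol, "tract_protocol"))
  for (e in edits) {
    op <- match.arg(e$op, c("add_mask", "subtract_mask",
                            "mirror_from_contralateral", "erode_interface"))
    slots <- roi_slots(protocol)
    roi <- slots[[e$roi]]
    if (is.null(roi)) abort(sprintf("protocol has no ROI slot '%s'", e$roi))
    new_vals <- switch(op,
      add_mask = pmin(roi$values + e$mask$values, 1),
      subtract_mask = pmax(roi$values - e$mask$values, 0),
      mirror_from_contralateral = {
        mirror_mask(e$contralateral, e$midline_axis, e$midline_coordinate)$values
      },
      # shave off the ROI voxels 6-adjacent to (or inside) the interface mask
      erode_interface = roi$values * (1 - pmin(dilate1(e$interface$values), 1))
    )
    new_mask <- binary_mask(array(new_vals, dim(roi$values)), affine = roi$affine)
    if (e$roi == "seed" && n_active(new_mask) == 0L) {
      abort(sprintf("edit '%s' would empty the seed of '%s'", op, protocol$abbreviation))
    }
    protocol$rois <- set_roi_slot(protocol$rois, e$roi, new_mask)
    protocol$provenance <- c(protocol$provenance, sprintf("%s(%s)", op, e$roi))
  }
  protocol
}

# --- directory layout --------------------------------------------------------

#' Write / read a protocol set as a directory tree
#'
#' One directory per tract holding `seed.nii.gz`, `target.nii.gz`,
#' `exclude.nii.gz`, `stop.nii.gz` and `waypoint_<k>.nii.gz` as applicable,
#' plus a set-level `manifest.json` and the template brain mask — the layout
#' XTRACT-style pipelines consume.
#'
#' @param set A [protocol_set()].
#' @param dir Directory to create.
#' @return `read_protocol_set()` returns a [protocol_set()].
#' @export
write_protocol_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(set$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  file_of <- list(seed = "seed.nii.gz", exclusion = "exclude.nii.gz",
                  stop = "stop.nii.gz", target = "target.nii.gz")
  meta <- lapply(set$protocols, function(p) {
    pd <- file.path(dir, p$abbreviation)
    dir.create(pd, showWarnings = FALSE)
    slots <- roi_slots(p)
    for (nm in names(slots)) {
      fn <- file_of[[nm]] %||% paste0(nm, ".nii.gz")
      write_volume(slots[[nm]], file.path(pd, fn))
    }
    list(name = p$name, abbreviation = p$abbreviation, category = p$category,
         hemisphere = p$hemisphere, rois = names(slots),
         provenance = p$provenance)
  })
  jsonlite::write_json(list(template = set$template, protocols = unname(meta)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_protocol_set
#' @export
read_protocol_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  brain <- as_binary_mask(read_volume(file.path(dir, "brain_mask.nii.gz")))
  file_of <- list(seed = "seed.nii.gz", exclusion = "exclude.nii.gz",
                  stop = "stop.nii.gz", target = "target.nii.gz")
  protos <- lapply(man$protocols, function(m) {
    pd <- file.path(dir, m$abbreviation)
    rois <- list(waypoints = list())
    for (nm in unlist(m$rois)) {
      fn <- file_of[[nm]] %||% paste0(nm, ".nii.gz")
      msk <- as_binary_mask(read_volume(file.path(pd, fn)))
      if (startsWith(nm, "waypoint_")) {
        rois$waypoints[[sub("^waypoint_", "", nm)]] <- msk
      } else {
        rois[[nm]] <- msk
      }
    }
    tract_protocol(
      name = m$name, abbreviation = m$abbreviation, category = m$category,
      hemisphere = m$hemisphere,
      rois = protocol_rois(seed = rois$seed, waypoints = rois$waypoints,
                           exclusion = rois$exclusion, stop = rois$stop,
                           target = rois$target),
      provenance = unlist(m$provenance) %||% character()
    )
  })
  protocol_set(template = man$template, protocols = protos, brain_mask = brain)
}
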