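#' Assemble a respiratory 4D study
#'
#' An ordered stack of phase images (0%, 10%, ..., 90% for clinical ten-phase
#' binning) sharing one patient frame of reference, with optional per-phase
#' ground-truth or manual heart masks.
#'
#' @param phases list of lists with `label`, `image` ([hs_image()]) and
#'   optional `truth` ([hs_mask()]).
#' @param patient_id identifier.
#' @return An object of class `phase4d_study`.
#' @export
phase4d_study <- function(phases, patient_id = "P0") {
  labels <- vapply(phases, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("phase labels must be unique")
  if (length(phases) < 1) stop("study needs at least one phase")
  structure(list(phases = phases, patient_id = patient_id),
            class = "phase4d_study")
}

#' @export
print.phase4d_study <- function(x, ...) {
  cat(sprintf("<phase4d_study> %s: %d phases (%s)\n", x$patient_id,
              length(x$phases),
              paste(vapply(x$phases, function(p) p$label, character(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Propagate a heart delineation to another respiratory phase
#'
#' Intra-patient deformable registration: both images come from the same 4D
#' acquisition and share the scanner frame, so no rigid step is used and the
#' demons registration starts from the identity. The fixed image is the
#' destination phase, so the returned mask lives on that phase's grid.
#'
#' @param phase0_image image carrying the delineation (the 0% phase).
#' @param phase_image destination phase image.
#' @param heart0 heart [hs_mask()] on the `phase0_image` grid.
#' @param reg_cfg a [reg_config()].
#' @return The propagated [hs_mask()] on the destination grid; attribute
#'   `field` carries the deformation.
#' @export
propagate_to_phase <- function(phase0_image, phase_image, heart0,
                               reg_cfg = reg_config()) {
  if (same_grid(phase0_image, phase_image) &&
      identical(phase0_image$values, phase_image$values)) {
    out <- heart0
    out$role <- "heart_auto"
    attr(out, "field") <- deformation_field(
      matrix(0, prod(dim(phase_image$values)), 3), phase_image)
    return(out)
  }
  field <- demons_register(phase_image, phase0_image, init = NULL,
                           cfg = reg_cfg)
  out <- apply_to_mask(field, heart0, phase_image)
  out$role <- "heart_auto"
  attr(out, "field") <- field
  out
}

#' Motion-encompassing PRV as the union of per-phase delineations
#'
#' The planning organ-at-risk volume for the heart: the voxelwise union of
#' the delineations on all breathing phases, on the grid of the first mask
#' (others are resampled there with nearest-neighbour interpolation if their
#' grids differ).
#'
#' @param phase_masks list of >= 2 [hs_mask()]s.
#' @return An [hs_mask()] with role `"prv"`.
#' @export
build_prv <- function(phase_masks) {
  if (length(phase_masks) < 2) stop("PRV needs at least 2 phase masks")
  ref <- phase_masks[[1]]
  vals <- ref$values
  for (m in phase_masks[-1]) {
    if (!same_grid(m, ref)) m <- resample(m, ref, "nearest")
    vals <- pmax(vals, m$values)
  }
  hs_mask(array(vals, dim = dim(ref$values)), ref$spacing, ref$origin,
          ref$direction, role = "prv")
}

atlas_at_phase <- function(atlas, label) {
  if (inherits(atlas, "atlas_entry")) return(atlas)
  if (!is.null(atlas[[label]])) return(atlas[[label]])
  if (!is.null(atlas[["0%"]])) return(atlas[["0%"]])
  atlas[[1]]
}

#' Segment a 4D study
#'
#' `mode = "propagate"` (the proposed pipeline) runs multi-atlas fusion once
#' on the 0% phase and propagates the result to the remaining phases by
#' intra-patient deformable registration (one fusion plus n-1 registrations).
#' `mode = "independent"` runs the full multi-atlas segmentation separately
#' on every phase (n fusions), using each atlas at the corresponding phase
#' when available and its 0% phase otherwise. Both modes finish by building
#' the PRV as the union of the per-phase masks on the phase-0 grid.
#'
#' All phase images and atlases are assumed cropped to the heart volume of
#' interest (see [crop_to_heart_voi()]).
#'
#' @param study a [phase4d_study()] (complete, ordered phases).
#' @param atlases list of [atlas_entry()]s, or per-atlas lists keyed by phase
#'   label.
#' @param mode `"propagate"` or `"independent"`.
#' @param reg_cfg a [reg_config()].
#' @param fus_cfg a [fusion_config()].
#' @return List with `masks` (per-phase heart_auto, named by phase label),
#'   `prv`, `phase0` fusion details, and `counts` (fusions and propagation
#'   registrations performed).
#' @export
segment_study <- function(study, atlases, mode = c("propagate", "independent"),
                          reg_cfg = reg_config(), fus_cfg = fusion_config()) {
  mode <- match.arg(mode)
  if (length(atlases) < 3) stop("need at least 3 atlases")
  labels <- vapply(study$phases, function(p) p$label, character(1))
  masks <- vector("list", length(labels))
  names(masks) <- labels
  counts <- c(fusions = 0L, propagation_registrations = 0L)
  phase0_detail <- NULL
  if (mode == "propagate") {
    a0 <- lapply(atlases, atlas_at_phase, label = labels[1])
    seg0 <- segment_heart(study$phases[[1]]$image, a0, reg_cfg, fus_cfg)
    counts["fusions"] <- 1L
    phase0_detail <- seg0
    masks[[1]] <- seg0$mask
    for (k in seq_along(labels)[-1]) {
      masks[[k]] <- propagate_to_phase(study$phases[[1]]$image,
                                       study$phases[[k]]$image,
                                       seg0$mask, reg_cfg)
      counts["propagation_registrations"] <-
        counts["propagation_registrations"] + 1L
    }
  } else {
    for (k in seq_along(labels)) {
      ak <- lapply(atlases, atlas_at_phase, label = labels[k])
      segk <- segment_heart(study$phases[[k]]$image, ak, reg_cfg, fus_cfg)
      counts["fusions"] <- counts["fusions"] + 1L
      if (k == 1L) phase0_detail <- segk
      masks[[k]] <- segk$mask
    }
  }
  prv <- if (length(masks) >= 2) build_prv(masks) else {
    p <- masks[[1]]; p$role <- "prv"; p
  }
  list(masks = masks, prv = prv, phase0 = phase0_detail, counts = counts)
}
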