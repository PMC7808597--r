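#' Atlas entry
#'
#' An image together with its heart delineation, both cropped to the volume
#' of interest and sharing one grid; the unit of the multi-atlas machinery.
#'
#' @param id unique label within an atlas set.
#' @param image an [hs_image()].
#' @param mask an [hs_mask()] on the same grid.
#' @return An object of class `atlas_entry`.
#' @export
atlas_entry <- function(id, image, mask) {
  if (!same_grid(image, mask)) stop("atlas image and mask must share a grid")
  structure(list(id = as.character(id), image = image, mask = mask),
            class = "atlas_entry")
}

#' Fusion configuration
#'
#' Parameters of atlas selection and local-weighted label fusion. The
#' rejection rule fences deviation scores at `median + k_iqr * IQR`; the
#' local weight is the inverse mean absolute intensity difference over a
#' cubic patch.
#'
#' @param k_iqr outlier fence multiplier for atlas rejection.
#' @param min_retained minimum number of atlases kept (>= 3).
#' @param patch_radius_mm radius of the cubic weighting patch, mm.
#' @param epsilon additive guard in the inverse-difference weight, HU.
#' @param probability_threshold fused-probability threshold for the final
#'   label, in (0, 1); voxels at or above it are labelled heart.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(k_iqr = 1.5, min_retained = 3L,
                          patch_radius_mm = 5, epsilon = 1,
                          probability_threshold = 0.5) {
  if (min_retained < 3) stop("min_retained must be >= 3")
  if (patch_radius_mm <= 0) stop("patch_radius_mm must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("probability_threshold must be in (0, 1)")
  structure(list(k_iqr = k_iqr, min_retained = as.integer(min_retained),
                 patch_radius_mm = patch_radius_mm, epsilon = epsilon,
                 probability_threshold = probability_threshold),
            class = "fusion_config")
}

#' Propagate an atlas set to a target image
#'
#' Registers every atlas to the target with the two-step rigid + demons
#' process and warps its image and heart mask onto the target grid with the
#' resulting field. A failed registration drops that atlas with a logged
#' message rather than aborting, as long as at least three succeed.
#'
#' @param target an [hs_image()] (cropped to the heart VOI).
#' @param atlases list of [atlas_entry()]s (>= 3).
#' @param reg_cfg a [reg_config()].
#' @return List of `propagated_atlas` objects (`id`, `warped_image`,
#'   `warped_mask`, `deviation_mm` filled later by selection); attribute
#'   `failures` names any dropped atlases.
#' @export
propagate_atlases <- function(target, atlases, reg_cfg = reg_config()) {
  if (length(atlases) < 3) stop("need at least 3 atlases")
  failures <- character()
  out <- list()
  for (at in atlases) {
    res <- try({
      rigid <- rigid_register(target, at$image, reg_cfg)
      field <- demons_register(target, at$image, init = rigid, cfg = reg_cfg)
      list(id = at$id,
           warped_image = apply_to_image(field, at$image, target),
           warped_mask = apply_to_mask(field, at$mask, target),
           deviation_mm = NA_real_,
           reg_log = field$log)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, at$id)
      message("atlas ", at$id, " dropped: registration failed (",
              trimws(attr(res, "condition")$message %||% "unknown"), ")")
    } else {
      out <- c(out, list(structure(res, class = "propagated_atlas")))
    }
  }
  if (length(out) < 3)
    stop("fewer than 3 atlases survived registration")
  attr(out, "failures") <- failures
  out
}

#' Voxelwise majority-vote consensus of propagated atlases
#'
#' A voxel is foreground when strictly more than half of the atlases label
#' it; exact half-count ties resolve to background.
#'
#' @param propagated list of >= 3 propagated atlases (from
#'   [propagate_atlases()]).
#' @return An [hs_mask()].
#' @export
consensus_mask <- function(propagated) {
  if (length(propagated) < 3) stop("need at least 3 propagated atlases")
  votes <- Reduce(`+`, lapply(propagated, function(p) p$warped_mask$values))
  tpl <- propagated[[1]]$warped_mask
  hs_mask(array(as.numeric(votes > length(propagated) / 2),
                dim = dim(tpl$values)),
          tpl$spacing, tpl$origin, tpl$direction, role = "other")
}

#' Surface deviation of each propagated atlas from the consensus
#'
#' The deviation score used for atlas rejection: the mean absolute surface
#' distance ([masd()]) between each warped mask and the consensus
#' delineation. An empty warped mask scores `Inf`, guaranteeing it is a
#' rejection candidate.
#'
#' @param propagated list of propagated atlases.
#' @param consensus nonempty consensus [hs_mask()].
#' @return The input list with `deviation_mm` filled in.
#' @export
atlas_deviation_scores <- function(propagated, consensus) {
  if (sum(consensus$values) == 0) stop("consensus mask is empty")
  lapply(propagated, function(p) {
    p$deviation_mm <- if (sum(p$warped_mask$values) == 0) Inf
    else masd(p$warped_mask, consensus)
    p
  })
}

#' Reject discordant atlases by their surface deviation
#'
#' Atlases whose deviation exceeds `median + k_iqr * IQR` of the deviation
#' scores are rejected. If that would leave fewer than `min_retained`
#' atlases, the `min_retained` lowest-deviation atlases are kept instead.
#' Input order is preserved; the attached decision log records every
#' rejection with its score.
#'
#' @param propagated list of propagated atlases with `deviation_mm` filled
#'   (see [atlas_deviation_scores()]).
#' @param cfg a [fusion_config()].
#' @return The retained sublist; attribute `selection_log` is a data.frame
#'   of id, deviation and decision.
#' @export
select_atlases <- function(propagated, cfg = fusion_config()) {
  if (length(propagated) < cfg$min_retained)
    stop("fewer atlases than min_retained")
  dev <- vapply(propagated, function(p) p$deviation_mm, numeric(1))
  if (any(is.na(dev))) stop("deviation scores missing; run atlas_deviation_scores first")
  fin <- dev[is.finite(dev)]
  fence <- stats::median(fin) + cfg$k_iqr * stats::IQR(fin)
  reject <- dev > fence
  if (sum(!reject) < cfg$min_retained) {
    keep_rank <- order(dev)[seq_len(cfg$min_retained)]
    reject <- !(seq_along(dev) %in% keep_rank)
  }
  log <- data.frame(id = vapply(propagated, function(p) p$id, character(1)),
                    deviation_mm = dev,
                    decision = ifelse(reject, "rejected", "retained"),
                    fence_mm = fence, stringsAsFactors = FALSE)
  out <- propagated[!reject]
  attr(out, "selection_log") <- log
  out
}

#' Local intensity-agreement weight map
#'
#' `weight(v) = 1 / (epsilon + mean |target - warped| over the cubic patch of
#' radius patch_radius_mm centered at v)`: atlases that locally resemble the
#' target get large weights. Weights are strictly positive and finite.
#'
#' @param target target [hs_image()].
#' @param warped_image a propagated atlas image on the same grid.
#' @param cfg a [fusion_config()].
#' @return Numeric array of weights on the target grid.
#' @export
local_weight <- function(target, warped_image, cfg = fusion_config()) {
  if (!same_grid(target, warped_image)) stop("grids do not match")
  d <- dim(target$values)
  rvox <- as.integer(round(cfg$patch_radius_mm / target$spacing))
  mad <- cpp_patch_mad(as.numeric(target$values),
                       as.numeric(warped_image$values),
                       as.integer(d), pmax(rvox, 0L))
  array(1 / (cfg$epsilon + mad), dim = d)
}

#' Local-weighted label fusion
#'
#' Fuses the retained warped masks into a heart probability map,
#' `p(v) = sum_i w_i(v) m_i(v) / sum_i w_i(v)`, and thresholds it at the
#' configured probability to produce the automatic heart delineation.
#'
#' @param retained list of retained propagated atlases.
#' @param weights list of weight arrays aligned with `retained` (from
#'   [local_weight()]).
#' @param cfg a [fusion_config()].
#' @return List with `probability` ([hs_image()]-like array on the target
#'   grid) and `mask` ([hs_mask()] with role `"heart_auto"`).
#' @export
fuse_labels <- function(retained, weights, cfg = fusion_config()) {
  if (length(retained) < 1) stop("need at least one retained atlas")
  if (length(weights) != length(retained))
    stop("weights must align with the retained atlas list")
  tpl <- retained[[1]]$warped_mask
  num <- den <- array(0, dim = dim(tpl$values))
  for (i in seq_along(retained)) {
    w <- weights[[i]]
    stopifnot(all(w > 0), all(is.finite(w)))
    num <- num + w * retained[[i]]$warped_mask$values
    den <- den + w
  }
  prob <- num / den
  mask <- hs_mask(array(as.numeric(prob >= cfg$probability_threshold),
                        dim = dim(prob)),
                  tpl$spacing, tpl$origin, tpl$direction, role = "heart_auto")
  list(probability = prob, mask = mask)
}

#' Multi-atlas heart segmentation of one target image
#'
#' The full fusion stage: propagate all atlases, build the consensus, score
#' and reject discordant atlases, compute local weights, and fuse. Both
#' images are assumed cropped to the heart volume of interest.
#'
#' @param target target [hs_image()].
#' @param atlases list of [atlas_entry()]s (>= 3).
#' @param reg_cfg a [reg_config()].
#' @param fus_cfg a [fusion_config()].
#' @return List with `mask` (Heart_auto), `probability`, `selection_log`,
#'   `failures`.
#' @export
segment_heart <- function(target, atlases, reg_cfg = reg_config(),
                          fus_cfg = fusion_config()) {
  prop <- propagate_atlases(target, atlases, reg_cfg)
  cons <- consensus_mask(prop)
  prop <- atlas_deviation_scores(prop, cons)
  kept <- select_atlases(prop, fus_cfg)
  weights <- lapply(kept, function(p) local_weight(target, p$warped_image,
                                                   fus_cfg))
  fused <- fuse_labels(kept, weights, fus_cfg)
  list(mask = fused$mask, probability = fused$probability,
       selection_log = attr(kept, "selection_log"),
       failures = attr(prop, "failures"))
}
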