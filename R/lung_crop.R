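#' Intensity-based lung segmentation
#'
#' Thresholds the image below `hu_threshold`, labels six-connected
#' components, removes components touching an axial (x or y) image border --
#' which excludes the exterior air surrounding the patient -- and components
#' smaller than `min_component_mm3`, then keeps the largest one or two
#' remaining components (two lungs, or one when they connect through the
#' airways at this threshold).
#'
#' @param image an [hs_image()] (HU-like intensities).
#' @param hu_threshold voxels strictly below this are lung candidates.
#'   Default -320 HU, a standard CT lung threshold.
#' @param min_component_mm3 minimum component volume retained, mm^3.
#' @return An [hs_mask()] with role `"lungs"`.
#' @export
segment_lungs <- function(image, hu_threshold = -320,
                          min_component_mm3 = 50000) {
  d <- dim(image$values)
  cand <- image$values < hu_threshold
  if (!any(cand)) stop("no lungs found: no voxels below threshold")
  lab <- array(cpp_label6(as.integer(cand), as.integer(d)), dim = d)
  # drop components touching the axial (x/y) borders: exterior air
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ]))
  border <- border[border > 0]
  sizes <- tabulate(lab)
  vox_mm3 <- prod(image$spacing)
  keep <- setdiff(which(sizes * vox_mm3 >= min_component_mm3), border)
  if (length(keep) == 0L) stop("no lungs found: no interior component survives")
  keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(min(2, length(keep)))]
  hs_mask(array(as.numeric(lab %in% keep), dim = d), image$spacing,
          image$origin, image$direction, role = "lungs")
}

#' Heart volume of interest from the lung mask
#'
#' The crop region used before registration: the bounding box of the lungs
#' expanded by a physical margin. The heart sits in the mediastinum between
#' the lungs, so the lung bounding box contains it.
#'
#' @param lungs a nonempty lungs [hs_mask()].
#' @param margin_mm expansion of the bounding box, mm (scalar or per axis).
#' @return A [voxel_box()].
#' @export
heart_voi <- function(lungs, margin_mm = 10) {
  mask_bounding_box(lungs, margin_mm)
}

#' Crop an image and its masks to a volume of interest
#'
#' Applies [crop()] consistently to the image and every supplied mask so all
#' outputs stay on one shared grid.
#'
#' @param image an [hs_image()].
#' @param masks list of [hs_mask()]s on the same grid (may be empty).
#' @param box a [voxel_box()].
#' @return List with `image` and `masks` (same names as the input list).
#' @export
crop_case <- function(image, masks = list(), box) {
  list(image = crop(image, box),
       masks = lapply(masks, crop, box = box))
}

# Full crop stage: lungs -> VOI -> cropped case.
crop_to_heart_voi <- function(image, masks = list(), hu_threshold = -320,
                              margin_mm = 10, min_component_mm3 = 50000) {
  lungs <- segment_lungs(image, hu_threshold, min_component_mm3)
  box <- heart_voi(lungs, margin_mm)
  out <- crop_case(image, masks, box)
  out$lungs <- crop(lungs, box)
  out$box <- box
  out
}
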