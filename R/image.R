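#' @useDynLib heartseg4d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volumetric image with physical-space geometry
#'
#' An `hs_image` stores one scalar (HU-like) value per voxel together with the
#' geometry that places the grid in physical space: voxel spacing (mm), the
#' position of the center of voxel (0,0,0), and an orthonormal 3x3 direction
#' matrix. The physical position of 0-based voxel index `(i,j,k)` is
#' `origin + direction %*% (c(i,j,k) * spacing)`, the NIfTI/ITK convention;
#' all distances in this package are millimetres.
#'
#' @param values numeric 3D array of intensities.
#' @param spacing positive length-3 numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, mm position of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping index axes to physical axes.
#' @return An object of class `hs_image`.
#' @export
hs_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3)) {
  values <- as_array3(values)
  geom_validate(dim(values), spacing, origin, direction)
  if (!all(is.finite(values))) stop("image values must all be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 direction = matrix(as.numeric(direction), 3, 3)),
            class = "hs_image")
}

#' Binary organ mask on an image grid
#'
#' Same geometry model as [hs_image()] but values restricted to \{0, 1\}. The
#' `role` tag records what the delineation represents (e.g. a manually
#' contoured heart, an automatic heart segmentation, a motion-encompassing
#' PRV, the lungs, or phantom ground truth).
#'
#' @inheritParams hs_image
#' @param role one of `"heart_manual"`, `"heart_auto"`, `"prv"`, `"lungs"`,
#'   `"truth"`, `"other"`.
#' @return An object of class `hs_mask` (which also inherits `hs_image`).
#' @export
hs_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    direction = diag(3), role = "other") {
  values <- as_array3(values)
  geom_validate(dim(values), spacing, origin, direction)
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  role <- match.arg(role, c("heart_manual", "heart_auto", "prv", "lungs",
                            "truth", "other"))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 direction = matrix(as.numeric(direction), 3, 3),
                 role = role),
            class = c("hs_mask", "hs_image"))
}

as_array3 <- function(values) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  storage.mode(values) <- "double"
  values
}

geom_validate <- function(dims, spacing, origin, direction) {
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be three counts >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on all axes")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("direction matrix must be orthonormal (|det| = 1)")
  invisible(TRUE)
}

#' @export
print.hs_image <- function(x, ...) {
  kind <- if (inherits(x, "hs_mask")) sprintf("mask [%s]", x$role) else "image"
  cat(sprintf("<hs_%s> %s  spacing %s mm  origin (%s) mm\n",
              if (inherits(x, "hs_mask")) "mask" else "image",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "hs_mask"))
    cat(sprintf("  role: %s  foreground voxels: %d\n", x$role,
                sum(x$values > 0)))
  else
    cat(sprintf("  intensity range [%.6g, %.6g]\n", min(x$values),
                max(x$values)))
  invisible(x)
}

img_dims <- function(img) dim(img$values)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Physical coordinates of voxel indices
#'
#' @param img an [hs_image()] or [hs_mask()].
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates of the voxel centers.
#' @export
voxel_to_physical <- function(img, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx, 2, img$spacing, "*") %*% t(img$direction) +
    matrix(img$origin, nrow(idx), 3, byrow = TRUE)
}

#' Half-open voxel box
#'
#' Axis-aligned voxel-index box with inclusive lower corner `lo` and exclusive
#' upper corner `hi` (0-based indices, so the full grid of an n^3 image is
#' `voxel_box(c(0,0,0), dims)`).
#'
#' @param lo,hi length-3 integer index triples, `lo <= hi` componentwise.
#' @return An object of class `voxel_box`.
#' @export
voxel_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo > hi))
    stop("voxel box requires lo <= hi componentwise")
  structure(list(lo = lo, hi = hi), class = "voxel_box")
}

#' @export
print.voxel_box <- function(x, ...) {
  cat(sprintf("<voxel_box> [%s) x [%s) x [%s)\n",
              paste(c(x$lo[1], x$hi[1]), collapse = ", "),
              paste(c(x$lo[2], x$hi[2]), collapse = ", "),
              paste(c(x$lo[3], x$hi[3]), collapse = ", ")))
  invisible(x)
}

geom_list <- function(img) {
  list(dim = as.integer(dim(img$values)), spacing = img$spacing,
       origin = img$origin, direction = as.numeric(img$direction))
}

rebuild_like <- function(template, values, dims = NULL, spacing = NULL,
                         origin = NULL) {
  dims <- if (is.null(dims)) dim(template$values) else dims
  values <- array(values, dim = dims)
  spacing <- if (is.null(spacing)) template$spacing else spacing
  origin <- if (is.null(origin)) template$origin else origin
  if (inherits(template, "hs_mask"))
    hs_mask(values, spacing, origin, template$direction, role = template$role)
  else
    hs_image(values, spacing, origin, template$direction)
}

#' Resample an image or mask onto a reference grid
#'
#' Values are sampled in physical space; voxels of the reference grid that
#' fall outside the support of `source` are filled with -1000 (air) for
#' images and 0 for masks. Masks are closed under both interpolators: with
#' `"linear"` the interpolated occupancy is thresholded at 0.5.
#'
#' @param source an [hs_image()] or [hs_mask()].
#' @param reference an object carrying the target grid geometry (another
#'   image/mask).
#' @param interp `"linear"` or `"nearest"`.
#' @return Same type as `source`, on the grid of `reference`.
#' @export
resample <- function(source, reference, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  gs <- geom_list(source); gr <- geom_list(reference)
  is_mask <- inherits(source, "hs_mask")
  fill <- if (is_mask) 0 else -1000
  out <- cpp_resample(as.numeric(source$values), gs$dim, gs$spacing, gs$origin,
                      gs$direction, gr$dim, gr$spacing, gr$origin,
                      gr$direction, as.numeric(diag(3)), c(0, 0, 0),
                      interp == "nearest", fill)
  if (is_mask && interp == "linear") out <- as.numeric(out >= 0.5)
  res <- rebuild_like(source, out, dims = gr$dim, spacing = gr$spacing,
                      origin = gr$origin)
  res$direction <- matrix(gr$direction, 3, 3)
  res
}

#' Crop an image or mask to a voxel box
#'
#' The origin is advanced so retained voxels keep their physical coordinates.
#'
#' @param source an [hs_image()] or [hs_mask()].
#' @param box a [voxel_box()] within the grid.
#' @return Same type as `source`, with dims equal to the box extent.
#' @export
crop <- function(source, box) {
  d <- dim(source$values)
  if (any(box$lo < 0) || any(box$hi > d)) stop("crop box outside grid")
  if (any(box$hi == box$lo)) stop("crop box is empty along some axis")
  vals <- source$values[(box$lo[1] + 1):box$hi[1],
                        (box$lo[2] + 1):box$hi[2],
                        (box$lo[3] + 1):box$hi[3], drop = FALSE]
  new_origin <- as.numeric(voxel_to_physical(source, box$lo))
  rebuild_like(source, vals, dims = box$hi - box$lo, origin = new_origin)
}

#' Bounding voxel box of a mask, with a physical margin
#'
#' The smallest half-open box containing all foreground voxels, expanded by
#' `ceiling(margin_mm / spacing)` voxels per axis and clipped to the grid.
#'
#' @param mask a nonempty [hs_mask()].
#' @param margin_mm scalar or per-axis expansion in mm.
#' @return A [voxel_box()].
#' @export
mask_bounding_box <- function(mask, margin_mm = 0) {
  w <- which(mask$values > 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  margin_mm <- rep_len(margin_mm, 3L)
  if (any(margin_mm < 0)) stop("margin_mm must be non-negative")
  grow <- as.integer(ceiling(margin_mm / mask$spacing))
  lo <- pmax(apply(w, 2, min) - 1L - grow, 0L)
  hi <- pmin(apply(w, 2, max) + grow, dim(mask$values))
  voxel_box(lo, hi)
}

mask_volume_mm3 <- function(mask) sum(mask$values) * prod(mask$spacing)

mask_centroid <- function(mask) {
  w <- which(mask$values > 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  colMeans(voxel_to_physical(mask, w - 1))
}
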