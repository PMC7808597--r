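#' Specification of a synthetic thorax phantom
#'
#' The phantom emulates the anatomy relevant to whole-heart contouring on
#' thoracic CT: an elliptic-cylinder body in air, two lung ellipsoids, and a
#' heart ellipsoid seated in the mediastinum between them. The heart ellipsoid
#' deliberately overlaps the medial faces of the lungs, so that part of the
#' heart surface is a high-contrast heart/lung interface while the remainder
#' borders soft tissue at near-identical intensity -- the low-contrast
#' situation that makes automatic heart delineation hard on real CT.
#'
#' Axes are x: right-left, y: posterior-anterior, z: inferior-superior
#' (z increases towards the head). All lengths in mm, intensities in HU.
#'
#' @param dims voxel counts per axis.
#' @param spacing mm per voxel.
#' @param body list with `center` (x,y mm), `radii` (x,y mm) and `half_height`
#'   (z mm) of the elliptic cylinder.
#' @param lungs list of two lists, each with `center` and `radii` (mm).
#' @param heart list with `center`, `radii` (mm) and `angle_deg` (rotation of
#'   the ellipsoid about z).
#' @param intensities named HU values for `air`, `body`, `lung`, `heart`.
#'   Defaults keep heart/body contrast at 5 HU, below the noise level, per the
#'   low-contrast mediastinum the generator emulates.
#' @param noise_sd additive Gaussian noise, HU.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 64), spacing = c(2.5, 2.5, 2.5),
                         body = list(center = c(80, 84, 80),
                                     radii = c(62, 48), half_height = 74),
                         lungs = list(list(center = c(54, 80, 84),
                                           radii = c(20, 30, 44)),
                                      list(center = c(106, 80, 84),
                                           radii = c(22, 30, 44))),
                         heart = list(center = c(80, 88, 66),
                                      radii = c(26, 23, 25), angle_deg = 25),
                         intensities = c(air = -1000, body = 40, lung = -750,
                                         heart = 45),
                         noise_sd = 10, seed = 1L) {
  spec <- structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                         body = body, lungs = lungs, heart = heart,
                         intensities = intensities,
                         noise_sd = as.numeric(noise_sd),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  geom_validate(spec$dims, spec$spacing, c(0, 0, 0), diag(3))
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(spec$heart$radii <= 0) || any(spec$body$radii <= 0) ||
      spec$body$half_height <= 0 ||
      any(vapply(spec$lungs, function(l) any(l$radii <= 0), logical(1))))
    stop("degenerate phantom geometry: all radii must be positive")
  if (spec$intensities[["lung"]] >= spec$intensities[["body"]])
    stop("lung intensity must be below body intensity")
  # heart must lie inside the body and between the lungs
  hc <- spec$heart$center; hr <- max(spec$heart$radii)
  bc <- spec$body$center
  if (sum(((hc[1:2] - bc[1:2]) / (spec$body$radii - hr))^2) > 1 ||
      abs(hc[3] - bc[3]) + hr > spec$body$half_height)
    stop("heart ellipsoid must lie inside the body")
  lcx <- vapply(spec$lungs, function(l) l$center[1], numeric(1))
  if (hc[1] <= min(lcx) || hc[1] >= max(lcx))
    stop("heart center must lie between the lung centers")
  # lungs must sit inside the body with margin, so the thresholded lungs can
  # never touch exterior air and merge with it
  th <- seq(0, pi, length.out = 24)
  phi <- seq(0, 2 * pi, length.out = 48)
  g <- expand.grid(th = th, phi = phi)
  shrink <- 5
  for (l in spec$lungs) {
    pts <- cbind(l$center[1] + l$radii[1] * sin(g$th) * cos(g$phi),
                 l$center[2] + l$radii[2] * sin(g$th) * sin(g$phi),
                 l$center[3] + l$radii[3] * cos(g$th))
    inside <- ((pts[, 1] - bc[1]) / (spec$body$radii[1] - shrink))^2 +
      ((pts[, 2] - bc[2]) / (spec$body$radii[2] - shrink))^2 <= 1 &
      abs(pts[, 3] - bc[3]) <= spec$body$half_height - shrink
    if (!all(inside))
      stop("lung ellipsoid too close to the body surface")
  }
  # the heart must fall inside the lung bounding box with margin, so the
  # lung-derived crop region always contains it
  ext <- function(l, a) c(l$center[a] - l$radii[a], l$center[a] + l$radii[a])
  lung_lo <- sapply(1:3, function(a) min(vapply(spec$lungs, function(l)
    ext(l, a)[1], numeric(1))))
  lung_hi <- sapply(1:3, function(a) max(vapply(spec$lungs, function(l)
    ext(l, a)[2], numeric(1))))
  thr <- spec$heart$angle_deg * pi / 180
  hx <- sqrt((spec$heart$radii[1] * cos(thr))^2 +
               (spec$heart$radii[2] * sin(thr))^2)
  hy <- sqrt((spec$heart$radii[1] * sin(thr))^2 +
               (spec$heart$radii[2] * cos(thr))^2)
  hext <- c(hx, hy, spec$heart$radii[3])
  voi_margin <- 7
  if (any(hc - hext < lung_lo - voi_margin) ||
      any(hc + hext > lung_hi + voi_margin))
    stop("heart extends beyond the lung bounding box margin")
  invisible(TRUE)
}

#' Respiratory motion specification for a 4D study
#'
#' Superior-inferior heart/diaphragm excursion over a cosine breathing trace
#' sampled at `n_phases` respiratory bins; phase 0 is end-exhale (no
#' displacement) and phase `n/2` full inhale (peak displacement). A fraction
#' of the excursion is applied along the anterior-posterior axis. The default
#' 10 mm amplitude sits within the excursion range reported for the heart
#' under free breathing (up to about 13 mm).
#'
#' @param amplitude_mm peak superior-inferior displacement, mm.
#' @param ap_fraction anterior-posterior amplitude as a fraction of
#'   `amplitude_mm`.
#' @param n_phases number of respiratory bins (10 for clinical 4D-CT).
#' @param seed integer seed for per-phase noise realizations.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(amplitude_mm = 10, ap_fraction = 0.3, n_phases = 10L,
                        seed = 1L) {
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (n_phases < 2) stop("n_phases must be >= 2")
  structure(list(amplitude_mm = as.numeric(amplitude_mm),
                 ap_fraction = as.numeric(ap_fraction),
                 n_phases = as.integer(n_phases), seed = as.integer(seed)),
            class = "motion_spec")
}

# Region membership on the voxel grid; dz/dy displace the heart, floor_drop
# lowers the lung floors (diaphragm) keeping the apices fixed.
phantom_membership <- function(spec, heart_dz = 0, heart_dy = 0,
                               floor_drop = 0) {
  d <- spec$dims; sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)

  bc <- spec$body$center; br <- spec$body$radii
  body <- (((X - bc[1]) / br[1])^2 + ((Y - bc[2]) / br[2])^2 <= 1) &
    (abs(Z - bc[3]) <= spec$body$half_height)

  lung <- array(FALSE, dim = d)
  for (l in spec$lungs) {
    cz <- l$center[3] - floor_drop / 2
    rz <- l$radii[3] + floor_drop / 2
    lung <- lung | (((X - l$center[1]) / l$radii[1])^2 +
                    ((Y - l$center[2]) / l$radii[2])^2 +
                    ((Z - cz) / rz)^2 <= 1)
  }
  lung <- lung & body

  h <- spec$heart
  th <- h$angle_deg * pi / 180
  hx <- X - h$center[1]
  hy <- Y - (h$center[2] + heart_dy)
  hz <- Z - (h$center[3] + heart_dz)
  rx <- cos(th) * hx + sin(th) * hy
  ry <- -sin(th) * hx + cos(th) * hy
  heart <- (rx / h$radii[1])^2 + (ry / h$radii[2])^2 +
    (hz / h$radii[3])^2 <= 1
  heart <- heart & body
  lung <- lung & !heart
  list(body = body, lung = lung, heart = heart)
}

phantom_from_membership <- function(spec, mem, noise_seed) {
  hu <- spec$intensities
  vals <- array(hu[["air"]], dim = spec$dims)
  vals[mem$body] <- hu[["body"]]
  vals[mem$lung] <- hu[["lung"]]
  vals[mem$heart] <- hu[["heart"]]
  if (spec$noise_sd > 0) {
    set.seed(noise_seed)
    vals <- vals + array(stats::rnorm(prod(spec$dims), sd = spec$noise_sd),
                         dim = spec$dims)
  }
  geom <- list(spacing = spec$spacing, origin = c(0, 0, 0))
  list(image = hs_image(vals, geom$spacing, geom$origin),
       heart = hs_mask(array(as.numeric(mem$heart), dim = spec$dims),
                       geom$spacing, geom$origin, role = "truth"),
       lungs = hs_mask(array(as.numeric(mem$lung), dim = spec$dims),
                       geom$spacing, geom$origin, role = "lungs"))
}

#' Generate a static thorax phantom with ground truth
#'
#' Voxels are assigned by region membership with innermost region winning
#' (heart over lung over body over air); truth masks record the exact
#' membership sets before noise is added, so they are noise-free ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case`: `image` ([hs_image()]), `heart` and
#'   `lungs` truth masks ([hs_mask()]), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  mem <- phantom_membership(spec)
  out <- phantom_from_membership(spec, mem, spec$seed)
  out$spec <- spec
  class(out) <- "phantom_case"
  out
}

#' Generate a cohort of anatomically varied phantoms
#'
#' Each member perturbs the base geometry: organ radii are scaled by
#' `1 + N(0, variation)` per axis, organ centers shifted by
#' `N(0, variation * mean radius)` per axis, and the heart orientation
#' jittered by `N(0, variation * 30)` degrees. Draws violating the phantom
#' invariants (heart outside the body or not between the lungs) are
#' redrawn. Each member gets its own noise realization.
#'
#' @param n number of members (>= 2).
#' @param base a [phantom_spec()] to perturb.
#' @param variation fractional standard deviation of the perturbations.
#' @param seed integer seed driving all perturbations.
#' @return A list of `n` `phantom_case` objects.
#' @export
make_cohort <- function(n, base = phantom_spec(), variation = 0.08,
                        seed = 1L) {
  if (n < 2) stop("a cohort needs at least 2 members")
  if (variation < 0) stop("variation must be >= 0")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    for (try in 1:100) {
      spec <- perturb_spec(base, variation)
      spec$seed <- base$seed + i
      ok <- !inherits(try(validate_phantom_spec(spec), silent = TRUE),
                      "try-error")
      if (ok) return(make_phantom(spec))
    }
    stop("could not draw a valid cohort member after 100 attempts")
  })
}

perturb_spec <- function(base, variation) {
  spec <- base
  jr <- function(r) r * (1 + stats::rnorm(length(r), sd = variation))
  jc <- function(cc, scale) cc + stats::rnorm(length(cc),
                                              sd = variation * scale)
  spec$heart$radii <- jr(base$heart$radii)
  spec$heart$center <- jc(base$heart$center, mean(base$heart$radii))
  spec$heart$angle_deg <- base$heart$angle_deg +
    stats::rnorm(1, sd = variation * 30)
  spec$lungs <- lapply(base$lungs, function(l) {
    list(center = jc(l$center, mean(l$radii)), radii = jr(l$radii))
  })
  spec$body$radii <- jr(base$body$radii)
  spec$body$center <- jc(base$body$center, mean(base$body$radii))
  spec
}

#' Build a ten-phase respiratory 4D study from a phantom
#'
#' Phase `p` of `n` displaces the heart by
#' `amplitude_mm * (1 - cos(2 pi p / n)) / 2` inferiorly (plus the
#' anterior-posterior share) and lowers the lung floors by the same amount
#' with the lung apices fixed, regenerating the anatomy analytically at each
#' phase so per-phase truth masks are exact. Phase 0 reproduces the base
#' phantom bit-exactly, including its noise realization.
#'
#' @param base a `phantom_case` from [make_phantom()].
#' @param motion a [motion_spec()].
#' @return A list of class `phase4d_study`: `phases` (list with `label`,
#'   `image`, `truth` per phase), `patient_id`, `motion`.
#' @export
make_4d_study <- function(base, motion = motion_spec(), patient_id = "P0") {
  stopifnot(inherits(base, "phantom_case"))
  spec <- base$spec
  n <- motion$n_phases
  extent_mm <- (spec$dims[3] - 1) * spec$spacing[3]
  low <- spec$heart$center[3] - spec$heart$radii[3] - motion$amplitude_mm
  if (low < 0 || motion$amplitude_mm > extent_mm)
    stop("motion amplitude pushes the heart outside the grid")
  phases <- lapply(seq_len(n) - 1L, function(p) {
    dmm <- motion$amplitude_mm * (1 - cos(2 * pi * p / n)) / 2
    if (p == 0L || dmm == 0) {
      ph <- list(image = base$image, truth = base$heart)
    } else {
      mem <- phantom_membership(spec, heart_dz = -dmm,
                                heart_dy = motion$ap_fraction * dmm,
                                floor_drop = dmm)
      out <- phantom_from_membership(spec, mem,
                                     noise_seed = spec$seed +
                                       motion$seed * 1000L + p)
      ph <- list(image = out$image, truth = out$heart)
    }
    ph$label <- sprintf("%d%%", p * as.integer(round(100 / n)))
    ph
  })
  structure(list(phases = phases, patient_id = patient_id, motion = motion,
                 spec = spec),
            class = "phase4d_study")
}

#' Maximum intensity projection across the phases of a 4D study
#'
#' The voxelwise maximum over all phase images, the image clinically used to
#' contour motion-encompassing volumes. Provided as a phantom utility for
#' building PRV reference masks; it is not a segmentation path.
#'
#' @param study a `phase4d_study`.
#' @return An [hs_image()] on the phase-0 grid.
#' @export
mip_image <- function(study) {
  stopifnot(inherits(study, "phase4d_study"))
  vals <- study$phases[[1]]$image$values
  for (ph in study$phases[-1]) vals <- pmax(vals, ph$image$values)
  rebuild_like(study$phases[[1]]$image, vals)
}
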