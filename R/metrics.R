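#' Surface points of a binary mask
#'
#' The delineation surface is realized as the set of centers of foreground
#' voxels that have at least one six-connected background neighbour (voxels
#' on the grid boundary count the outside as background), in physical mm
#' coordinates. Voxel-center surfaces are deterministic and directly
#' checkable against exhaustive oracles, which is why they are preferred here
#' over mesh extraction.
#'
#' @param mask a nonempty [hs_mask()].
#' @return n x 3 matrix of mm coordinates (class `surface_points`).
#' @export
surface_points <- function(mask) {
  m <- as.integer(mask$values > 0)
  if (!any(m == 1L)) stop("mask is empty")
  surf <- cpp_surface6(m, as.integer(dim(mask$values)))
  idx <- which(array(surf, dim = dim(mask$values)), arr.ind = TRUE) - 1
  structure(voxel_to_physical(mask, idx), class = "surface_points")
}

check_pair <- function(a, b, allow_empty = FALSE) {
  if (!same_grid(a, b)) stop("masks must share a grid")
  na <- sum(a$values); nb <- sum(b$values)
  if (!allow_empty && (na == 0 || nb == 0)) stop("mask is empty")
  if (na == 0 && nb == 0) stop("both masks are empty")
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 means no overlap, 1 perfect overlap.
#'
#' @param a,b [hs_mask()]s on the same grid, not both empty.
#' @return Fraction in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  check_pair(a, b, allow_empty = TRUE)
  2 * sum(a$values * b$values) / (sum(a$values) + sum(b$values))
}

# Directed nearest-surface distances (mm) from each surface voxel of `from`
# to the surface of `to`, via an exact Euclidean distance transform of the
# target surface sampled at the source surface voxels.
directed_surface_distances <- function(from, to) {
  d <- as.integer(dim(from$values))
  sf <- cpp_surface6(as.integer(from$values > 0), d)
  st <- cpp_surface6(as.integer(to$values > 0), d)
  dt <- cpp_edt(as.integer(st), d, to$spacing)
  dt[sf]
}

#' Mean absolute surface-to-surface distance (MASD)
#'
#' Average of the two directed mean nearest-surface distances between the
#' voxel-center surfaces of the two masks, Euclidean in mm. The symmetrized
#' average-of-directed-means convention is used (one of several in use; the
#' alternative pools both surface point sets before averaging and differs by
#' less than the voxel scale).
#'
#' @param a,b nonempty [hs_mask()]s on the same grid.
#' @return Distance in mm.
#' @export
masd <- function(a, b) {
  check_pair(a, b)
  (mean(directed_surface_distances(a, b)) +
     mean(directed_surface_distances(b, a))) / 2
}

#' Hausdorff distance (maximum surface-to-surface distance)
#'
#' The larger of the two directed maxima of nearest-surface distances; more
#' sensitive to local outliers than [masd()].
#'
#' @param a,b nonempty [hs_mask()]s on the same grid.
#' @return Distance in mm.
#' @export
hd <- function(a, b) {
  check_pair(a, b)
  max(max(directed_surface_distances(a, b)),
      max(directed_surface_distances(b, a)))
}

#' Compare two delineations with all three metrics
#'
#' @param a,b nonempty [hs_mask()]s on the same grid.
#' @param label_a,label_b names recorded in the result.
#' @return A one-row data.frame with `dsc`, `masd_mm`, `hd_mm`.
#' @export
compare_masks <- function(a, b, label_a = "a", label_b = "b") {
  data.frame(label_a = label_a, label_b = label_b,
             dsc = dsc(a, b), masd_mm = masd(a, b), hd_mm = hd(a, b),
             stringsAsFactors = FALSE)
}

#' Cohort summary table of segmentation metrics
#'
#' Aggregates per-patient, per-phase comparison results into mean and sample
#' standard deviation (n-1 denominator; a single observation reports sd 0)
#' per respiratory phase, plus a pooled all-phases row and, when PRV
#' comparisons are supplied, a PRV row.
#'
#' @param results data.frame with columns `patient`, `phase` (phase label or
#'   `"PRV"`), `dsc`, `masd_mm`, `hd_mm`.
#' @return A data.frame with one row per phase plus `"Average (all phases)"`
#'   and optionally `"PRV"`; attribute `n` carries the cohort size.
#' @export
cohort_table <- function(results) {
  needed <- c("patient", "phase", "dsc", "masd_mm", "hd_mm")
  if (!is.data.frame(results) || !all(needed %in% names(results)) ||
      nrow(results) == 0L)
    stop("results must be a nonempty data.frame with columns ",
         paste(needed, collapse = ", "))
  msd <- function(x) {
    s <- if (length(x) > 1L) stats::sd(x) else 0
    c(mean = mean(x), sd = s)
  }
  row_for <- function(label, sub) {
    d <- msd(sub$dsc); m <- msd(sub$masd_mm); h <- msd(sub$hd_mm)
    data.frame(phase = label, n = nrow(sub),
               dsc_mean = d[1], dsc_sd = d[2],
               masd_mean_mm = m[1], masd_sd_mm = m[2],
               hd_mean_mm = h[1], hd_sd_mm = h[2],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  is_prv <- results$phase == "PRV"
  phases <- unique(results$phase[!is_prv])
  rows <- lapply(phases, function(p) row_for(p, results[results$phase == p, ]))
  if (any(!is_prv))
    rows <- c(rows, list(row_for("Average (all phases)",
                                 results[!is_prv, ])))
  if (any(is_prv)) rows <- c(rows, list(row_for("PRV", results[is_prv, ])))
  out <- do.call(rbind, rows)
  attr(out, "n") <- length(unique(results$patient))
  out
}

#' Write a cohort metrics table as CSV
#'
#' @param table output of [cohort_table()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
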