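#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline: lung-based cropping,
#' registration, fusion, the 4D segmentation mode, and the seed echoed into
#' provenance. All stages are deterministic given inputs and configuration.
#'
#' @param hu_threshold lung segmentation threshold, HU.
#' @param margin_mm VOI margin around the lung bounding box, mm.
#' @param min_component_mm3 minimum lung component volume, mm^3.
#' @param reg a [reg_config()].
#' @param fusion a [fusion_config()].
#' @param mode `"propagate"` or `"independent"` (see [segment_study()]).
#' @param seed integer recorded in provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(hu_threshold = -320, margin_mm = 10,
                            min_component_mm3 = 50000,
                            reg = reg_config(), fusion = fusion_config(),
                            mode = c("propagate", "independent"), seed = 0L) {
  mode <- match.arg(mode)
  structure(list(hu_threshold = hu_threshold, margin_mm = margin_mm,
                 min_component_mm3 = min_component_mm3, reg = reg,
                 fusion = fusion, mode = mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Normalize a cohort member (phantom_case or phase4d_study) to a study with
# truth masks.
as_study <- function(member, id) {
  if (inherits(member, "phase4d_study")) {
    if (is.null(member$patient_id)) member$patient_id <- id
    return(member)
  }
  if (inherits(member, "phantom_case"))
    return(phase4d_study(list(list(label = "0%", image = member$image,
                                   truth = member$heart)),
                         patient_id = id))
  stop("cohort members must be phantom cases or 4D studies")
}

# Crop every phase of a study to the heart VOI derived from its first phase.
crop_study <- function(study, cfg) {
  lungs <- segment_lungs(study$phases[[1]]$image, cfg$hu_threshold,
                         cfg$min_component_mm3)
  box <- heart_voi(lungs, cfg$margin_mm)
  study$phases <- lapply(study$phases, function(ph) {
    ph$image <- crop(ph$image, box)
    if (!is.null(ph$truth)) ph$truth <- crop(ph$truth, box)
    ph
  })
  study$box <- box
  study
}

# Atlas entry from a (cropped) study: its 0% phase image and truth mask.
study_as_atlas <- function(study) {
  ph <- study$phases[[1]]
  if (is.null(ph$truth)) stop("atlas member lacks a heart delineation")
  atlas_entry(study$patient_id, ph$image, ph$truth)
}

#' Segment one study against an atlas set and evaluate
#'
#' Crops the target study to its heart volume of interest, runs
#' [segment_study()] in the configured mode, and, when ground-truth masks are
#' present, evaluates every per-phase delineation (and the PRV against the
#' union of per-phase truths) with [dsc()], [masd()] and [hd()].
#'
#' @param target a `phantom_case` or [phase4d_study()] with truth masks.
#' @param atlas_members list of cohort members used as atlases (their 0%
#'   images and truth delineations), or ready-made [atlas_entry()]s.
#' @param cfg a [pipeline_config()].
#' @return List with `segmentation` (per-phase masks + PRV), `results`
#'   (metrics data.frame) and `study` (the cropped target).
#' @export
run_single <- function(target, atlas_members, cfg = pipeline_config()) {
  study <- crop_study(as_study(target, "target"), cfg)
  atl <- lapply(seq_along(atlas_members), function(j) {
    m <- atlas_members[[j]]
    if (inherits(m, "atlas_entry")) m
    else study_as_atlas(crop_study(as_study(m, paste0("A", j)), cfg))
  })
  seg <- segment_study(study, atl, cfg$mode, cfg$reg, cfg$fusion)
  results <- evaluate_study(study, seg)
  list(segmentation = seg, results = results, study = study)
}

evaluate_study <- function(study, seg) {
  rows <- list()
  truths <- list()
  for (ph in study$phases) {
    if (is.null(ph$truth) || sum(ph$truth$values) == 0) next
    truths[[ph$label]] <- ph$truth
    m <- seg$masks[[ph$label]]
    rows[[length(rows) + 1L]] <-
      data.frame(patient = study$patient_id, phase = ph$label,
                 dsc = dsc(m, ph$truth), masd_mm = masd(m, ph$truth),
                 hd_mm = hd(m, ph$truth), stringsAsFactors = FALSE)
  }
  if (length(truths) >= 2) {
    prv_ref <- build_prv(truths)
    rows[[length(rows) + 1L]] <-
      data.frame(patient = study$patient_id, phase = "PRV",
                 dsc = dsc(seg$prv, prv_ref),
                 masd_mm = masd(seg$prv, prv_ref),
                 hd_mm = hd(seg$prv, prv_ref), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Leave-one-out experiment over a cohort
#'
#' For each cohort member, all remaining members form the atlas set; the
#' member is cropped, segmented in the configured mode, its PRV built, and
#' the results evaluated against its ground truth. Per-case failures are
#' caught, logged and excluded from aggregation, with the failure count
#' surfaced in the report. The whole run is determined by the cohort,
#' configuration and seed.
#'
#' @param cohort list of >= 4 members (`phantom_case` or [phase4d_study()]
#'   with truth masks).
#' @param cfg a [pipeline_config()].
#' @param verbose print per-case progress?
#' @return List with `table` (the [cohort_table()]), `results` (per-case
#'   rows), `cases` (per-case segmentations), `n_failed`, `failed_ids`.
#' @export
run_leave_one_out <- function(cohort, cfg = pipeline_config(),
                              verbose = FALSE) {
  if (length(cohort) < 4)
    stop("leave-one-out needs >= 4 cohort members (target + 3 atlases)")
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(cohort))
  all_rows <- list()
  cases <- list()
  failed <- character()
  for (i in seq_along(cohort)) {
    res <- try({
      target <- as_study(cohort[[i]], ids[i])
      target$patient_id <- ids[i]
      run_single(target, cohort[-i], cfg)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- c(failed, ids[i])
      message("case ", ids[i], " failed: ",
              trimws(attr(res, "condition")$message %||% "unknown"))
      next
    }
    if (verbose)
      message(sprintf("case %s: mean DSC %.3f", ids[i],
                      mean(res$results$dsc[res$results$phase != "PRV"])))
    cases[[ids[i]]] <- res$segmentation
    all_rows[[length(all_rows) + 1L]] <- res$results
  }
  if (length(all_rows) == 0L) stop("every leave-one-out case failed")
  results <- do.call(rbind, all_rows)
  list(table = cohort_table(results), results = results, cases = cases,
       n_failed = length(failed), failed_ids = failed)
}

# ---- manifests and config files -------------------------------------------

#' Read an experiment manifest
#'
#' A YAML file listing cohort members: each patient has an `id`, a `phases`
#' map from phase label to image path, and optionally a `truth` map from
#' phase label to mask path. Paths are resolved relative to the manifest
#' location.
#'
#' @param path manifest YAML path.
#' @return List of [phase4d_study()] objects.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  pats <- man$patients
  if (is.null(pats) || length(pats) == 0) stop("manifest lists no patients")
  ids <- vapply(pats, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids in manifest")
  studies <- lapply(pats, function(p) {
    labels <- names(p$phases)
    phases <- lapply(labels, function(lb) {
      ph <- list(label = lb, image = read_volume(resolve(p$phases[[lb]])))
      tp <- p$truth[[lb]]
      if (!is.null(tp))
        ph$truth <- read_volume(resolve(tp), as_mask = TRUE, role = "truth")
      ph
    })
    phase4d_study(phases, patient_id = p$id)
  })
  names(studies) <- ids
  studies
}

#' Write a cohort of studies to disk with a manifest
#'
#' Writes every phase image (and truth mask) as NIfTI under `dir` and a
#' `manifest.yaml` indexing them, the on-disk form consumed by the command
#' line tools and [read_manifest()].
#'
#' @param studies list of [phase4d_study()] (or `phantom_case`) objects.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(studies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(studies), function(i) {
    st <- as_study(studies[[i]],
                   names(studies)[i] %||% sprintf("P%02d", i))
    id <- st$patient_id
    phases <- list(); truth <- list()
    for (ph in st$phases) {
      tag <- gsub("%", "", ph$label)
      img_rel <- sprintf("%s_phase%s.nii.gz", id, tag)
      write_volume(ph$image, file.path(dir, img_rel))
      phases[[ph$label]] <- img_rel
      if (!is.null(ph$truth)) {
        tr_rel <- sprintf("%s_phase%s_truth.nii.gz", id, tag)
        write_volume(ph$truth, file.path(dir, tr_rel))
        truth[[ph$label]] <- tr_rel
      }
    }
    out <- list(id = id, phases = phases)
    if (length(truth)) out$truth <- truth
    out
  })
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(patients = entries), path)
  invisible(path)
}

#' Echo a pipeline configuration to YAML
#'
#' Serializes every parameter of a [pipeline_config()] (including the nested
#' registration and fusion configurations) so each output directory carries
#' the full provenance of the run.
#'
#' @param cfg a [pipeline_config()].
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}
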