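#' Total metabolic tumour volume of one patient, one method, one observer
#'
#' Segments every observer box with the given method and combines the
#' per-lesion masks into a patient total. Voxel-based methods are combined by
#' the union of suprathreshold voxels (each voxel counted once even when
#' observer boxes overlap); the fitting method, whose per-lesion MTV is an
#' analytic sphere volume, sums over boxes.
#'
#' @param volume an `suv_volume`.
#' @param boxes list of `lesion_box`es placed by one observer.
#' @param spec a [method_spec()].
#' @param liver a `liver_stats`.
#' @param double_count if TRUE, overlapping masks are summed instead of
#'   unioned (documented deviation toggle; default FALSE).
#' @param background optional fixed background SUV forwarded to the adaptive
#'   methods instead of the per-box shell estimate.
#' @return list with `mtv_cm3`, per-lesion `masks`, and `thresholds`.
#' @export
total_mtv <- function(volume, boxes, spec, liver = NULL, double_count = FALSE,
                      background = NULL) {
  if (!length(boxes)) return(list(mtv_cm3 = 0, masks = list(), thresholds = numeric(0)))
  masks <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    masks[[i]] <- tryCatch(
      segment_lesion(volume, boxes[[i]], spec, liver = liver,
                     background = background, other_boxes = boxes[-i]),
      error = function(e)
        stop(sprintf("lesion box %d (%s): %s", i, spec$name, conditionMessage(e)),
             call. = FALSE))
  }
  if (spec$name == "fitting") {
    mtv <- sum(vapply(masks, lesion_mtv_cm3, 0))
  } else if (double_count) {
    mtv <- sum(vapply(masks, lesion_mtv_cm3, 0))
  } else {
    idx <- unique(unlist(lapply(masks, `[[`, "indices")))
    mtv <- mask_volume_cm3(length(idx), volume$spacing)
  }
  list(mtv_cm3 = mtv, masks = masks,
       thresholds = vapply(masks, function(m) m$threshold, 0))
}

#' Organ inclusion rules for bone marrow and spleen
#'
#' Bone marrow enters the MTV only with focal uptake. The spleen enters with
#' focal uptake, or with diffuse uptake strictly higher than 150% of the
#' liver background (diffuse uptake exactly at 1.5 x liver is excluded).
#'
#' @param spleen_state one of "absent", "focal", "diffuse".
#' @param spleen_diffuse_suv diffuse spleen SUV (used only when diffuse).
#' @param liver_background liver reference SUV (SUVmean).
#' @param marrow_state one of "absent", "focal", "diffuse".
#' @return list with logicals `spleen_included`, `marrow_included`.
#' @export
organ_inclusion <- function(spleen_state = "absent", spleen_diffuse_suv = 0,
                            liver_background = 0, marrow_state = "absent") {
  spleen_state <- match.arg(spleen_state, c("absent", "focal", "diffuse"))
  marrow_state <- match.arg(marrow_state, c("absent", "focal", "diffuse"))
  if (spleen_diffuse_suv < 0 || liver_background < 0) stop("SUV values must be >= 0")
  spleen <- spleen_state == "focal" ||
    (spleen_state == "diffuse" && spleen_diffuse_suv > 1.5 * liver_background)
  marrow <- marrow_state == "focal"
  list(spleen_included = spleen, marrow_included = marrow)
}

#' Measure one phantom patient with several methods and observers
#'
#' Computes liver statistics automatically from the ground-truth liver ROI
#' (shared by both observers), applies the organ-inclusion rules, and returns
#' the per-(method, observer) total MTV. An included organ contributes a
#' dedicated organ box segmented by the active method.
#'
#' @param volume an `suv_volume`.
#' @param truth the matching `phantom_truth`.
#' @param boxes_by_observer list (one element per observer) of box lists.
#' @param methods named list of [method_spec()]s.
#' @return data.frame with columns observer, method, mtv_cm3,
#'   spleen_included, marrow_included.
#' @export
measure_patient <- function(volume, truth, boxes_by_observer, methods) {
  liver <- compute_liver_stats(volume, truth$liver$center_mm, truth$liver$radius_mm)
  inc <- organ_inclusion(truth$spleen$state,
                         spleen_diffuse_suv = if (!is.null(truth$spleen$suv)) truth$spleen$suv else 0,
                         liver_background = liver$suv_mean,
                         marrow_state = truth$marrow$state)
  organ_boxes <- list()
  add_organ <- function(desc) {
    b <- sphere_tight_box(truth$dim, truth$spacing, truth$origin,
                          desc$center_mm, desc$radius_mm)
    mb <- ceiling((truth$psf_fwhm_mm + 4) / truth$spacing)
    lesion_box(pmax(b$low - mb, 0), pmin(b$high + mb, truth$dim))
  }
  if (inc$spleen_included) organ_boxes <- c(organ_boxes, list(add_organ(truth$spleen)))
  if (inc$marrow_included) organ_boxes <- c(organ_boxes, list(add_organ(truth$marrow)))

  rows <- list()
  for (obs in seq_along(boxes_by_observer)) {
    boxes <- c(boxes_by_observer[[obs]], organ_boxes)
    for (mn in names(methods)) {
      tm <- total_mtv(volume, boxes, methods[[mn]], liver = liver)
      rows[[length(rows) + 1L]] <- data.frame(
        observer = obs, method = mn, mtv_cm3 = tm$mtv_cm3,
        spleen_included = inc$spleen_included,
        marrow_included = inc$marrow_included)
    }
  }
  do.call(rbind, rows)
}
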