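#' Overall normal-appearing white matter mask
#'
#' Tissue classified as NAWM at all time points and at least 2 mm (exact
#' Euclidean distance, anisotropic voxel spacing respected) from any voxel
#' classified as T2 lesion at any study time point. "At least 2 mm away" is
#' read inclusively: voxels at exactly `dist_mm` are retained.
#'
#' @param series subject series with per-timepoint tissue maps and lesion
#'   masks.
#' @param dist_mm exclusion radius (mm, default 2).
#' @return logical mask.
#' @export
compute_overall_nawm <- function(series, dist_mm = 2) {
  lab <- tissue_labels()
  nawm_all <- Reduce(`&`, lapply(series$timepoints,
                                 function(tp) tp$tissue == lab["wm"]))
  les_union <- Reduce(`|`, lapply(series$timepoints, `[[`, "lesion_mask"))
  nawm_all & !exclusion_zone(les_union, series$pixdim, dist_mm)
}

#' Define the pre-lesion ROI of a tracked lesion event
#'
#' Starts from the event's end-of-study residual mask and retains voxels
#' that are (i) classified as NAWM at every analysed visit strictly before
#' lesion onset and (ii) at least `dist_mm` from every pre-existing lesion
#' voxel at every pre-onset visit. Rejection (fewer than `min_voxels`
#' survivors, i.e. below 10 voxels = 30 mm^3 at default spacing) is a
#' status, not an error.
#'
#' @param event `"lesion_event"` with a residual mask.
#' @param series the subject series.
#' @param min_voxels size filter (default 10).
#' @param dist_mm exclusion radius (mm, default 2; strict `<` exclusion).
#' @return list: `mask` (or `NULL`), `status` one of `accepted`,
#'   `rejected_tissue`, `rejected_distance`, `rejected_size`, and
#'   `n_voxels`.
#' @export
define_prelesion_roi <- function(event, series, min_voxels = 10L, dist_mm = 2) {
  lab <- tissue_labels()
  pre_idx <- which(vapply(series$timepoints, `[[`, numeric(1), "week") <
                     event$first_seen_week)
  cand <- event$residual_mask
  if (!any(cand))
    return(list(mask = NULL, status = "rejected_size", n_voxels = 0L))

  # (ii) NAWM at all pre-onset visits
  for (vi in pre_idx) cand <- cand & (series$timepoints[[vi]]$tissue == lab["wm"])
  if (!any(cand))
    return(list(mask = NULL, status = "rejected_tissue", n_voxels = 0L))

  # (iii) >= dist_mm from any pre-existing lesion at all pre-onset visits
  pre_lesions <- Reduce(`|`, lapply(series$timepoints[pre_idx], `[[`, "lesion_mask"),
                        accumulate = FALSE,
                        init = array(FALSE, dim(cand)))
  if (any(pre_lesions)) {
    d <- distance_to_mask(cand, pre_lesions, series$pixdim)
    keep <- which(cand)[d >= dist_mm]
    cand <- array(FALSE, dim(cand)); cand[keep] <- TRUE
  }
  if (!any(cand))
    return(list(mask = NULL, status = "rejected_distance", n_voxels = 0L))
  if (sum(cand) < min_voxels)
    return(list(mask = NULL, status = "rejected_size", n_voxels = sum(cand)))
  list(mask = cand, status = "accepted", n_voxels = sum(cand))
}

#' Build a mirror-matched pre-lesion / contralateral ROI pair
#'
#' The contralateral ROI is the pre-lesion ROI reflected across the brain
#' midline, adjusted so that only portions classified as NAWM and at least
#' `dist_mm` from T2 lesions at *all* time points remain; any adjustment is
#' applied back to the pre-lesion ROI via reflection, so the final masks
#' are exact mirrors. Pairs below `min_voxels` are rejected.
#'
#' @param prelesion_mask accepted pre-lesion mask from
#'   [define_prelesion_roi()].
#' @param series the subject series.
#' @param lesion_id identifier carried into the pair.
#' @param min_voxels,dist_mm filters as in [define_prelesion_roi()].
#' @return object of class `"roi_pair"`: `lesion_id`, `prelesion_mask`,
#'   `contralateral_mask`, `n_voxels`, `qc_status`.
#' @export
define_pair <- function(prelesion_mask, series, lesion_id = NA_character_,
                        min_voxels = 10L, dist_mm = 2) {
  lab <- tissue_labels()
  contra <- reflect_across_midline(prelesion_mask)

  nawm_all <- Reduce(`&`, lapply(series$timepoints,
                                 function(tp) tp$tissue == lab["wm"]))
  contra <- contra & nawm_all
  les_union <- Reduce(`|`, lapply(series$timepoints, `[[`, "lesion_mask"))
  if (any(contra) && any(les_union)) {
    d <- distance_to_mask(contra, les_union, series$pixdim)
    keep <- which(contra)[d >= dist_mm]
    contra <- array(FALSE, dim(contra)); contra[keep] <- TRUE
  }
  pre <- reflect_across_midline(contra)   # reflect adjustments back

  n <- sum(pre)
  status <- if (n >= min_voxels) "accepted" else "rejected_size"
  structure(list(lesion_id = lesion_id,
                 prelesion_mask = if (status == "accepted") pre else NULL,
                 contralateral_mask = if (status == "accepted") contra else NULL,
                 n_voxels = n, qc_status = status),
            class = "roi_pair")
}

#' Derive all accepted ROI pairs of a subject
#'
#' Applies [define_prelesion_roi()] and [define_pair()] to every tracked
#' lesion event and returns the pairs plus a QC ledger of rejection
#' reasons.
#'
#' @param series subject series.
#' @param events list of `"lesion_event"` objects (from
#'   [find_lesion_events()]).
#' @param min_voxels,dist_mm ROI filters.
#' @return list: `pairs` (accepted `"roi_pair"`s), `qc` (data.frame of
#'   lesion_id, stage, status, n_voxels).
#' @export
derive_roi_pairs <- function(series, events, min_voxels = 10L, dist_mm = 2) {
  pairs <- list()
  qc <- list()
  for (e in events) {
    roi <- define_prelesion_roi(e, series, min_voxels, dist_mm)
    if (roi$status != "accepted") {
      qc[[length(qc) + 1L]] <- data.frame(lesion_id = e$lesion_id,
                                          stage = "prelesion", status = roi$status,
                                          n_voxels = roi$n_voxels)
      next
    }
    pair <- define_pair(roi$mask, series, e$lesion_id, min_voxels, dist_mm)
    qc[[length(qc) + 1L]] <- data.frame(lesion_id = e$lesion_id, stage = "pair",
                                        status = pair$qc_status,
                                        n_voxels = pair$n_voxels)
    if (pair$qc_status == "accepted") {
      pair$first_seen_week <- e$first_seen_week
      pair$prior_reference_week <- e$prior_reference_week
      pairs[[length(pairs) + 1L]] <- pair
    }
  }
  list(pairs = pairs,
       qc = if (length(qc)) do.call(rbind, qc)
            else data.frame(lesion_id = character(0), stage = character(0),
                            status = character(0), n_voxels = integer(0)))
}
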