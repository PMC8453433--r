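#' Detect new T2 lesions between two consecutive analysed visits
#'
#' 26-connected components of the current T2 lesion mask that do not
#' intersect the 1-voxel (26-neighbourhood) dilation of the previous mask
#' and contain at least `min_voxels` voxels. Components touching a previous
#' lesion after dilation are classified as enlargements of existing lesions
#' and excluded, not reported as new.
#'
#' @param prev_mask,curr_mask co-registered logical 3D arrays (same grid).
#' @param min_voxels minimum component size at detection (default 3; the
#'   10-voxel ROI size filter is applied later).
#' @return list of new-lesion components, each `list(mask, n_voxels)`.
#' @export
detect_new_t2 <- function(prev_mask, curr_mask, min_voxels = 3L) {
  if (!identical(dim(prev_mask), dim(curr_mask)))
    stop("detect_new_t2: grid mismatch between masks")
  if (!any(curr_mask)) return(list())
  dprev <- if (any(prev_mask)) dilate_mask(prev_mask, rbind(c(0L, 0L, 0L), neigh26()))
           else array(FALSE, dim(prev_mask))
  labs <- label_components(curr_mask)
  out <- list()
  for (id in seq_len(max(labs))) {
    comp <- labs == id
    if (any(comp & dprev)) next          # enlargement of an existing lesion
    if (sum(comp) < min_voxels) next
    out[[length(out) + 1L]] <- list(mask = comp, n_voxels = sum(comp))
  }
  out
}

#' Track a new-lesion event to end of study
#'
#' Starting from the detection mask, the per-visit tracked mask at each
#' subsequent analysed visit is the connected overlap of the previous
#' tracked mask with that visit's T2 lesion mask (26-connectivity). The
#' residual mask is the final visit's tracked extent; events that fully
#' resolve are retained with residual volume 0 (they fail the ROI size
#' filter downstream).
#'
#' @param event list with at least `mask` (detection mask),
#'   `first_seen_week`, `prior_reference_week`.
#' @param subsequent_masks list of T2 lesion masks at the analysed visits
#'   after first detection (in time order).
#' @param pixdim voxel spacing (mm) for the residual volume.
#' @return `"lesion_event"` object: detection metadata, `masks` (per visit
#'   from first seen to end), `residual_mask`, `residual_volume` (mm^3).
#' @export
track_to_end <- function(event, subsequent_masks, pixdim = c(1, 1, 3)) {
  cur <- event$mask
  masks <- list(cur)
  for (m in subsequent_masks) {
    if (!identical(dim(m), dim(cur))) stop("track_to_end: grid mismatch")
    cur <- cur & m                      # overlap stays within the tracked extent
    masks[[length(masks) + 1L]] <- cur
  }
  structure(c(event[setdiff(names(event), "mask")],
              list(detection_mask = event$mask, masks = masks,
                   residual_mask = cur,
                   residual_volume = sum(cur) * prod(pixdim))),
            class = "lesion_event")
}

#' Find and track all new-lesion events of a subject series
#'
#' Runs [detect_new_t2()] over each consecutive visit pair and
#' [track_to_end()] on every detection.
#'
#' @param series subject series with per-timepoint `lesion_mask`.
#' @param min_voxels detection size threshold.
#' @return list of `"lesion_event"` objects with `lesion_id` fields.
#' @export
find_lesion_events <- function(series, min_voxels = 3L) {
  tps <- series$timepoints
  weeks <- vapply(tps, `[[`, numeric(1), "week")
  events <- list()
  for (vi in seq_along(tps)[-1]) {
    found <- detect_new_t2(tps[[vi - 1L]]$lesion_mask, tps[[vi]]$lesion_mask,
                           min_voxels)
    for (f in found) {
      ev <- list(mask = f$mask, n_voxels = f$n_voxels,
                 subject_id = series$subject_id,
                 first_seen_week = weeks[vi],
                 prior_reference_week = weeks[vi - 1L],
                 onset_visit = vi)
      later <- if (vi < length(tps))
        lapply(tps[(vi + 1L):length(tps)], `[[`, "lesion_mask") else list()
      events[[length(events) + 1L]] <- track_to_end(ev, later, series$pixdim)
    }
  }
  for (i in seq_along(events))
    events[[i]]$lesion_id <- sprintf("%s_L%02d", series$subject_id, i)
  events
}

#' Tabulate lesion events
#' @param events list of `"lesion_event"` objects.
#' @return data.frame (one row per event) suitable for the event TSV.
#' @export
lesion_event_table <- function(events) {
  if (length(events) == 0)
    return(data.frame(lesion_id = character(0), subject_id = character(0),
                      first_seen_week = numeric(0),
                      prior_reference_week = numeric(0),
                      n_voxels = integer(0), residual_voxels = integer(0),
                      residual_volume = numeric(0)))
  do.call(rbind, lapply(events, function(e) data.frame(
    lesion_id = e$lesion_id, subject_id = e$subject_id,
    first_seen_week = e$first_seen_week,
    prior_reference_week = e$prior_reference_week,
    n_voxels = e$n_voxels, residual_voxels = sum(e$residual_mask),
    residual_volume = e$residual_volume, stringsAsFactors = FALSE)))
}
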