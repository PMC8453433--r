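#' Scanner-specific MTR calibration from a reference healthy control
#'
#' Computes the median MTR over grey-matter and white-matter labelled voxels
#' of a reference healthy-control scan on a given scanner. The two medians
#' are subsequently used as scanner-specific normalization factors for all
#' patient scans acquired on the same scanner: the GM median maps to 0, the
#' WM median to 1 (see [normalize_mtr()]). Medians with even counts are the
#' mean of the two central values (the R default).
#'
#' @param hc_series healthy-control series (class `"nawm_series"`) whose
#'   first timepoint supplies the MTR volume.
#' @param tissue_map optional label map overriding the series' own.
#' @return object of class `"scanner_calibration"`:
#'   `scanner_id`, `median_gm_mtr`, `median_wm_mtr`.
#' @export
calibrate_mtr <- function(hc_series, tissue_map = NULL) {
  tp <- hc_series$timepoints[[1]]
  if (is.null(tissue_map)) tissue_map <- tp$tissue
  lab <- tissue_labels()
  mtr <- tp$volumes$mtr
  gm_vox <- mtr[tissue_map == lab["gm"]]
  wm_vox <- mtr[tissue_map == lab["wm"]]
  if (length(gm_vox) == 0) stop("calibrate_mtr: empty grey-matter mask")
  if (length(wm_vox) == 0) stop("calibrate_mtr: empty white-matter mask")
  gm <- stats::median(gm_vox)
  wm <- stats::median(wm_vox)
  if (wm <= gm)
    stop("calibrate_mtr: white-matter median (", signif(wm, 6),
         ") must exceed grey-matter median (", signif(gm, 6), ")")
  structure(list(scanner_id = hc_series$scanner_id,
                 median_gm_mtr = gm, median_wm_mtr = wm),
            class = "scanner_calibration")
}

#' Save / load a scanner calibration as JSON
#' @param calibration a `"scanner_calibration"`.
#' @param path JSON file path.
#' @return the calibration (invisibly for write).
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE, digits = NA)
  invisible(calibration)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "scanner_calibration")
}

#' Normalize an MTR volume against a scanner calibration
#'
#' Voxel-wise affine map `(mtr - median_gm) / (median_wm - median_gm)`:
#' the MTR value of median healthy grey matter maps to 0 and of median
#' healthy white matter to 1, so normalized MTR is interpretable across
#' scanners (0 = healthy GM, 1 = healthy WM).
#'
#' @param mtr_volume 3D array of raw MTR.
#' @param calibration a `"scanner_calibration"` from the same scanner.
#' @return normalized volume (same shape/attributes).
#' @export
normalize_mtr <- function(mtr_volume, calibration) {
  out <- (mtr_volume - calibration$median_gm_mtr) /
    (calibration$median_wm_mtr - calibration$median_gm_mtr)
  attributes(out) <- attributes(mtr_volume)
  out
}

#' Least-trimmed-squares affine intensity fit
#'
#' Robust fit of `moving ~ gain * reference + offset` minimizing the sum of
#' the `h = floor(fraction * n)` smallest squared residuals (with the
#' default `fraction = 0.5`, the half of voxels whose least-squares fit has
#' the smallest sum of squared residuals). Optimized by concentration
#' steps: from a random size-`h` subset, iterate (OLS on subset; re-select
#' the `h` smallest-residual voxels) until the subset is a fixed point, over
#' `n_starts` random starts, keeping the best objective. As in the
#' standard fast-LTS scheme, every start gets two concentration steps and
#' only the `refine_top` most promising candidates are iterated to full
#' convergence. The objective is non-increasing across C-steps (asserted).
#' Deterministic under `seed`.
#'
#' @param reference_volume,moving_volume numeric arrays/vectors of equal
#'   length (the co-registered scan pair).
#' @param mask optional logical array selecting fit voxels (default: all).
#' @param fraction trimming fraction in (0, 1]; 1 gives ordinary least
#'   squares.
#' @param n_starts random restarts (ignored when `fraction = 1`).
#' @param max_iter C-step cap per start.
#' @param refine_top number of best candidate subsets iterated to
#'   convergence.
#' @param seed RNG seed for subset draws (RNG state is restored on exit).
#' @return object of class `"affine_intensity_map"`: `gain`, `offset`,
#'   `n_retained`, `objective` (trimmed sum of squares), `retained`
#'   (indices into the masked voxel vector).
#' @export
lts_fit <- function(reference_volume, moving_volume, mask = NULL,
                    fraction = 0.5, n_starts = 50L, max_iter = 100L,
                    refine_top = 5L, seed = 171L) {
  x <- as.vector(reference_volume)
  y <- as.vector(moving_volume)
  if (length(x) != length(y)) stop("lts_fit: volumes differ in length")
  if (!is.null(mask)) { x <- x[as.vector(mask)]; y <- y[as.vector(mask)] }
  n <- length(x)
  if (n < 4) stop("lts_fit: mask must contain at least 4 voxels")
  if (fraction <= 0 || fraction > 1) stop("lts_fit: fraction must be in (0, 1]")
  h <- floor(fraction * n)
  if (h < 2) stop("lts_fit: trimmed subset too small")

  # indices of the h smallest values; ties at the threshold resolved by
  # voxel index (deterministic, no full sort)
  select_h <- function(r2, h) {
    thr <- sort(r2, partial = h)[h]
    cand <- which(r2 <= thr)
    if (length(cand) > h) {
      strict <- cand[r2[cand] < thr]
      ties <- cand[r2[cand] >= thr]   # == thr up to representation
      cand <- c(strict, ties[seq_len(h - length(strict))])
    }
    sort(cand)
  }
  ols <- function(idx) {
    xs <- x[idx]; ys <- y[idx]
    sxx <- stats::var(xs)
    if (!is.finite(sxx) || sxx <= 0) return(NULL)   # degenerate subset
    g <- stats::cov(xs, ys) / sxx
    c(gain = g, offset = mean(ys) - g * mean(xs))
  }
  if (fraction == 1) {
    cf <- ols(seq_len(n))
    if (is.null(cf))
      stop("lts_fit: degenerate intensities (zero variance on subset)")
    r2 <- (y - cf["offset"] - cf["gain"] * x)^2
    return(structure(list(gain = unname(cf["gain"]), offset = unname(cf["offset"]),
                          n_retained = n, objective = sum(r2),
                          retained = seq_len(n)),
                     class = "affine_intensity_map"))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # run C-steps from a coefficient pair; returns subset/objective/coefs
  c_steps <- function(cf, n_iter) {
    obj_prev <- Inf
    idx <- integer(0)
    for (it in seq_len(n_iter)) {
      r2 <- (y - cf["offset"] - cf["gain"] * x)^2
      new_idx <- select_h(r2, h)
      obj <- sum(r2[new_idx])
      stopifnot(obj <= obj_prev + 1e-9 * (1 + abs(obj_prev)))  # C-step monotone
      converged <- identical(new_idx, idx) ||
        abs(obj_prev - obj) < 1e-14 * (1 + obj)
      idx <- new_idx; obj_prev <- obj
      if (converged) break
      cf2 <- ols(idx)
      if (is.null(cf2)) return(NULL)    # degenerate subset: drop start
      cf <- cf2
    }
    list(cf = cf, idx = idx, objective = obj_prev)
  }

  cands <- list()
  for (s in seq_len(n_starts)) {
    # elemental start: the exact line through two voxels with distinct
    # reference values, then two concentration steps
    cf <- NULL
    for (try in 1:20) {
      ij <- sample.int(n, 2)
      if (x[ij[1]] != x[ij[2]]) {
        g <- (y[ij[2]] - y[ij[1]]) / (x[ij[2]] - x[ij[1]])
        cf <- c(gain = g, offset = y[ij[1]] - g * x[ij[1]])
        break
      }
    }
    if (is.null(cf)) next
    cand <- c_steps(cf, 2L)
    if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
  }
  if (length(cands) == 0)
    stop("lts_fit: degenerate intensities (zero variance on subset)")
  ord <- order(vapply(cands, `[[`, numeric(1), "objective"))
  best <- NULL
  for (k in ord[seq_len(min(refine_top, length(ord)))]) {
    fin <- c_steps(cands[[k]]$cf, max_iter)
    if (is.null(fin)) next
    if (is.null(best) || fin$objective < best$objective) best <- fin
  }
  if (is.null(best))
    stop("lts_fit: degenerate intensities (zero variance on subset)")
  structure(list(gain = unname(best$cf["gain"]),
                 offset = unname(best$cf["offset"]),
                 n_retained = h, objective = best$objective,
                 retained = best$idx),
            class = "affine_intensity_map")
}

#' Map a volume into a reference intensity frame
#'
#' Inverts the fitted `moving = gain * reference + offset` relation:
#' `aligned = (moving - offset) / gain`.
#'
#' @param vol volume in the moving frame.
#' @param map an `"affine_intensity_map"` from [lts_fit()].
#' @return volume expressed on the reference scale.
#' @export
apply_intensity_map <- function(vol, map) {
  out <- (vol - map$offset) / map$gain
  attributes(out) <- attributes(vol)
  out
}

# Voxels eligible for the longitudinal LTS fit: brain tissue excluding
# lesions at either timepoint (spec default; the paper leaves the fit
# support unstated).
lts_support <- function(series, vi, max_voxels = 20000L) {
  lab <- tissue_labels()
  base <- series$timepoints[[1]]$tissue
  cur <- series$timepoints[[vi]]$tissue
  keep <- array(as.vector(base) %in% c(lab["csf"], lab["gm"], lab["wm"]) &
                  as.vector(cur) %in% c(lab["csf"], lab["gm"], lab["wm"]),
                dim(base))
  n <- sum(keep)
  if (n > max_voxels) {      # deterministic even thinning for speed
    vox <- which(keep)
    sel <- vox[round(seq(1L, n, length.out = max_voxels))]
    keep <- array(FALSE, dim(base)); keep[sel] <- TRUE
  }
  keep
}

#' Two-stage normalization of T1-weighted intensities
#'
#' Stage 1 (cross-sectional, baseline): affine map sending the median
#' grey-matter intensity to 0 and the median NAWM intensity to 1. Stage 2
#' (longitudinal): each follow-up is mapped onto the baseline scale by a
#' least-trimmed-squares fit over brain voxels (excluding lesions), then
#' the stage-1 map is applied. The baseline output therefore satisfies
#' median(GM) = 0 and median(NAWM) = 1 exactly, and the outputs are
#' invariant to any global affine distortion of a follow-up scan.
#'
#' @param series subject series with tissue maps.
#' @param fraction,n_starts,seed LTS parameters (see [lts_fit()]).
#' @return list of normalized volumes, one per timepoint.
#' @export
normalize_t1 <- function(series, fraction = 0.5, n_starts = 50L, seed = 171L,
                         lts_max_voxels = 6000L) {
  lab <- tissue_labels()
  base_tp <- series$timepoints[[1]]
  base <- base_tp$volumes$t1w
  gm <- base[base_tp$tissue == lab["gm"]]
  nawm <- base[base_tp$tissue == lab["wm"]]
  if (length(nawm) == 0) stop("normalize_t1: empty NAWM mask at baseline")
  if (length(gm) == 0) stop("normalize_t1: empty grey-matter mask at baseline")
  m_gm <- stats::median(gm); m_wm <- stats::median(nawm)
  if (m_wm == m_gm) stop("normalize_t1: GM and NAWM medians coincide")
  stage1 <- function(v) (v - m_gm) / (m_wm - m_gm)

  out <- vector("list", length(series$timepoints))
  out[[1]] <- stage1(base)
  for (vi in seq_along(series$timepoints)[-1]) {
    mov <- series$timepoints[[vi]]$volumes$t1w
    map <- lts_fit(base, mov, mask = lts_support(series, vi, lts_max_voxels),
                   fraction = fraction, n_starts = n_starts,
                   seed = seed + vi)
    out[[vi]] <- stage1(apply_intensity_map(mov, map))
  }
  for (vi in seq_along(out)) attr(out[[vi]], "pixdim") <- series$pixdim
  out
}

#' Two-stage normalization of T2-weighted intensities
#'
#' Stage 1: each follow-up is mapped onto the baseline scale by a
#' least-trimmed-squares fit (as in [normalize_t1()]). Stage 2: mean
#' normalization to NAWM using the baseline NAWM statistics, so that mean
#' NAWM maps to 0 and one unit of normalized T2 intensity represents one
#' intensity standard deviation of NAWM. The baseline output has
#' mean(NAWM) = 0 and sd(NAWM) = 1 exactly (sample SD, n - 1 denominator).
#'
#' @inheritParams normalize_t1
#' @return list of normalized volumes, one per timepoint.
#' @export
normalize_t2 <- function(series, fraction = 0.5, n_starts = 50L, seed = 171L,
                         lts_max_voxels = 6000L) {
  lab <- tissue_labels()
  base_tp <- series$timepoints[[1]]
  base <- base_tp$volumes$t2w
  nawm_mask <- base_tp$tissue == lab["wm"]
  if (!any(nawm_mask)) stop("normalize_t2: empty NAWM mask at baseline")
  m <- mean(base[nawm_mask]); s <- stats::sd(base[nawm_mask])
  if (!is.finite(s) || s == 0)
    stop("normalize_t2: zero NAWM intensity SD at baseline")
  stage2 <- function(v) (v - m) / s

  out <- vector("list", length(series$timepoints))
  out[[1]] <- stage2(base)
  for (vi in seq_along(series$timepoints)[-1]) {
    mov <- series$timepoints[[vi]]$volumes$t2w
    map <- lts_fit(base, mov, mask = lts_support(series, vi, lts_max_voxels),
                   fraction = fraction, n_starts = n_starts,
                   seed = seed + 100L + vi)
    out[[vi]] <- stage2(apply_intensity_map(mov, map))
  }
  for (vi in seq_along(out)) attr(out[[vi]], "pixdim") <- series$pixdim
  out
}

#' Normalize all channels of a subject series
#'
#' Convenience wrapper: applies [normalize_mtr()] per timepoint (using the
#' scanner calibration), [normalize_t1()] and [normalize_t2()], and stores
#' the results as `timepoints[[k]]$normalized${nmtr,nt1,nt2}`.
#'
#' @param series subject series.
#' @param calibration `"scanner_calibration"` for the series' scanner.
#' @param ... passed to the T1/T2 normalizers.
#' @return the series with normalized volumes attached.
#' @export
normalize_series <- function(series, calibration, ...) {
  if (!identical(calibration$scanner_id, series$scanner_id))
    stop("normalize_series: calibration scanner (", calibration$scanner_id,
         ") does not match series scanner (", series$scanner_id, ")")
  nt1 <- normalize_t1(series, ...)
  nt2 <- normalize_t2(series, ...)
  for (vi in seq_along(series$timepoints)) {
    series$timepoints[[vi]]$normalized <- list(
      nmtr = normalize_mtr(series$timepoints[[vi]]$volumes$mtr, calibration),
      nt1 = nt1[[vi]], nt2 = nt2[[vi]])
  }
  series
}
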