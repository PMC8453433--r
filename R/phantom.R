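#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds and validates the parameter set describing a simulated trial
#' cohort: grid geometry, visit schedule, scanner intensity distortions,
#' lesion dynamics and the injected pre-lesion abnormalities. Defaults
#' emulate a monthly-scan relapsing-MS trial arm: visits every 4 weeks to
#' week 24, ellipsoidal new lesions appearing at scheduled visits with
#' spatial density peaking periventricularly, a pre-lesion normalized-MTR
#' decrement and normalized-T2 increment present from the first simulated
#' visit, and a fraction of each effect mirrored contralaterally.
#'
#' @param grid_shape voxels per axis; the left-right axis (first) must be
#'   even so the midline falls between two voxel columns.
#' @param voxel_size_mm per-axis spacing; the default 1 x 1 x 3 mm makes
#'   10 voxels = 30 mm^3, matching the ROI size filter.
#' @param n_subjects number of MS subjects.
#' @param n_hc number of healthy-control dummy-run scans (>= one per scanner).
#' @param visit_weeks strictly increasing scan weeks; new lesions can appear
#'   at any non-baseline visit.
#' @param trial_mode visit-schedule preset; `"synergy_monthly"` scans every
#'   4 weeks to week 24 and excludes the -4-week visit from analysis,
#'   `"ascend_semiannual"` scans every 24 weeks to week 96,
#'   `"advance_annual"` scans every 48 weeks to week 144. Overridden by an
#'   explicit `visit_weeks`.
#' @param scanners named list of per-scanner affine intensity distortions,
#'   each `list(gain = c(mtr=,t1w=,t2w=), offset = c(...))`.
#' @param lesion_rate expected new lesions per subject per non-baseline visit.
#' @param lesion_radius_mm range of ellipsoid semi-axes (mm).
#' @param prelesion_delta_nmtr injected pre-lesion nMTR change (normalized
#'   units; negative = myelin-sensitive signal loss).
#' @param prelesion_delta_nt2 injected pre-lesion nT2 change (baseline NAWM
#'   SD units; positive = hyperintensity).
#' @param prelesion_delta_nt1 injected pre-lesion nT1 change (default 0: T1
#'   is isointense before lesion formation).
#' @param contralateral_fraction fraction of each pre-lesion effect injected
#'   in the mirror footprint (0..1).
#' @param inject_mode `"additive"` (default): effects are added to the
#'   local tissue intensity, so the footprint deviates from its *own*
#'   spatial norm by the configured delta and the pre-lesion-vs-contralateral
#'   contrast equals `(1 - contralateral_fraction) * delta` exactly in the
#'   noiseless case (mirror symmetry); `"calibrated"`: the footprint
#'   injection is compensated so the footprint-vs-overall-NAWM contrast on
#'   the normalized scale equals delta exactly instead (used for
#'   normalization-contract checks).
#' @param noise_sd per-channel additive Gaussian noise SD, named
#'   `c(mtr=,t1w=,t2w=)`; a scalar scales the defaults.
#' @param drift_gain_sd,drift_offset_sd per-visit affine acquisition drift of
#'   the T1w/T2w channels (the LTS stage is designed to remove it); MTR, a
#'   ratio measure, carries scanner-level distortion only.
#' @param mtr_gradient,t1_gradient,t2_gradient amplitude (raw units) of the
#'   smooth periventricular-to-juxtacortical white-matter gradient per
#'   channel (lowest MTR near the ventricles), median-centred so the WM
#'   median equals the nominal tissue mean.
#' @param lesion_field_scale_mm e-folding length of the periventricular
#'   lesion-probability field exp(-d_ventricle / scale).
#' @param nawm_decrement_nmtr diffuse MS-related NAWM abnormality: peak
#'   normalized-MTR decrement of patient white matter, spatially weighted
#'   by the same periventricular field as the lesion probability (so the
#'   abnormality atlas co-localizes with lesion risk); absent in healthy
#'   controls.
#' @param onset_ramp if `TRUE`, injected effects ramp linearly from half to
#'   full magnitude over the pre-onset visits (progressive-MS-like
#'   worsening); default `FALSE` (effects constant at all pre-onset times).
#' @param resolve_fraction fraction of lesion events that shrink to half
#'   their footprint after onset (reduces the end-of-study residual).
#' @param seed RNG seed controlling the whole cohort.
#' @return validated config, class `"phantom_config"`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 16L),
                           voxel_size_mm = c(1, 1, 3),
                           n_subjects = 8L,
                           n_hc = 4L,
                           visit_weeks = NULL,
                           trial_mode = c("synergy_monthly",
                                          "ascend_semiannual",
                                          "advance_annual"),
                           scanners = default_scanners(),
                           lesion_rate = 0.5,
                           lesion_radius_mm = c(2, 6),
                           prelesion_delta_nmtr = -0.1,
                           prelesion_delta_nt2 = 0.5,
                           prelesion_delta_nt1 = 0,
                           contralateral_fraction = 0.4,
                           inject_mode = c("additive", "calibrated"),
                           noise_sd = c(mtr = 0.4, t1w = 12, t2w = 8),
                           drift_gain_sd = 0.05,
                           drift_offset_sd = c(t1w = 10, t2w = 8),
                           mtr_gradient = 3,
                           t1_gradient = 30,
                           t2_gradient = 25,
                           lesion_field_scale_mm = 3,
                           nawm_decrement_nmtr = 0.08,
                           onset_ramp = FALSE,
                           resolve_fraction = 0,
                           seed = 1L) {
  trial_mode <- match.arg(trial_mode)
  inject_mode <- match.arg(inject_mode)
  if (is.null(visit_weeks)) {
    visit_weeks <- switch(trial_mode,
      synergy_monthly   = seq(0, 24, by = 4),
      ascend_semiannual = seq(0, 96, by = 24),
      advance_annual    = seq(0, 144, by = 48))
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("phantom_config: grid_shape must be 3 values >= 8")
  if (grid_shape[1] %% 2L != 0L)
    stop("phantom_config: grid_shape must be even along the left-right axis")
  if (any(diff(visit_weeks) <= 0))
    stop("phantom_config: visit_weeks must be strictly increasing")
  if (contralateral_fraction < 0 || contralateral_fraction > 1)
    stop("phantom_config: contralateral_fraction must be in [0, 1]")
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- noise_sd * c(mtr = 0.4, t1w = 12, t2w = 10) / 0.4 * 0.4
  stopifnot(all(c("mtr", "t1w", "t2w") %in% names(noise_sd)))
  cfg <- list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
              n_subjects = as.integer(n_subjects), n_hc = as.integer(n_hc),
              visit_weeks = visit_weeks, trial_mode = trial_mode,
              scanners = scanners, lesion_rate = lesion_rate,
              lesion_radius_mm = lesion_radius_mm,
              prelesion_delta_nmtr = prelesion_delta_nmtr,
              prelesion_delta_nt2 = prelesion_delta_nt2,
              prelesion_delta_nt1 = prelesion_delta_nt1,
              contralateral_fraction = contralateral_fraction,
              inject_mode = inject_mode,
              noise_sd = noise_sd, drift_gain_sd = drift_gain_sd,
              drift_offset_sd = drift_offset_sd,
              mtr_gradient = mtr_gradient, t1_gradient = t1_gradient,
              t2_gradient = t2_gradient,
              lesion_field_scale_mm = lesion_field_scale_mm,
              nawm_decrement_nmtr = nawm_decrement_nmtr,
              onset_ramp = onset_ramp, resolve_fraction = resolve_fraction,
              tissue_means = list(
                mtr = c(csf = 5,   gm = 30,  wm = 40,  lesion = 25),
                t1w = c(csf = 200, gm = 400, wm = 800, lesion = 600),
                t2w = c(csf = 1000, gm = 600, wm = 500, lesion = 680)),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Canonical study-scale cohort configurations
#'
#' Two fixed "stated worlds" used by the acceptance checks and reusable in
#' analyses. `longitudinal_cohort_config` emulates a monthly-scan trial arm
#' at desk scale (48 subjects, expected ~144 new lesions, i.e. roughly the
#' test data set's lesion yield): the pre-lesion contrasts of the weighted
#' mixed-model analysis are powered at every pre-onset visit.
#' `atlas_cohort_config` is a short two-visit cohort (80 patients, 16
#' healthy controls, ~320 small lesions) whose empirical lesion-probability
#' atlas resolves the periventricular field: lesions use 2-3.5 mm radii
#' because footprints much larger than the field's 3 mm e-folding length
#' smear the probability map at this grid scale.
#'
#' @param seed cohort RNG seed.
#' @return a [phantom_config()].
#' @export
longitudinal_cohort_config <- function(seed = 1L) {
  phantom_config(n_subjects = 48L, n_hc = 8L, lesion_rate = 0.5, seed = seed)
}

#' @rdname longitudinal_cohort_config
#' @export
atlas_cohort_config <- function(seed = 1L) {
  phantom_config(n_subjects = 80L, n_hc = 16L, visit_weeks = c(0, 4),
                 lesion_rate = 4, lesion_radius_mm = c(2, 3.5), seed = seed)
}

#' Default two-scanner distortion set
#'
#' Scanner A is the identity; scanner B applies a per-channel affine
#' gain/offset, exactly the distortion class the calibration and
#' least-trimmed-squares stages are designed to remove.
#' @return named list of scanner distortions.
#' @export
default_scanners <- function() {
  list(
    A = list(gain = c(mtr = 1,    t1w = 1,   t2w = 1),
             offset = c(mtr = 0,  t1w = 0,   t2w = 0)),
    B = list(gain = c(mtr = 1.08, t1w = 1.2, t2w = 0.9),
             offset = c(mtr = 1.5, t1w = 60, t2w = -30))
  )
}

#' Static anatomy shared by all phantoms of a configuration
#'
#' Builds the left-right-symmetric brain template: an ellipsoidal brain with
#' a grey-matter shell, white-matter core and two mirrored periventricular
#' CSF cavities; the distance-to-ventricle field driving both the
#' white-matter intensity gradients and the lesion-probability field; and
#' the per-channel noiseless structural intensity volumes (template units,
#' before scanner distortion). The gradient term is `amplitude * (dn -
#' median(dn))` with `dn` the ventricle distance scaled to [0, 1]; because
#' the map is monotone in `dn` and mirror voxels duplicate every distance
#' value, the white-matter median of each channel equals its nominal tissue
#' mean exactly.
#'
#' @param config a [phantom_config()].
#' @return list with `labels` (integer array), `d_vent` (mm),
#'   `lesion_field` (unnormalized spatial density over WM), `structural`
#'   (list of mtr/t1w/t2w arrays) and grid metadata.
#' @export
phantom_template <- function(config) {
  shp <- config$grid_shape; pd <- config$voxel_size_mm
  cc <- axis_coords_mm(shp, pd)
  L <- shp * pd
  X <- array(cc[[1]], shp)
  Y <- array(rep(cc[[2]], each = shp[1]), shp)
  Z <- array(rep(cc[[3]], each = shp[1] * shp[2]), shp)

  rb <- 0.46 * L
  u <- sqrt((X / rb[1])^2 + (Y / rb[2])^2 + (Z / rb[3])^2)
  brain <- u <= 1
  gm <- brain & u > 0.82

  vc <- c(0.10 * L[1], 0, 0)             # mirrored ventricle centres (+/- x)
  vr <- c(0.05 * L[1], 0.15 * L[2], 0.12 * L[3])
  vent <- (((abs(X) - vc[1]) / vr[1])^2 + (Y / vr[2])^2 + (Z / vr[3])^2) <= 1
  vent <- vent & brain & !gm
  if (!any(vent))
    stop("phantom_template: grid too small to contain the ventricle template; ",
         "increase grid_shape")

  lab <- tissue_labels()
  labels <- array(lab["background"], shp)
  labels[brain] <- lab["wm"]
  labels[gm] <- lab["gm"]
  labels[vent] <- lab["csf"]

  d_vent <- array(Inf, shp)
  wmv <- which(labels == lab["wm"])
  # distance from every brain voxel to the ventricle surface (symmetric field)
  qall <- which(brain)
  d_vent[qall] <- distance_to_mask(arrayInd(qall, shp), vent, pd)

  wm_mask <- labels == lab["wm"]
  dn <- d_vent / max(d_vent[wm_mask])
  med_dn <- stats::median(dn[wm_mask])

  structural <- list()
  for (ch in c("mtr", "t1w", "t2w")) {
    tm <- config$tissue_means[[ch]]
    vol <- array(0, shp)
    vol[labels == lab["csf"]] <- tm["csf"]
    vol[labels == lab["gm"]] <- tm["gm"]
    # MTR/T1w lowest periventricularly; T2w highest (free-water-like).
    # Median-centred monotone map: WM median = nominal tissue mean exactly.
    amp <- switch(ch, mtr = config$mtr_gradient, t1w = config$t1_gradient,
                  t2w = -config$t2_gradient)
    vol[wm_mask] <- tm["wm"] + amp * (dn[wm_mask] - med_dn)
    structural[[ch]] <- vol
  }

  lesion_field <- array(0, shp)
  lesion_field[wm_mask] <- exp(-d_vent[wm_mask] / config$lesion_field_scale_mm)

  list(labels = labels, d_vent = d_vent, lesion_field = lesion_field,
       structural = structural, shape = shp, pixdim = pd,
       coords = list(X = X, Y = Y, Z = Z))
}

# Derive a reproducible 32-bit sub-seed from the cohort seed.
derive_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 7919 + idx * 104729) %% 2147483647)
}

scanner_affine <- function(config, scanner_id, channel) {
  sc <- config$scanners[[scanner_id]]
  if (is.null(sc)) stop("unknown scanner_id: ", scanner_id)
  c(gain = unname(sc$gain[channel]), offset = unname(sc$offset[channel]))
}

#' Generate a healthy-control dummy-run scan
#'
#' A single-timepoint, lesion-free, exactly mirror-symmetric phantom (when
#' `noise_sd = 0`) on the given scanner: channel intensity = template tissue
#' value x scanner gain + offset + noise. Used as the per-scanner reference
#' for MTR calibration and as the HC cohort for atlas construction.
#'
#' @param config a [phantom_config()].
#' @param scanner_id name of a configured scanner.
#' @param seed RNG seed for the noise draw.
#' @param template optional precomputed [phantom_template()] (shared across
#'   subjects for speed).
#' @return a subject series (class `"nawm_series"`) with one timepoint.
#' @export
generate_healthy_control <- function(config, scanner_id = "A",
                                     seed = config$seed, template = NULL) {
  if (is.null(template)) template <- phantom_template(config)
  set.seed(seed)
  vols <- list()
  for (ch in c("mtr", "t1w", "t2w")) {
    af <- scanner_affine(config, scanner_id, ch)
    v <- template$structural[[ch]] * af["gain"] + af["offset"]
    ns <- config$noise_sd[[ch]]
    if (ns > 0) v <- v + array(stats::rnorm(length(v), 0, ns), dim(v))
    attr(v, "pixdim") <- template$pixdim
    vols[[ch]] <- v
  }
  tp <- list(week = 0, volumes = vols, tissue = template$labels,
             lesion_mask = array(FALSE, template$shape))
  structure(list(subject_id = paste0("hc-", scanner_id, "-", seed %% 1000L),
                 scanner_id = scanner_id, role = "hc",
                 pixdim = template$pixdim, timepoints = list(tp),
                 covariates = NULL, truth = NULL),
            class = "nawm_series")
}

# Sample one ellipsoidal lesion footprint in WM from the periventricular
# probability field; returns NULL after `max_tries` failed placements.
sample_lesion_footprint <- function(config, template, existing, max_tries = 20L) {
  shp <- template$shape; pd <- template$pixdim
  wm <- template$labels == tissue_labels()["wm"]
  w <- template$lesion_field[wm]
  wm_idx <- which(wm)
  vent <- template$labels == tissue_labels()["csf"]
  for (try in seq_len(max_tries)) {
    centre <- arrayInd(sample(wm_idx, 1, prob = w), shp)
    r <- stats::runif(3, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    cm <- (centre - (shp + 1) / 2) * pd
    E <- ((template$coords$X - cm[1]) / r[1])^2 +
         ((template$coords$Y - cm[2]) / r[2])^2 +
         ((template$coords$Z - cm[3]) / r[3])^2
    blob <- E <= 1
    if (any(blob & vent)) next                 # overlaps ventricles: retry
    foot <- blob & wm
    if (sum(foot) < 10L) next                  # too small to seed a viable ROI
    if (any(foot & reflect_across_midline(foot))) next  # straddles midline
    # keep a 1-voxel buffer from every earlier event (and its mirror) so a
    # new event can never read as an enlargement of an existing lesion
    fdil <- dilate_mask(foot, rbind(c(0L, 0L, 0L), neigh26()))
    if (any(fdil & existing)) next
    if (any(reflect_across_midline(fdil) & existing)) next
    return(foot)
  }
  NULL
}

#' Generate one MS subject's longitudinal series
#'
#' New-lesion events are sampled per non-baseline visit (Poisson with mean
#' `lesion_rate`) with spatial density proportional to the periventricular
#' lesion-probability field. Before onset, the future-lesion footprint
#' carries the configured normalized-scale abnormalities back-transformed to
#' raw intensities (with a per-event compensation so the full-footprint mean
#' contrast against overall NAWM equals the target exactly in the noiseless
#' case), and the mirror footprint carries `contralateral_fraction` of each
#' effect; at and after onset the footprint is lesion-labelled with lesional
#' intensities. The truth ledger records every injection.
#'
#' @inheritParams generate_healthy_control
#' @return a subject series (class `"nawm_series"`) with `$truth` holding
#'   the event table and injected magnitudes.
#' @export
generate_ms_subject <- function(config, scanner_id = "A", seed = config$seed,
                                template = NULL) {
  if (is.null(template)) template <- phantom_template(config)
  set.seed(seed)
  shp <- template$shape; pd <- template$pixdim
  weeks <- config$visit_weeks
  lab <- tissue_labels()

  # diffuse MS-related NAWM abnormality: periventricular nMTR decrement,
  # co-located with the lesion-probability field, patients only
  if (config$nawm_decrement_nmtr != 0) {
    tm <- config$tissue_means$mtr
    template$structural$mtr <- template$structural$mtr -
      config$nawm_decrement_nmtr * unname(tm["wm"] - tm["gm"]) *
      template$lesion_field
  }

  # --- sample lesion events ------------------------------------------------
  events <- list()
  existing <- array(FALSE, shp)
  skipped <- 0L
  for (vi in seq_along(weeks)[-1]) {
    n_new <- stats::rpois(1, config$lesion_rate)
    for (k in seq_len(n_new)) {
      foot <- sample_lesion_footprint(config, template, existing)
      if (is.null(foot)) { skipped <- skipped + 1L; next }
      existing <- existing | foot | reflect_across_midline(foot)
      resolves <- config$resolve_fraction > 0 &&
        stats::runif(1) < config$resolve_fraction
      shrunk <- NULL
      if (resolves) {
        fv <- which(foot)
        keep <- sort(sample(fv, ceiling(length(fv) / 2)))
        shrunk <- array(FALSE, shp); shrunk[keep] <- TRUE
      }
      events[[length(events) + 1L]] <-
        list(onset_visit = vi, first_seen_week = weeks[vi],
             prior_reference_week = weeks[vi - 1L],
             footprint = foot, shrunk = shrunk)
    }
  }

  # --- per-visit label maps and lesion masks -------------------------------
  labels_t <- lesions_t <- vector("list", length(weeks))
  for (vi in seq_along(weeks)) {
    lm <- array(FALSE, shp)
    for (e in events) {
      if (vi < e$onset_visit) next
      m <- if (!is.null(e$shrunk) && vi > e$onset_visit) e$shrunk else e$footprint
      lm <- lm | m
    }
    lt <- template$labels
    lt[lm] <- lab["lesion"]
    labels_t[[vi]] <- lt
    lesions_t[[vi]] <- lm
  }

  # --- noiseless intensity construction with exact-effect injection --------
  inj <- compute_injections(config, template, events, labels_t, lesions_t)

  drift <- list()
  for (ch in c("t1w", "t2w")) {
    drift[[ch]] <- cbind(gain = 1 + stats::rnorm(length(weeks), 0, config$drift_gain_sd),
                         offset = stats::rnorm(length(weeks), 0, config$drift_offset_sd[[ch]]))
  }

  tps <- vector("list", length(weeks))
  for (vi in seq_along(weeks)) {
    vols <- list()
    for (ch in c("mtr", "t1w", "t2w")) {
      v <- template$structural[[ch]]
      v[lesions_t[[vi]]] <- config$tissue_means[[ch]]["lesion"]
      for (ei in seq_along(events)) {
        e <- events[[ei]]
        ramp <- injection_ramp(config, vi, e$onset_visit)
        if (vi < e$onset_visit)
          v[e$footprint] <- v[e$footprint] + ramp * inj$delta_raw[[ch]][ei]
        mir <- reflect_across_midline(e$footprint) & !lesions_t[[vi]]
        v[mir] <- v[mir] + ramp * inj$delta_raw_contra[[ch]][ei]
      }
      af <- scanner_affine(config, scanner_id, ch)
      v <- v * af["gain"] + af["offset"]
      if (ch %in% c("t1w", "t2w"))
        v <- v * drift[[ch]][vi, "gain"] + drift[[ch]][vi, "offset"]
      ns <- config$noise_sd[[ch]]
      if (ns > 0) v <- v + array(stats::rnorm(length(v), 0, ns), shp)
      attr(v, "pixdim") <- pd
      vols[[ch]] <- v
    }
    tps[[vi]] <- list(week = weeks[vi], volumes = vols,
                      tissue = labels_t[[vi]], lesion_mask = lesions_t[[vi]])
  }

  covar <- data.frame(
    age = round(stats::rnorm(1, 40, 8), 1),
    sex = sample(c("F", "M"), 1, prob = c(0.7, 0.3)),
    treatment_group = sample(c("placebo", "active"), 1, prob = c(1, 2)),
    disease_duration = round(stats::rgamma(1, shape = 2, scale = 3), 1),
    baseline_gd_count = stats::rpois(1, 1),
    baseline_t2_volume = round(stats::rlnorm(1, log(8000), 0.6)),
    stringsAsFactors = FALSE)

  truth <- if (length(events)) data.frame(
    event = seq_along(events),
    first_seen_week = vapply(events, `[[`, numeric(1), "first_seen_week"),
    prior_reference_week = vapply(events, `[[`, numeric(1), "prior_reference_week"),
    n_voxels = vapply(events, function(e) sum(e$footprint), numeric(1)),
    delta_nmtr = config$prelesion_delta_nmtr,
    delta_nt1 = config$prelesion_delta_nt1,
    delta_nt2 = config$prelesion_delta_nt2,
    contralateral_fraction = config$contralateral_fraction,
    delta_raw_mtr = inj$delta_raw$mtr,
    delta_raw_t1w = inj$delta_raw$t1w,
    delta_raw_t2w = inj$delta_raw$t2w,
    resolves = vapply(events, function(e) !is.null(e$shrunk), logical(1))
  ) else data.frame()

  structure(list(subject_id = sprintf("sub-%04d", seed %% 10000L),
                 scanner_id = scanner_id, role = "ms", pixdim = pd,
                 timepoints = tps, covariates = covar, truth = truth,
                 truth_footprints = lapply(events, `[[`, "footprint"),
                 n_skipped_placements = skipped),
            class = "nawm_series")
}

injection_ramp <- function(config, vi, onset_visit) {
  if (!config$onset_ramp || onset_visit <= 2L) return(1)
  if (vi >= onset_visit) return(1)
  0.5 + 0.5 * (vi - 1) / (onset_visit - 1 - 1 + 1e-12)
}

# Solve the per-event raw injection magnitudes so that in the noiseless case
# the FULL-footprint mean contrast on each normalized scale equals the
# configured delta exactly. Normalized scales that depend on the injected
# volumes themselves (the T2 NAWM SD; the T1 medians) are handled by a short
# fixed-point iteration; the contamination of the overall-NAWM mean by
# contralateral injections is included in the same loop.
compute_injections <- function(config, template, events, labels_t, lesions_t) {
  chans <- c("mtr", "t1w", "t2w")
  ne <- length(events)
  zero <- stats::setNames(as.list(rep(0, 3)), chans)
  if (ne == 0)
    return(list(delta_raw = lapply(zero, rep, 0),
                delta_raw_contra = lapply(zero, rep, 0)))

  lab <- tissue_labels()
  shp <- template$shape
  nawm_all <- Reduce(`&`, lapply(labels_t, function(l) l == lab["wm"]))
  les_union <- Reduce(`|`, lesions_t)
  overall <- nawm_all & !exclusion_zone(les_union, template$pixdim, 2)
  nawm_base <- labels_t[[1]] == lab["wm"]
  gm_mask <- template$labels == lab["gm"]

  deltas <- c(mtr = config$prelesion_delta_nmtr,
              t1w = config$prelesion_delta_nt1,
              t2w = config$prelesion_delta_nt2)
  cf <- config$contralateral_fraction

  foot_idx <- lapply(events, function(e) which(e$footprint))
  mir_idx <- lapply(events, function(e) which(reflect_across_midline(e$footprint)))

  d_f <- d_c <- lapply(stats::setNames(chans, chans),
                       function(ch) rep(0, ne))
  for (it in 1:40) {
    prev <- c(unlist(d_f), unlist(d_c))
    for (ch in chans) {
      base <- template$structural[[ch]]
      v <- base
      for (ei in seq_len(ne)) {       # baseline state: all events pre-onset
        v[foot_idx[[ei]]] <- v[foot_idx[[ei]]] + d_f[[ch]][ei]
        v[mir_idx[[ei]]] <- v[mir_idx[[ei]]] + d_c[[ch]][ei]
      }
      scale <- switch(ch,
        mtr = {
          tm <- config$tissue_means$mtr
          unname(tm["wm"] - tm["gm"])     # HC calibration: template-unit gap
        },
        t1w = unname(stats::median(v[nawm_base]) - stats::median(v[gm_mask])),
        t2w = unname(stats::sd(v[nawm_base])))
      m_overall <- mean(v[overall])
      for (ei in seq_len(ne)) {
        mu_f <- mean(base[foot_idx[[ei]]])
        # additive: local deviation of delta (footprint-vs-contralateral
        # contrast exact by mirror symmetry); calibrated: compensated so the
        # footprint-vs-overall-NAWM contrast is exactly delta (a zero
        # target always means "no injection at all"). Contralateral is
        # plain additive in both modes, preserving the mirror site's
        # natural spatial profile.
        d_f[[ch]][ei] <- if (deltas[[ch]] == 0) 0
          else if (config$inject_mode == "calibrated")
            deltas[[ch]] * scale - (mu_f - m_overall)
          else deltas[[ch]] * scale
        d_c[[ch]][ei] <- cf * deltas[[ch]] * scale
      }
    }
    if (max(abs(c(unlist(d_f), unlist(d_c)) - prev)) < 1e-12) break
  }
  list(delta_raw = d_f, delta_raw_contra = d_c)
}

#' Generate a full synthetic cohort
#'
#' Deterministic under the config seed: healthy-control dummy runs (one
#' reference per scanner plus extras, round-robin), MS subjects round-robin
#' across scanners, a covariate table and a truth ledger of every injected
#' lesion event. Optionally writes the cohort to disk as NIfTI volumes
#' (`sub-<id>_wk-<week>_<channel>.nii.gz`, masks as uint8) plus TSV
#' covariate/truth tables.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional output directory for the NIfTI/TSV bundle.
#' @param overwrite refuse to write into an existing non-empty `out_dir`
#'   unless `TRUE`.
#' @return list of class `"nawm_cohort"`: `subjects`, `hcs`, `covariates`,
#'   `truth`, `config`, `template`.
#' @export
generate_cohort <- function(config, out_dir = NULL, overwrite = FALSE) {
  template <- phantom_template(config)
  scn <- names(config$scanners)

  hcs <- lapply(seq_len(max(config$n_hc, length(scn))), function(i) {
    generate_healthy_control(config, scn[(i - 1L) %% length(scn) + 1L],
                             seed = derive_seed(config$seed, i), template)
  })
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    s <- generate_ms_subject(config, scn[(i - 1L) %% length(scn) + 1L],
                             seed = derive_seed(config$seed, 1000L + i), template)
    s$subject_id <- sprintf("sub-%04d", i)
    s
  })

  covariates <- do.call(rbind, lapply(subjects, function(s)
    cbind(data.frame(subject_id = s$subject_id, scanner_id = s$scanner_id,
                     stringsAsFactors = FALSE), s$covariates)))
  truth <- do.call(rbind, lapply(subjects, function(s) {
    if (is.null(s$truth) || nrow(s$truth) == 0) return(NULL)
    cbind(data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE), s$truth)
  }))
  if (is.null(truth)) truth <- data.frame()

  cohort <- structure(list(subjects = subjects, hcs = hcs,
                           covariates = covariates, truth = truth,
                           config = config, template = template),
                      class = "nawm_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, overwrite)
  cohort
}

#' Write / read a cohort as NIfTI + TSV
#'
#' One gzipped NIfTI per channel per timepoint plus tissue/lesion masks, a
#' covariate TSV and a truth-ledger TSV. `read_cohort` restores the
#' in-memory structure (without the truth footprint masks, which are
#' simulation internals).
#'
#' @param cohort a `"nawm_cohort"`.
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("write_cohort: ", dir, " exists and is not empty; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series <- function(s, sub_dir) {
    dir.create(sub_dir, showWarnings = FALSE)
    for (tp in s$timepoints) {
      stem <- file.path(sub_dir, sprintf("%s_wk-%03d", s$subject_id, tp$week))
      for (ch in names(tp$volumes))
        write_nifti(tp$volumes[[ch]], paste0(stem, "_", ch, ".nii.gz"),
                    pixdim = s$pixdim)
      write_nifti(array(as.integer(tp$tissue), dim(tp$tissue)),
                  paste0(stem, "_tissue.nii.gz"), pixdim = s$pixdim,
                  datatype = "uint8")
      write_nifti(tp$lesion_mask, paste0(stem, "_lesionmask.nii.gz"),
                  pixdim = s$pixdim, datatype = "uint8")
    }
  }
  for (s in cohort$subjects) write_series(s, file.path(dir, s$subject_id))
  for (h in cohort$hcs) write_series(h, file.path(dir, h$subject_id))
  meta <- data.frame(
    subject_id = c(vapply(cohort$subjects, `[[`, "", "subject_id"),
                   vapply(cohort$hcs, `[[`, "", "subject_id")),
    scanner_id = c(vapply(cohort$subjects, `[[`, "", "scanner_id"),
                   vapply(cohort$hcs, `[[`, "", "scanner_id")),
    role = c(rep("ms", length(cohort$subjects)), rep("hc", length(cohort$hcs))),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "participants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$grid_shape <- as.integer(unlist(cfg$grid_shape))
  cfg$visit_weeks <- as.numeric(unlist(cfg$visit_weeks))
  for (f in c("noise_sd", "drift_offset_sd"))
    cfg[[f]] <- unlist(cfg[[f]])
  cfg$tissue_means <- lapply(cfg$tissue_means, unlist)
  cfg$scanners <- lapply(cfg$scanners, function(s) lapply(s, unlist))
  class(cfg) <- "phantom_config"
  meta <- utils::read.delim(file.path(dir, "participants.tsv"))
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"))
  tl_path <- file.path(dir, "truth_ledger.tsv")
  truth <- tryCatch(utils::read.delim(tl_path), error = function(e) data.frame())

  read_series <- function(sid, scanner, role) {
    sub_dir <- file.path(dir, sid)
    files <- list.files(sub_dir, pattern = "_mtr\\.nii\\.gz$")
    weeks <- sort(as.numeric(sub(".*_wk-(\\d+)_mtr\\.nii\\.gz", "\\1", files)))
    tps <- lapply(weeks, function(w) {
      stem <- file.path(sub_dir, sprintf("%s_wk-%03d", sid, w))
      vols <- lapply(c(mtr = "mtr", t1w = "t1w", t2w = "t2w"), function(ch)
        read_nifti(paste0(stem, "_", ch, ".nii.gz")))
      tissue <- read_nifti(paste0(stem, "_tissue.nii.gz"))
      list(week = w, volumes = vols,
           tissue = array(as.integer(tissue), dim(tissue)),
           lesion_mask = read_nifti(paste0(stem, "_lesionmask.nii.gz")) > 0)
    })
    pix <- attr(tps[[1]]$volumes$mtr, "pixdim")
    cv <- covariates[covariates$subject_id == sid, setdiff(names(covariates),
                     c("subject_id", "scanner_id")), drop = FALSE]
    structure(list(subject_id = sid, scanner_id = scanner, role = role,
                   pixdim = pix, timepoints = tps,
                   covariates = if (nrow(cv)) cv else NULL, truth = NULL),
              class = "nawm_series")
  }
  subjects <- hcs <- list()
  for (i in seq_len(nrow(meta))) {
    s <- read_series(meta$subject_id[i], meta$scanner_id[i], meta$role[i])
    if (meta$role[i] == "ms") subjects[[length(subjects) + 1L]] <- s
    else hcs[[length(hcs) + 1L]] <- s
  }
  structure(list(subjects = subjects, hcs = hcs, covariates = covariates,
                 truth = truth, config = cfg,
                 template = phantom_template(cfg)),
            class = "nawm_cohort")
}
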