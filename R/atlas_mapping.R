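#' Voxel-wise mean normalized-MTR atlas over a cohort
#'
#' Per-voxel mean of normalized MTR across subjects whose NAWM mask
#' includes the voxel, with the contributing-subject count recorded as
#' coverage. Voxels covered by fewer than `min_coverage` (fraction of the
#' cohort) are flagged missing (`NA`), not zero. All volumes must share the
#' template grid (synthetic mode uses identity registration).
#'
#' @param nmtr_list list of normalized MTR volumes (one per subject).
#' @param mask_list list of logical NAWM masks, same order and grid.
#' @param cohort_label `"HC"` or `"PwMS"` (metadata only).
#' @param min_coverage minimum fraction of subjects covering a voxel
#'   (default 0.25).
#' @return object of class `"mean_atlas"`: `mean` (NA where under-covered),
#'   `coverage` (integer array), `n_subjects`, `cohort_label`,
#'   `min_coverage`.
#' @export
build_mean_atlas <- function(nmtr_list, mask_list, cohort_label = "PwMS",
                             min_coverage = 0.25) {
  n <- length(nmtr_list)
  stopifnot(n >= 1, length(mask_list) == n)
  d <- dim(nmtr_list[[1]])
  acc <- array(0, d); cov <- array(0L, d)
  for (i in seq_len(n)) {
    if (!identical(dim(nmtr_list[[i]]), d) || !identical(dim(mask_list[[i]]), d))
      stop("build_mean_atlas: grid mismatch at subject ", i)
    m <- mask_list[[i]]
    acc[m] <- acc[m] + nmtr_list[[i]][m]
    cov <- cov + m
  }
  mean_vol <- array(NA_real_, d)
  ok <- cov >= max(1L, ceiling(min_coverage * n))
  mean_vol[ok] <- acc[ok] / cov[ok]
  structure(list(mean = mean_vol, coverage = cov, n_subjects = n,
                 cohort_label = cohort_label, min_coverage = min_coverage),
            class = "mean_atlas")
}

#' Voxel-wise difference of two mean atlases (HC minus PwMS)
#'
#' A positive value marks tissue where the patient cohort's normalized MTR
#' falls below the healthy-control reference, i.e. NAWM abnormality.
#' Voxels under-covered in either atlas are missing.
#'
#' @param hc_atlas,pwms_atlas `"mean_atlas"` objects on the same grid.
#' @return numeric array (HC - PwMS, NA where either input is missing).
#' @export
difference_atlas <- function(hc_atlas, pwms_atlas) {
  if (!identical(dim(hc_atlas$mean), dim(pwms_atlas$mean)))
    stop("difference_atlas: grid mismatch")
  hc_atlas$mean - pwms_atlas$mean
}

#' T2-lesion probability atlas
#'
#' Voxel-wise probability of T2 lesion occurrence: the sum of the binary
#' per-subject lesion masks divided by the number of subjects, so
#' `p * n_subjects` is integer-valued by construction.
#'
#' @param lesion_masks list of binary (logical or 0/1) masks on a shared
#'   grid, one per subject.
#' @return object of class `"probability_atlas"`: `p`, `n_subjects`.
#' @export
build_probability_atlas <- function(lesion_masks) {
  n <- length(lesion_masks)
  stopifnot(n >= 1)
  d <- dim(lesion_masks[[1]])
  acc <- array(0, d)
  for (m in lesion_masks) {
    if (!identical(dim(m), d)) stop("build_probability_atlas: grid mismatch")
    v <- as.vector(m)
    if (!all(v %in% c(0, 1, FALSE, TRUE)))
      stop("build_probability_atlas: non-binary lesion mask")
    acc <- acc + array(as.numeric(v), d)
  }
  structure(list(p = acc / n, n_subjects = n), class = "probability_atlas")
}

#' Discretize a lesion-probability atlas into categorical bins
#'
#' Bins of increasing probability over a support mask. The lowest bin is
#' anchored at p < `first_bin_max` (default 0.0025: tissue where the
#' lesion probability is minimal); the remaining bins are by default
#' equal-width in log10 p over the observed range, or equal-count
#' (`mode = "quantile"`: rank-split, so bin sizes differ by at most 1).
#' Explicit `edges` override both (right-open bins, last bin closed).
#'
#' @param atlas `"probability_atlas"`.
#' @param n_bins total number of bins (>= 2; Fig-style analyses use 4 or
#'   12).
#' @param support logical mask of voxels to bin (default: all voxels).
#' @param mode `"logwidth"` (default) or `"quantile"`.
#' @param first_bin_max upper edge of the anchored lowest bin.
#' @param edges optional full ascending edge vector (length `n_bins + 1`).
#' @return object of class `"probability_bins"`: `bin` (integer array, NA
#'   outside support), `edges` (NULL for quantile mode), `n_bins`.
#' @export
discretize_probability <- function(atlas, n_bins = 12L, support = NULL,
                                   mode = c("logwidth", "quantile"),
                                   first_bin_max = 0.0025, edges = NULL) {
  mode <- match.arg(mode)
  p <- atlas$p
  if (is.null(support)) support <- array(TRUE, dim(p))
  if (n_bins < 2) stop("discretize_probability: n_bins must be >= 2")
  bin <- array(NA_integer_, dim(p))
  pv <- p[support]

  if (!is.null(edges)) {
    if (any(diff(edges) <= 0)) stop("discretize_probability: non-monotone edges")
    b <- findInterval(pv, edges, rightmost.closed = TRUE, all.inside = FALSE)
    b[b < 1L | b > length(edges) - 1L] <- NA_integer_
    bin[support] <- b
  } else if (mode == "logwidth") {
    hi <- pv[pv >= first_bin_max]
    if (length(hi) == 0) {
      bin[support] <- 1L
      edges <- c(0, first_bin_max)
    } else {
      lo <- log10(first_bin_max); top <- log10(max(hi)) + 1e-12
      inner <- 10^seq(lo, top, length.out = n_bins)
      edges <- c(0, inner)
      b <- findInterval(pv, edges, rightmost.closed = TRUE)
      bin[support] <- pmin(b, n_bins)
    }
  } else {
    ord <- order(pv)                    # ties broken by voxel index: deterministic
    sizes <- diff(round(seq(0, length(pv), length.out = n_bins + 1)))
    b <- integer(length(pv))
    b[ord] <- rep(seq_len(n_bins), times = sizes)
    bin[support] <- b
    edges <- NULL
  }
  structure(list(bin = bin, edges = edges, n_bins = as.integer(n_bins)),
            class = "probability_bins")
}

#' Per-subject mean normalized MTR within each probability bin
#'
#' Aggregation used by [trend_test()]: one value per subject per bin (mean
#' nMTR over that subject's NAWM voxels falling in the bin), avoiding
#' voxel-level pseudo-replication.
#'
#' @param nmtr_list,mask_list per-subject volumes and NAWM masks.
#' @param bins `"probability_bins"` on the same grid.
#' @param population label attached to all rows (e.g. `"HC"`).
#' @return data.frame: subject, population, bin, value.
#' @export
bin_subject_means <- function(nmtr_list, mask_list, bins, population) {
  rows <- list()
  for (i in seq_along(nmtr_list)) {
    m <- mask_list[[i]]
    b <- bins$bin
    for (k in seq_len(bins$n_bins)) {
      sel <- m & !is.na(b) & b == k
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, population = population, bin = k,
        value = mean(nmtr_list[[i]][sel]), n_voxels = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Likelihood-ratio trend test of bin-by-population interaction
#'
#' Compares, by maximum likelihood, a model of per-subject bin means that
#' includes a population-by-bin interaction against one that does not; the
#' bin main effect is always discrete (a factor), so spatial nonlinearity
#' of normalized MTR across bins is absorbed before the interaction is
#' tested. With `bin_linear = TRUE` (the NAWM-abnormality trend analysis)
#' the interaction enters as a continuous linear term in the bin index and
#' the LRT has 1 degree of freedom; with `bin_linear = FALSE` the
#' interaction is discrete and the LRT has `n_bins - 1` degrees of
#' freedom.
#'
#' @param df data.frame from [bin_subject_means()] (or equivalent) with
#'   columns population, bin, value.
#' @param bin_linear model the bin effect as continuous linear (default).
#' @return list: `statistic` (2 delta log-lik), `df`, `p.value`,
#'   `fit_full`, `fit_reduced`.
#' @export
trend_test <- function(df, bin_linear = TRUE) {
  if (length(unique(df$population)) < 2)
    stop("trend_test: both populations must be present")
  if (length(unique(df$bin)) < 2) stop("trend_test: need >= 2 bins")
  tab <- table(df$population, df$bin)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("trend_test: empty population x bin cell(s): ",
         paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  df$population <- factor(df$population)
  df$bin_f <- factor(df$bin)
  df$bin_num <- as.numeric(df$bin)
  # per-row precision weights: subject-bin means over more voxels are less
  # noisy (equal weights if no n_voxels column is supplied)
  wts <- if ("n_voxels" %in% names(df)) df$n_voxels else rep(1, nrow(df))
  red <- stats::lm(value ~ population + bin_f, data = df, weights = wts)
  full <- if (bin_linear)
    stats::lm(value ~ population + bin_f + population:bin_num, data = df,
              weights = wts)
  else
    stats::lm(value ~ population + bin_f + population:bin_f, data = df,
              weights = wts)
  stat <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(red)))
  dfree <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
  list(statistic = stat, df = dfree,
       p.value = stats::pchisq(stat, dfree, lower.tail = FALSE),
       fit_full = full, fit_reduced = red)
}

#' ROI frequency distribution across probability bins
#'
#' For each ROI class (pre-lesion, contralateral, overall NAWM), the
#' fraction of its voxels falling in each probability bin; fractions sum
#' to 1 per class.
#'
#' @param roi_masks named list of logical masks.
#' @param bins `"probability_bins"` on the same grid.
#' @return data.frame: class, bin, fraction.
#' @export
roi_bin_distribution <- function(roi_masks, bins) {
  out <- list()
  for (cls in names(roi_masks)) {
    m <- roi_masks[[cls]]
    b <- bins$bin[m]
    b <- b[!is.na(b)]
    n <- length(b)
    frac <- tabulate(b, nbins = bins$n_bins) / max(n, 1L)
    out[[length(out) + 1L]] <- data.frame(class = cls,
                                          bin = seq_len(bins$n_bins),
                                          fraction = frac)
  }
  do.call(rbind, out)
}
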