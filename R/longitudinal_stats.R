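#' Build the per-lesion longitudinal contrast table
#'
#' For every accepted ROI pair and every analysed visit strictly before
#' lesion onset, computes the mean normalized intensity over the
#' pre-lesion, contralateral and overall-NAWM masks and emits the three
#' pairwise differences (pre-lesion vs overall, pre-lesion vs
#' contralateral, contralateral vs overall) per channel, in long format.
#' Each row carries the patient weight 1 / (number of accepted lesions of
#' that patient), so patients contribute equally regardless of lesion
#' count. For monthly schedules the final pre-onset interval visit (the
#' prior reference scan, -4 weeks) is excluded from analysis; it still
#' participates in the ROI validity filters.
#'
#' @param series a normalized subject series (see [normalize_series()]).
#' @param pairs accepted `"roi_pair"`s for that subject (with onset weeks).
#' @param exclude_last_interval drop the prior-reference visit from the
#'   analysis rows (default `TRUE`, the monthly-schedule convention).
#' @param channels normalized channels to tabulate.
#' @return data.frame with columns subject_id, lesion_id,
#'   weeks_before_onset, visit_week, contrast, channel, value, weight,
#'   plus the subject covariates.
#' @export
build_sample_table <- function(series, pairs,
                               exclude_last_interval = TRUE,
                               channels = c("nmtr", "nt1", "nt2")) {
  if (length(pairs) == 0) return(empty_sample_table())
  overall <- compute_overall_nawm(series)
  weeks <- vapply(series$timepoints, `[[`, numeric(1), "week")
  w <- 1 / length(pairs)
  rows <- list()
  for (pair in pairs) {
    pre_idx <- which(weeks < pair$first_seen_week)
    if (exclude_last_interval)
      pre_idx <- pre_idx[weeks[pre_idx] != pair$prior_reference_week]
    if (length(pre_idx) == 0) next
    for (vi in pre_idx) {
      nz <- series$timepoints[[vi]]$normalized
      if (is.null(nz)) stop("build_sample_table: series not normalized")
      for (ch in channels) {
        v <- nz[[ch]]
        m_pre <- mean(v[pair$prelesion_mask])
        m_con <- mean(v[pair$contralateral_mask])
        m_all <- mean(v[overall])
        vals <- c(pre_vs_overall = m_pre - m_all,
                  pre_vs_contra = m_pre - m_con,
                  contra_vs_overall = m_con - m_all)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = series$subject_id, lesion_id = pair$lesion_id,
          weeks_before_onset = weeks[vi] - pair$first_seen_week,
          visit_week = weeks[vi],
          contrast = names(vals), channel = ch, value = unname(vals),
          weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_sample_table())
  out <- do.call(rbind, rows)
  if (!is.null(series$covariates))
    out <- cbind(out, series$covariates[rep(1L, nrow(out)), , drop = FALSE],
                 row.names = NULL)
  out
}

empty_sample_table <- function() {
  data.frame(subject_id = character(0), lesion_id = character(0),
             weeks_before_onset = numeric(0), visit_week = numeric(0),
             contrast = character(0), channel = character(0),
             value = numeric(0), weight = numeric(0))
}

#' Combine per-subject sample tables for a cohort
#' @param tables list of data.frames from [build_sample_table()].
#' @return single long-format data.frame.
#' @export
bind_sample_tables <- function(tables) {
  tables <- Filter(function(t) nrow(t) > 0, tables)
  if (length(tables) == 0) return(empty_sample_table())
  do.call(rbind, tables)
}

# ---------------------------------------------------------------------------
# Weighted nested linear mixed-effects model with AR(1) residual correlation
# ---------------------------------------------------------------------------

# Per-subject marginal correlation-scale covariance Sigma_i / sigma^2:
#   gamma_p * J  +  blockdiag_over_lesions( gamma_l * J + D^1/2 R(rho) D^1/2 )
# with D = diag(1/w) and R the AR(1) matrix over visit rank (or week)
# distance within lesion. `b` carries precomputed per-lesion index sets,
# |dist| difference matrices and weight factors (see fit_weighted_lmm).
build_subject_sigma <- function(b, gamma_p, gamma_l, rho) {
  n <- length(b$rows)
  S <- matrix(gamma_p, n, n)
  for (k in seq_along(b$les_idx)) {
    ii <- b$les_idx[[k]]
    S[ii, ii] <- S[ii, ii] + gamma_l + b$les_wfac[[k]] * rho^b$les_D[[k]]
  }
  S
}

# Attach per-lesion precomputations to a subject block.
prep_block <- function(rows, lesion, dist, w) {
  les <- unique(lesion)
  les_idx <- lapply(les, function(lj) which(lesion == lj))
  list(rows = rows, lesion = lesion, dist = dist, w = w,
       les_idx = les_idx,
       les_D = lapply(les_idx, function(ii) abs(outer(dist[ii], dist[ii], `-`))),
       les_wfac = lapply(les_idx, function(ii) {
         sw <- 1 / sqrt(w[ii]); sw %o% sw
       }))
}

# -2 * profiled REML (or ML) criterion and GLS pieces at given theta.
lmm_criterion <- function(theta, blocks, X, y, reml = TRUE) {
  gamma_p <- exp(theta[1]); gamma_l <- exp(theta[2]); rho <- tanh(theta[3])
  n <- length(y); p <- ncol(X)
  logdet <- 0
  Xw <- matrix(0, n, p); yw <- numeric(n)
  for (b in blocks) {
    S <- build_subject_sigma(b, gamma_p, gamma_l, rho)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Xw[b$rows, ] <- backsolve(ch, X[b$rows, , drop = FALSE], transpose = TRUE)
    yw[b$rows] <- backsolve(ch, y[b$rows], transpose = TRUE)
  }
  XtX <- crossprod(Xw)
  beta <- tryCatch(solve(XtX, crossprod(Xw, yw)), error = function(e) NULL)
  if (is.null(beta)) return(list(value = 1e10))
  rss <- sum((yw - Xw %*% beta)^2)
  if (reml) {
    df <- n - p
    sigma2 <- rss / df
    val <- df * log(2 * pi * sigma2) + logdet +
      determinant(XtX, logarithm = TRUE)$modulus[1] + df
  } else {
    sigma2 <- rss / n
    val <- n * log(2 * pi * sigma2) + logdet + n
  }
  list(value = val, beta = drop(beta), sigma2 = sigma2, XtX = XtX,
       gamma_p = gamma_p, gamma_l = gamma_l, rho = rho)
}

#' Restricted/marginal log-likelihood of the weighted nested AR(1) model
#'
#' Evaluates the (restricted) log-likelihood of the model fitted by
#' [fit_weighted_lmm()] at *given* variance components, using the same
#' per-subject block computations as the fitter. Convention: the REML
#' log-likelihood is
#' \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + r'V^{-1}r]}
#' with \eqn{V} the full marginal covariance and \eqn{r} the GLS residual.
#' Useful as a target for independent (dense multivariate-normal) oracles.
#'
#' @param fit a `"nawm_lmm"` object.
#' @param sigma2,sigma2_patient,sigma2_lesion,rho variance components; by
#'   default the fitted values.
#' @param reml evaluate the REML (default) or ML log-likelihood.
#' @return log-likelihood (scalar).
#' @export
lmm_loglik <- function(fit, sigma2 = fit$sigma2,
                       sigma2_patient = fit$sigma2_patient,
                       sigma2_lesion = fit$sigma2_lesion, rho = fit$rho,
                       reml = TRUE) {
  gamma_p <- sigma2_patient / sigma2
  gamma_l <- sigma2_lesion / sigma2
  blocks <- fit$blocks; X <- fit$X; y <- fit$y
  n <- length(y); p <- ncol(X)
  logdet <- n * log(sigma2)
  Xw <- matrix(0, n, p); yw <- numeric(n)
  for (b in blocks) {
    S <- build_subject_sigma(b, gamma_p, gamma_l, rho)
    ch <- chol(S)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Xw[b$rows, ] <- backsolve(ch, X[b$rows, , drop = FALSE], transpose = TRUE)
    yw[b$rows] <- backsolve(ch, y[b$rows], transpose = TRUE)
  }
  Xw <- Xw / sqrt(sigma2); yw <- yw / sqrt(sigma2)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  quad <- sum((yw - Xw %*% beta)^2)
  if (reml) {
    -0.5 * ((n - p) * log(2 * pi) + logdet +
              determinant(XtX, logarithm = TRUE)$modulus[1] + quad)
  } else {
    -0.5 * (n * log(2 * pi) + logdet + quad)
  }
}

#' Fit the patient-weighted nested mixed-effects model with AR(1) errors
#'
#' Model: `y = X beta + b_patient + b_lesion + eps`, with
#' `b_patient ~ N(0, sigma2_patient)`, `b_lesion ~ N(0, sigma2_lesion)`
#' nested within patient, and residuals with `Var(eps) = sigma2 / w` and
#' AR(1) correlation `rho^|t - t'|` over ordered visits within lesion
#' (visit *rank* distance by default; calendar-week distance via
#' `ar1_on = "weeks"`). Estimated by profiled REML (beta and sigma2
#' profiled out; the two variance ratios and rho optimized by L-BFGS-B on
#' unconstrained transforms, best of several deterministic starts).
#'
#' @param formula fixed-effects formula (response on the left), e.g.
#'   `value ~ factor(weeks_before_onset)`.
#' @param data long-format data.frame (one row per lesion x visit).
#' @param subject,lesion,time,weight column names for grouping, time
#'   ordering and patient weights.
#' @param ar1_on `"rank"` (default) or `"weeks"`: distance metric in the
#'   AR(1) exponent.
#' @param reml REML (default) or ML estimation.
#' @param theta_starts optional list of starting values
#'   `(log gamma_p, log gamma_l, atanh rho)` for the variance-component
#'   search (default: four spread-out starts).
#' @return object of class `"nawm_lmm"`: `beta`, `vcov_beta`, `sigma2`,
#'   `sigma2_patient`, `sigma2_lesion`, `rho`, `logLik`, `df_resid`,
#'   fitting metadata and the design pieces needed by [ls_means()].
#' @export
fit_weighted_lmm <- function(formula, data, subject = "subject_id",
                             lesion = "lesion_id", time = "visit_week",
                             weight = "weight",
                             ar1_on = c("rank", "weeks"), reml = TRUE,
                             theta_starts = NULL) {
  ar1_on <- match.arg(ar1_on)
  for (col in c(subject, lesion, time, weight))
    if (!col %in% names(data)) stop("fit_weighted_lmm: missing column ", col)
  if (length(unique(data[[subject]])) < 2)
    stop("fit_weighted_lmm: need at least 2 subjects")

  ord <- order(data[[subject]], data[[lesion]], data[[time]])
  data <- data[ord, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fit_weighted_lmm: singular fixed-effects design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  # within-lesion time distance for the AR(1) exponent
  key <- interaction(data[[subject]], data[[lesion]], drop = TRUE)
  dist <- numeric(nrow(data))
  for (k in levels(key)) {
    ii <- which(key == k)
    dist[ii] <- if (ar1_on == "rank") rank(data[[time]][ii])
                else data[[time]][ii]
  }
  blocks <- lapply(unique(data[[subject]]), function(s) {
    rows <- which(data[[subject]] == s)
    prep_block(rows, as.character(data[[lesion]][rows]), dist[rows],
               data[[weight]][rows])
  })

  if (is.null(theta_starts))
    theta_starts <- list(c(-2, -2, 0), c(0, 0, 0),
                         c(log(0.5), log(0.5), atanh(0.5)), c(-6, -6, 0))
  starts <- theta_starts
  lim <- c(-20, 20); rlim <- atanh(0.995)
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, function(th) lmm_criterion(th, blocks, X, y, reml)$value,
                        method = "L-BFGS-B",
                        lower = c(lim[1], lim[1], -rlim),
                        upper = c(lim[2], lim[2], rlim),
                        control = list(maxit = 200))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("fit_weighted_lmm: optimization failed to find a valid fit; trace: ",
         paste(signif(best$par, 4), collapse = ", "))

  fin <- lmm_criterion(best$par, blocks, X, y, reml)
  vcov_beta <- fin$sigma2 * solve(fin$XtX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(fin$beta, colnames(X))

  structure(list(beta = beta, vcov_beta = vcov_beta,
                 sigma2 = fin$sigma2,
                 sigma2_patient = fin$sigma2 * fin$gamma_p,
                 sigma2_lesion = fin$sigma2 * fin$gamma_l,
                 rho = fin$rho,
                 logLik = -0.5 * fin$value,
                 n = length(y), p = ncol(X), df_resid = length(y) - ncol(X),
                 reml = reml, ar1_on = ar1_on, formula = formula,
                 converged = best$convergence == 0,
                 X = X, y = y, blocks = blocks, data = data,
                 weight_col = weight),
            class = "nawm_lmm")
}

#' @export
print.nawm_lmm <- function(x, ...) {
  cat("Weighted nested LMM with AR(1) residuals (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  n = %d, fixed effects = %d, logLik = %.4f\n",
              x$n, x$p, x$logLik))
  cat(sprintf("  sigma2 = %.5g  sigma2_patient = %.5g  sigma2_lesion = %.5g  rho = %.4f\n",
              x$sigma2, x$sigma2_patient, x$sigma2_lesion, x$rho))
  cat("Fixed effects:\n")
  print(cbind(estimate = x$beta, se = sqrt(diag(x$vcov_beta))))
  invisible(x)
}

#' Multiplicity adjustment across levels of a categorical term
#'
#' Thin, validating wrapper around the standard step-down adjustments:
#' adjusted p-values are monotone, never below the raw values and capped at
#' 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param method `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return adjusted p-values.
#' @export
adjust_multiplicity <- function(pvalues, method = c("holm", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("adjust_multiplicity: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Least-squares means of a categorical term
#'
#' Estimated marginal mean of the response at each level of `term`:
#' continuous covariates fixed at their weighted sample means (weights =
#' the patient weights used in the fit), other categorical covariates
#' averaged with equal weight over their levels, interactions formed from
#' the averaged columns. Each LS mean is tested against 0 with a t
#' statistic on the residual degrees of freedom and adjusted for
#' multiplicity across levels.
#'
#' @param fit a `"nawm_lmm"`.
#' @param term name of the factor term (default: the first factor in the
#'   model frame).
#' @param adjust multiplicity method (see [adjust_multiplicity()]).
#' @return data.frame: level, estimate, se, df, t, p, p_adj.
#' @export
ls_means <- function(fit, term = NULL, adjust = "holm") {
  data <- fit$data
  mf <- stats::model.frame(fit$formula, data)
  cls <- attr(attr(mf, "terms"), "dataClasses")[-1]
  facs <- names(cls)[cls %in% c("factor", "character", "ordered")]
  if (is.null(term)) {
    if (length(facs) == 0) term <- NA_character_ else term <- facs[1]
  } else if (!(term %in% names(mf))) {
    stop("ls_means: term '", term, "' is not in the model")
  }

  w <- data[[fit$weight_col]]
  grid_vars <- setdiff(names(mf)[-1], term)
  base <- list()
  for (v in grid_vars) {
    col <- mf[[v]]
    base[[v]] <- if (is.numeric(col)) stats::weighted.mean(col, w)
                 else factor(levels(factor(col)), levels = levels(factor(col)))
  }
  ref_grid <- if (length(base)) expand.grid(base, stringsAsFactors = FALSE)
              else data.frame(row.names = 1)

  if (is.na(term)) {
    levs <- "(overall)"
    grids <- list(ref_grid)
  } else {
    col <- mf[[term]]
    levs <- levels(factor(col))
    grids <- lapply(levs, function(l) {
      g <- ref_grid
      g[[term]] <- factor(l, levels = levs)
      g
    })
  }

  Terms <- stats::delete.response(stats::terms(fit$formula))
  xlev <- lapply(mf[facs], function(c) levels(factor(c)))
  L <- t(vapply(grids, function(g) {
    mm <- stats::model.matrix(Terms, stats::model.frame(Terms, g, xlev = xlev))
    colMeans(mm)                         # equal-weight average over factor cells
  }, numeric(length(fit$beta))))

  est <- drop(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$vcov_beta) * L))
  tt <- est / se
  p <- 2 * stats::pt(-abs(tt), fit$df_resid)
  data.frame(level = levs, estimate = est, se = se, df = fit$df_resid,
             t = tt, p = p, p_adj = adjust_multiplicity(p, adjust),
             stringsAsFactors = FALSE)
}
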