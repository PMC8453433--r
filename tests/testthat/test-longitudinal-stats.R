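# --- sample table ----------------------------------------------------------

constant_series <- function(value = 0.7, d = c(16, 12, 6), nvis = 3) {
  lab <- tissue_labels()
  tissues <- replicate(nvis, array(lab[["wm"]], d), simplify = FALSE)
  normalized <- replicate(nvis, list(
    nmtr = array(value, d), nt1 = array(value, d), nt2 = array(value, d)),
    simplify = FALSE)
  make_series(tissues, lesions = replicate(nvis, array(FALSE, d), simplify = FALSE),
              normalized = normalized)
}

fake_pair <- function(d = c(16, 12, 6), first_seen_week = 8, id = "L1") {
  pre <- array(FALSE, d); pre[3:5, 4:7, 2:3] <- TRUE
  structure(list(lesion_id = id, prelesion_mask = pre,
                 contralateral_mask = reflect_across_midline(pre),
                 n_voxels = sum(pre), qc_status = "accepted",
                 first_seen_week = first_seen_week,
                 prior_reference_week = first_seen_week - 4),
            class = "roi_pair")
}

test_that("constant images give zero contrasts and correct row structure", {
  s <- constant_series()
  tab <- build_sample_table(s, list(fake_pair()), exclude_last_interval = FALSE)
  expect_true(all(abs(tab$value) < 1e-12))
  # 2 pre-onset visits x 3 contrasts x 3 channels
  expect_equal(nrow(tab), 2 * 3 * 3)
  expect_setequal(unique(tab$contrast),
                  c("pre_vs_overall", "pre_vs_contra", "contra_vs_overall"))
  expect_true(all(tab$weight == 1))
})

test_that("the prior-reference visit is excluded in monthly mode", {
  s <- constant_series(nvis = 3)
  tab <- build_sample_table(s, list(fake_pair(first_seen_week = 8)),
                            exclude_last_interval = TRUE)
  expect_setequal(unique(tab$weeks_before_onset), -8)   # the -4 visit dropped
})

test_that("per-lesion weights are the inverse of the subject's lesion count", {
  s <- constant_series()
  pairs <- lapply(1:4, function(k) fake_pair(id = paste0("L", k)))
  tab <- build_sample_table(s, pairs, exclude_last_interval = FALSE)
  expect_true(all(tab$weight == 0.25))
})

test_that("a flat-gradient injected decrement propagates exactly to the contrasts", {
  cfg <- tiny_config(noise_sd = quiet_noise, mtr_gradient = 0, t1_gradient = 0,
                     nawm_decrement_nmtr = 0,
                     prelesion_delta_nmtr = -0.2, prelesion_delta_nt1 = 0,
                     contralateral_fraction = 0, lesion_rate = 1, seed = 3)
  tpl <- phantom_template(cfg)
  ms <- generate_ms_subject(cfg, "A", seed = 15, template = tpl)
  expect_gt(nrow(ms$truth), 0)
  hc <- generate_healthy_control(cfg, "A", seed = 16, template = tpl)
  ms <- normalize_series(ms, calibrate_mtr(hc))
  events <- find_lesion_events(ms)
  pairs <- derive_roi_pairs(ms, events)$pairs
  expect_gt(length(pairs), 0)
  tab <- build_sample_table(ms, pairs, exclude_last_interval = FALSE)
  nm <- tab[tab$channel == "nmtr", ]
  ok_pair <- nm$lesion_id %in% vapply(pairs, `[[`, "", "lesion_id")
  # ROIs that survive untrimmed recover the injections exactly
  full <- vapply(pairs, function(p) {
    e <- events[[which(vapply(events, `[[`, "", "lesion_id") == p$lesion_id)]]
    identical(p$prelesion_mask, e$residual_mask)
  }, logical(1))
  for (p in pairs[full]) {
    sub <- nm[nm$lesion_id == p$lesion_id, ]
    expect_equal(sub$value[sub$contrast == "pre_vs_overall"],
                 rep(-0.2, sum(sub$contrast == "pre_vs_overall")),
                 tolerance = 1e-9)
    expect_equal(sub$value[sub$contrast == "pre_vs_contra"],
                 rep(-0.2, sum(sub$contrast == "pre_vs_contra")),
                 tolerance = 1e-9)
    expect_equal(sub$value[sub$contrast == "contra_vs_overall"],
                 rep(0, sum(sub$contrast == "contra_vs_overall")),
                 tolerance = 1e-9)
  }
})

# --- mixed model -----------------------------------------------------------

test_that("balanced data reduce the weighted LMM to weighted least squares", {
  d <- simdata_lmm(2, nsub = 12, nles = 2, nvis = 3, s2p = 0, s2l = 0, rho = 0)
  d$time <- factor(d$visit_week)
  fit <- fit_weighted_lmm(value ~ time, d)
  wls <- stats::lm(value ~ time, data = d, weights = d$weight)
  expect_equal(unname(fit$beta), unname(coef(wls)), tolerance = 1e-6)
})

test_that("blockwise REML log-likelihood equals the dense MVN oracle", {
  d <- simdata_lmm(4, nsub = 2, nles = 2, nvis = 3)
  fit <- fit_weighted_lmm(value ~ 1, d)
  # at the fitted parameters
  ll_dense <- dense_reml_loglik(value ~ 1, d, fit$sigma2, fit$sigma2_patient,
                                fit$sigma2_lesion, fit$rho)
  expect_lt(abs(lmm_loglik(fit) - ll_dense), 1e-8)
  expect_lt(abs(fit$logLik - ll_dense), 1e-8)
  # and at arbitrary (non-fitted) variance components
  ll2 <- dense_reml_loglik(value ~ 1, d, 0.7, 0.2, 0.4, -0.3)
  expect_lt(abs(lmm_loglik(fit, sigma2 = 0.7, sigma2_patient = 0.2,
                           sigma2_lesion = 0.4, rho = -0.3) - ll2), 1e-8)
})

test_that("estimates agree with the reference nlme implementation", {
  d <- simdata_lmm(5, nsub = 12, nles = 2, nvis = 4)
  fit <- fit_weighted_lmm(value ~ 1, d)
  d$vw <- 1 / d$weight
  ref <- nlme::lme(value ~ 1, random = ~ 1 | subject_id / lesion_id, data = d,
                   correlation = nlme::corAR1(form = ~ visit_week / 4 |
                                                subject_id / lesion_id),
                   weights = nlme::varFixed(~vw), method = "REML")
  vc <- nlme::VarCorr(ref)
  expect_equal(unname(fit$beta[1]), unname(nlme::fixef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$sigma2_patient, as.numeric(vc[2, 1]), tolerance = 1e-3)
  expect_equal(fit$sigma2_lesion, as.numeric(vc[4, 1]), tolerance = 1e-3)
  expect_equal(fit$rho,
               as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
})

test_that("weight rescaling leaves fixed effects and LS means unchanged", {
  d <- simdata_lmm(6, nsub = 10, nles = 2, nvis = 3)
  d$time <- factor(d$visit_week)
  f1 <- fit_weighted_lmm(value ~ time, d)
  d2 <- d; d2$weight <- d2$weight * 7
  f2 <- fit_weighted_lmm(value ~ time, d2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-5)
  expect_equal(ls_means(f1, "time")$estimate, ls_means(f2, "time")$estimate,
               tolerance = 1e-5)
})

test_that("lesion duplication with halved weights preserves the weighted grand mean", {
  d <- simdata_lmm(8, nsub = 6, nles = 2, nvis = 3)
  gm1 <- weighted.mean(d$value, d$weight)
  s1 <- d$subject_id == "s001"
  dup <- d[s1, ]
  dup$lesion_id <- paste0(dup$lesion_id, "_dup")
  d2 <- rbind(d, dup)
  d2$weight[d2$subject_id == "s001"] <- d$weight[s1][1] / 2
  gm2 <- weighted.mean(d2$value, d2$weight)
  expect_equal(gm1, gm2, tolerance = 1e-12)
})

test_that("the fitted residual correlation decays monotonically with visit gap", {
  d <- simdata_lmm(10, nsub = 15, nles = 2, nvis = 5, rho = 0.6)
  fit <- fit_weighted_lmm(value ~ 1, d)
  gaps <- 0:4
  corr <- fit$rho^gaps
  expect_true(all(diff(abs(corr)) < 0))
  expect_lt(abs(fit$rho), 1)
  expect_gte(fit$sigma2_patient, 0)
  expect_gte(fit$sigma2_lesion, 0)
})

test_that("singular designs and bad inputs raise informative errors", {
  d <- simdata_lmm(12, nsub = 4, nles = 2, nvis = 3)
  d$dup <- d$visit_week * 2
  expect_error(fit_weighted_lmm(value ~ visit_week + dup, d), "collinear")
  expect_error(fit_weighted_lmm(value ~ 1, d[d$subject_id == "s001", ]),
               "2 subjects")
  expect_error(fit_weighted_lmm(value ~ 1, d[, setdiff(names(d), "weight")]),
               "weight")
})

# --- LS means and multiplicity --------------------------------------------

test_that("intercept-only LS mean is the weighted grand GLS mean", {
  d <- simdata_lmm(14, nsub = 10, nles = 1, nvis = 1, s2p = 0, s2l = 0,
                   rho = 0)
  fit <- fit_weighted_lmm(value ~ 1, d)
  lsm <- ls_means(fit)
  expect_equal(nrow(lsm), 1)
  expect_equal(lsm$estimate, unname(fit$beta[1]))
  # one observation per subject, equal weights: the GLS intercept is the
  # weighted grand mean exactly
  expect_equal(lsm$estimate, weighted.mean(d$value, d$weight), tolerance = 1e-9)
})

test_that("LS means recover known time-level effects inside their CIs", {
  d <- simdata_lmm(16, nsub = 40, nles = 3, nvis = 4, beta0 = -0.2)
  d$time <- factor(d$visit_week)
  fit <- fit_weighted_lmm(value ~ time, d)
  lsm <- ls_means(fit, "time")
  expect_equal(nrow(lsm), 4)
  # z = (estimate - truth)/se is calibrated (unit sd); 3.5 sigma per level
  for (i in seq_len(4)) {
    expect_lt(abs(lsm$estimate[i] + 0.2), 3.5 * lsm$se[i])
  }
  expect_true(all(lsm$p_adj >= lsm$p))
})

test_that("LS means average categorical covariates and fix continuous ones", {
  d <- simdata_lmm(18, nsub = 20, nles = 2, nvis = 3)
  set.seed(18)
  subj <- unique(d$subject_id)
  sex <- setNames(sample(c("F", "M"), length(subj), replace = TRUE), subj)
  age <- setNames(rnorm(length(subj), 40, 8), subj)
  d$sex <- factor(sex[d$subject_id])
  d$age <- age[d$subject_id]
  d$time <- factor(d$visit_week)
  fit <- fit_weighted_lmm(value ~ time + sex + age, d)
  lsm <- ls_means(fit, "time")
  # manual reference row for level 1: sex averaged, age at weighted mean
  bt <- fit$beta
  manual <- bt["(Intercept)"] + 0.5 * bt["sexM"] +
    weighted.mean(d$age, d$weight) * bt["age"]
  expect_equal(lsm$estimate[1], unname(manual), tolerance = 1e-10)
  expect_error(ls_means(fit, "nonexistent"), "not in the model")
})

test_that("multiplicity adjustment follows the standard contracts", {
  expect_equal(adjust_multiplicity(0.03), 0.03)
  expect_equal(adjust_multiplicity(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  set.seed(9)
  p <- runif(6)
  expect_true(all(adjust_multiplicity(p, "holm") <=
                    adjust_multiplicity(p, "bonferroni") + 1e-15))
  expect_true(all(adjust_multiplicity(p, "holm") >= p))
  expect_true(all(adjust_multiplicity(p, "holm") <= 1))
  expect_equal(adjust_multiplicity(p, "none"), p)
  expect_error(adjust_multiplicity(c(0.5, 1.2)), "\\[0, 1\\]")
})
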