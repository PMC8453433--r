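make_hc_for_cal <- function(gm_vals, wm_vals) {
  # tiny 1D-ish series: labels 2 (GM) then 3 (WM) along x
  n <- length(gm_vals) + length(wm_vals)
  tissue <- array(0L, c(n, 1, 1))
  mtr <- array(0, c(n, 1, 1))
  tissue[seq_along(gm_vals), 1, 1] <- 2L
  tissue[length(gm_vals) + seq_along(wm_vals), 1, 1] <- 3L
  mtr[seq_along(gm_vals), 1, 1] <- gm_vals
  mtr[length(gm_vals) + seq_along(wm_vals), 1, 1] <- wm_vals
  structure(list(subject_id = "hc", scanner_id = "A", role = "hc",
                 pixdim = c(1, 1, 1),
                 timepoints = list(list(week = 0, volumes = list(mtr = mtr),
                                        tissue = tissue,
                                        lesion_mask = array(FALSE, c(n, 1, 1))))),
            class = "nawm_series")
}

test_that("calibrate_mtr takes tissue medians and enforces the WM > GM invariant", {
  cal <- calibrate_mtr(make_hc_for_cal(c(0.3, 0.4, 0.5), c(0.8, 0.9, 1.0)))
  expect_equal(cal$median_gm_mtr, 0.4)
  expect_equal(cal$median_wm_mtr, 0.9)
  expect_error(calibrate_mtr(make_hc_for_cal(c(0.9, 0.9, 0.9), c(0.4, 0.4, 0.4))),
               "must exceed")
  expect_error(calibrate_mtr(make_hc_for_cal(numeric(0), c(0.8, 0.9))),
               "grey-matter")
  expect_error(calibrate_mtr(make_hc_for_cal(c(0.3, 0.4), numeric(0))),
               "white-matter")
})

test_that("normalize_mtr maps the calibration anchors to 0 and 1", {
  cal <- structure(list(scanner_id = "A", median_gm_mtr = 30, median_wm_mtr = 40),
                   class = "scanner_calibration")
  v <- array(30, c(4, 4, 2))
  expect_true(all(normalize_mtr(v, cal) == 0))
  v[] <- 40
  expect_true(all(normalize_mtr(v, cal) == 1))
  v[] <- 35
  expect_true(all(normalize_mtr(v, cal) == 0.5))
})

test_that("normalize_mtr is affine, order-preserving and invertible", {
  cal <- structure(list(scanner_id = "A", median_gm_mtr = 28.5, median_wm_mtr = 41.2),
                   class = "scanner_calibration")
  set.seed(3)
  v <- array(runif(60, 10, 60), c(5, 4, 3))
  nm <- normalize_mtr(v, cal)
  expect_true(all(diff(nm[order(v)]) >= 0))
  back <- nm * (cal$median_wm_mtr - cal$median_gm_mtr) + cal$median_gm_mtr
  expect_lt(max(abs(back - v)), 1e-12)
})

test_that("lts_fit recovers exact and contaminated affine relations", {
  set.seed(1)
  x <- rnorm(300)
  f <- lts_fit(x, 2 * x + 5)
  expect_equal(f$gain, 2, tolerance = 1e-10)
  expect_equal(f$offset, 5, tolerance = 1e-10)
  expect_equal(f$n_retained, 150L)              # floor(0.5 * n) contract

  y <- 1.5 * x - 3
  y[1:90] <- y[1:90] + 100                       # 30% contamination
  f <- lts_fit(x, y, fraction = 0.5)
  expect_lt(abs(f$gain - 1.5), 1e-6)
  expect_lt(abs(f$offset + 3), 1e-6)
})

test_that("fraction = 1 reduces lts_fit to ordinary least squares", {
  set.seed(2)
  x <- rnorm(80); y <- 0.7 * x + 2 + rnorm(80, 0, 0.3)
  f <- lts_fit(x, y, fraction = 1)
  ols <- stats::lm(y ~ x)
  expect_equal(f$gain, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(f$offset, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(f$n_retained, 80L)
})

test_that("lts_fit equals the exhaustive-subset optimum on tiny instances", {
  set.seed(7)
  for (rep in 1:4) {
    n <- 12; h <- 6
    x <- rnorm(n); y <- 1.2 * x + rnorm(n, 0, 0.5)
    y[sample(n, 3)] <- y[sample(n, 3)] + 8
    f <- lts_fit(x, y, fraction = 0.5, n_starts = 200, refine_top = 20)
    best <- Inf
    cmb <- utils::combn(n, h)
    for (j in seq_len(ncol(cmb))) {
      ii <- cmb[, j]
      mx <- mean(x[ii]); my <- mean(y[ii])
      g <- sum((x[ii] - mx) * (y[ii] - my)) / sum((x[ii] - mx)^2)
      r2 <- (y - (my - g * mx) - g * x)^2
      best <- min(best, sum(sort(r2)[seq_len(h)]))
    }
    expect_lt(abs(f$objective - best), 1e-8)
  }
})

test_that("lts_fit rejects degenerate inputs and bad fractions", {
  x <- rep(1, 50)
  expect_error(lts_fit(x, x * 2), "degenerate")
  expect_error(lts_fit(rnorm(50), rnorm(50), fraction = 0), "fraction")
  expect_error(lts_fit(rnorm(50), rnorm(49)), "length")
})

# two-timepoint series with an affine acquisition change on the follow-up
affine_series <- function(cfg, gain, offset, channel = "t2w") {
  tpl <- phantom_template(cfg)
  hc <- generate_healthy_control(cfg, "A", seed = 31, template = tpl)
  tp1 <- hc$timepoints[[1]]
  tp2 <- tp1
  tp2$week <- 4
  tp2$volumes[[channel]] <- tp1$volumes[[channel]] * gain + offset
  hc$timepoints <- list(tp1, tp2)
  hc
}

test_that("normalize_t1 satisfies the stage-1 anchors and removes affine drift", {
  cfg <- tiny_config(noise_sd = quiet_noise)
  s <- affine_series(cfg, 1.1, 0, channel = "t1w")
  nt1 <- normalize_t1(s)
  lab <- tissue_labels()
  base_t <- s$timepoints[[1]]$tissue
  expect_equal(median(nt1[[1]][base_t == lab["gm"]]), 0)
  expect_equal(median(nt1[[1]][base_t == lab["wm"]]), 1)
  expect_lt(max(abs(nt1[[2]] - nt1[[1]])), 1e-9)
  # worked example: GM median 400, NAWM median 800 -> voxel at 600 maps to
  # 0.5 (probe placed in background so the medians are untouched)
  expect_equal(median(s$timepoints[[1]]$volumes$t1w[base_t == lab["gm"]]), 400)
  expect_equal(median(s$timepoints[[1]]$volumes$t1w[base_t == lab["wm"]]), 800)
  probe <- s
  probe$timepoints[[1]]$volumes$t1w[1, 1, 1] <- 600
  expect_equal(normalize_t1(probe)[[1]][1, 1, 1], 0.5)
})

test_that("normalize_t2 anchors baseline NAWM at mean 0 / SD 1 and removes offsets", {
  cfg <- tiny_config(noise_sd = quiet_noise)
  s <- affine_series(cfg, 1, 50, channel = "t2w")
  nt2 <- normalize_t2(s)
  lab <- tissue_labels()
  nawm <- s$timepoints[[1]]$tissue == lab["wm"]
  expect_equal(mean(nt2[[1]][nawm]), 0)
  expect_equal(sd(nt2[[1]][nawm]), 1)
  expect_lt(max(abs(nt2[[2]] - nt2[[1]])), 1e-9)
  # z-score contract: a voxel at mean + 2 SD maps to 2
  m <- mean(s$timepoints[[1]]$volumes$t2w[nawm])
  sdv <- sd(s$timepoints[[1]]$volumes$t2w[nawm])
  probe <- s
  probe$timepoints[[1]]$volumes$t2w[1, 1, 1] <- m + 2 * sdv
  expect_equal(normalize_t2(probe)[[1]][1, 1, 1], 2)
})

test_that("T1/T2 outputs are invariant to global affine distortion of a follow-up", {
  cfg <- tiny_config(noise_sd = quiet_noise)
  for (ch in c("t1w", "t2w")) {
    fn <- if (ch == "t1w") normalize_t1 else normalize_t2
    ref <- fn(affine_series(cfg, 1, 0, channel = ch))
    dis <- fn(affine_series(cfg, 0.83, -37, channel = ch))
    expect_lt(max(abs(dis[[2]] - ref[[2]])), 1e-9)
  }
})

test_that("empty or degenerate tissue inputs raise channel-appropriate errors", {
  cfg <- tiny_config(noise_sd = quiet_noise)
  s <- affine_series(cfg, 1, 0)
  s$timepoints[[1]]$tissue[s$timepoints[[1]]$tissue == 3L] <- 0L
  expect_error(normalize_t1(s), "NAWM")
  expect_error(normalize_t2(s), "NAWM")
  s2 <- affine_series(cfg, 1, 0)
  s2$timepoints[[1]]$volumes$t2w[] <- 7
  expect_error(normalize_t2(s2), "SD")
})

test_that("calibration JSON round-trips", {
  cal <- structure(list(scanner_id = "B", median_gm_mtr = 33.9, median_wm_mtr = 44.7),
                   class = "scanner_calibration")
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$median_wm_mtr, 44.7)
  expect_identical(back$scanner_id, "B")
  unlink(f)
})
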