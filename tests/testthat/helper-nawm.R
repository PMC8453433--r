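# Shared fixtures: small configs and hand-built series, all generated in code.

quiet_noise <- c(mtr = 0, t1w = 0, t2w = 0)

# small, fast phantom world for smoke/property tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(32L, 32L, 12L), n_subjects = 4L, n_hc = 2L,
                   seed = 42L)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# Minimal subject series built by hand: `tissues` and `lesions` are lists of
# label arrays / logical masks per visit.
make_series <- function(tissues, lesions = NULL, weeks = NULL,
                        pixdim = c(1, 1, 3), volumes = NULL,
                        normalized = NULL, subject_id = "sub-test") {
  nt <- length(tissues)
  if (is.null(weeks)) weeks <- seq(0, by = 4, length.out = nt)
  if (is.null(lesions))
    lesions <- lapply(tissues, function(t) t == tissue_labels()["lesion"])
  tps <- lapply(seq_len(nt), function(i) {
    tp <- list(week = weeks[i], tissue = tissues[[i]],
               lesion_mask = lesions[[i]])
    if (!is.null(volumes)) tp$volumes <- volumes[[i]]
    if (!is.null(normalized)) tp$normalized <- normalized[[i]]
    tp
  })
  structure(list(subject_id = subject_id, scanner_id = "A", role = "ms",
                 pixdim = pixdim, timepoints = tps, covariates = NULL),
            class = "nawm_series")
}

# simulate directly from the weighted nested AR(1) model
simdata_lmm <- function(seed, nsub = 20, nles = 2, nvis = 4, beta0 = -0.2,
                        s2p = 0.5, s2l = 0.3, s2 = 0.4, rho = 0.6) {
  set.seed(seed)
  rows <- vector("list", nsub * nles)
  k <- 0L
  for (i in seq_len(nsub)) {
    bi <- stats::rnorm(1, 0, sqrt(s2p))
    w <- 1 / nles
    for (j in seq_len(nles)) {
      bij <- stats::rnorm(1, 0, sqrt(s2l))
      e <- numeric(nvis)
      e[1] <- stats::rnorm(1, 0, sqrt(s2 / w))
      for (t in seq_len(nvis)[-1])
        e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, sqrt((s2 / w) * (1 - rho^2)))
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = sprintf("s%03d", i),
        lesion_id = sprintf("s%03d_l%d", i, j),
        visit_week = seq_len(nvis) * 4, value = beta0 + bi + bij + e,
        weight = w)
    }
  }
  do.call(rbind, rows)
}

# dense multivariate-normal REML log-likelihood, written independently of
# the package's blockwise path (the brute-force oracle)
dense_reml_loglik <- function(formula, data, s2, s2p, s2l, rho,
                              subject = "subject_id", lesion = "lesion_id",
                              time = "visit_week", weight = "weight") {
  ord <- order(data[[subject]], data[[lesion]], data[[time]])
  d <- data[ord, , drop = FALSE]
  X <- stats::model.matrix(formula, stats::model.frame(formula, d))
  y <- stats::model.response(stats::model.frame(formula, d))
  n <- nrow(d)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- 0
    if (d[[subject]][i] == d[[subject]][j]) v <- v + s2p
    if (d[[lesion]][i] == d[[lesion]][j]) {
      ii <- which(d[[lesion]] == d[[lesion]][i])
      ti <- rank(d[[time]][ii])[match(i, ii)]
      tj <- rank(d[[time]][ii])[match(j, ii)]
      v <- v + s2l + s2 * rho^abs(ti - tj) /
        sqrt(d[[weight]][i] * d[[weight]][j])
    }
    V[i, j] <- v
  }
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  b <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  p <- ncol(X)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus[1] +
                       determinant(A)$modulus[1] + t(r) %*% Vi %*% r))
}
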