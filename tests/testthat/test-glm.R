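test_that("gamma HRF kernel has the analytic mode, support and mass", {
  k <- gamma_hrf(hrf_params(), dt = 0.01, duration = 32)
  # shape 4, scale 1.5 s -> mode at (4 - 1) * 1.5 = 4.5 s
  expect_equal((which.max(k) - 1) * 0.01, 4.5, tolerance = 0.011)
  expect_true(all(k >= 0))
  expect_equal(sum(k), 1, tolerance = 1e-6)
  expect_equal(sum(gamma_hrf(dt = 2)), 1, tolerance = 1e-6)
})

test_that("high-pass filtering removes slow components and the mean", {
  tr <- 2; n <- 400
  expect_equal(highpass(rep(3.7, n), 100, tr), rep(0, n), tolerance = 1e-12)
  slow <- sin(2 * pi * (1:n) * tr / 200)        # period 200 s
  filt <- highpass(slow, cutoff_s = 100, tr_s = tr)
  expect_lt(sum(filt^2) / sum(slow^2), 0.01)
  fast <- sin(2 * pi * (1:n) * tr / 20)         # period 20 s, in passband
  expect_gt(sum(highpass(fast, 100, tr)^2) / sum(fast^2), 0.9)
  expect_error(highpass(slow, cutoff_s = 3, tr_s = tr), "at least 2 \\* TR")
})

test_that("white-noise variance drops by the drift-basis dimension fraction", {
  set.seed(8)
  tr <- 2; n <- 200; cutoff <- 100
  k_drift <- floor(2 * n * tr / cutoff) + 1     # cosines + intercept
  x <- matrix(rnorm(n * 400), n, 400)
  ratio <- mean(colSums(highpass(x, cutoff, tr)^2) / colSums(x^2))
  expect_equal(ratio, 1 - k_drift / n, tolerance = 0.01)
})

test_that("single-trial design matrices have the documented layout", {
  cfg <- design_config()
  set.seed(11)
  kernel <- gamma_hrf(dt = cfg$tr_s)
  run1 <- generate_event_schedule(cfg, 1)
  n_t <- ceiling((max(run1$onset_s) + 20) / cfg$tr_s)
  motion <- matrix(rnorm(n_t * 6, 0, 0.1), n_t, 6)
  des <- build_design_matrix(run1, kernel, motion, cfg$tr_s, n_t)
  expect_identical(ncol(des$x), 36L + 6L + 1L)
  expect_identical(length(des$trial_cols), 36L)

  run4 <- generate_event_schedule(cfg, 4)      # a conditioned run
  n_t4 <- ceiling((max(run4$onset_s) + 20) / cfg$tr_s)
  des4 <- build_design_matrix(run4, kernel, NULL, cfg$tr_s, n_t4)
  expect_identical(sum(des4$trial_nuisance), 4L)
  cs_free <- sum(run4$class == "CS+" & !run4$shock)
  expect_identical(cs_free, 8L)                # test-eligible CS+ trials

  empty <- run1[0, ]
  des0 <- build_design_matrix(empty, kernel, motion, cfg$tr_s, n_t)
  expect_identical(ncol(des0$x), 7L)           # motion + intercept only

  dup <- rbind(run1[1, ], run1[1, ])           # identical regressors
  expect_error(build_design_matrix(dup, kernel, NULL, cfg$tr_s, n_t),
               "rank deficient")
})

test_that("t and beta match textbook normal equations on a toy problem", {
  set.seed(12)
  n <- 20
  x <- cbind(1, rnorm(n), rnorm(n))
  y <- cbind(rnorm(n), rnorm(n, sd = 2))
  fit <- fit_tstats(y, x)
  # independent brute-force oracle
  xtx_inv <- solve(t(x) %*% x)
  beta <- xtx_inv %*% t(x) %*% y
  for (j in 1:2) {
    res <- y[, j] - x %*% beta[, j]
    s2 <- sum(res^2) / (n - 3)
    t_or <- beta[, j] / sqrt(s2 * diag(xtx_inv))
    expect_equal(unname(fit$beta[, j]), unname(beta[, j]), tolerance = 1e-10)
    expect_equal(unname(fit$t[, j]), unname(t_or), tolerance = 1e-10)
  }
  expect_identical(fit$dof, 17L)
  expect_error(fit_tstats(y[1:2, ], x[1:2, ]), "more timepoints")
})

test_that("noiseless BOLD round-trips through the GLM to the injected patterns", {
  set.seed(13)
  geom <- tiny_geometry("B", grid = c(6, 6, 6), block = 2:4, noise_sd = 0)
  cfg <- design_config()
  pat <- simulate_participant(cfg, geom)
  bold <- generate_bold(pat, cfg, noise_sd = 0, drift_amplitude = 0)
  # noiseless single-trial response: the first samples after onset follow the
  # kernel exactly (later trials cannot reach them: the gamma starts at 0 and
  # the next onset is >= 9.5 s away)
  one <- bold[[1]]
  v <- which(geom$informative_mask)[1]
  kernel <- gamma_hrf(dt = cfg$tr_s)
  onset_idx <- round(one$events$onset_s[1] / cfg$tr_s) + 1L
  expect_equal(one$bold[onset_idx + 1:3, v],
               pat$patterns[1, v] * kernel[2:4], tolerance = 1e-10)

  # near-noiseless series keeps the t maps finite while the trial responses
  # still dominate completely
  for (r in seq_along(bold))
    bold[[r]]$bold <- bold[[r]]$bold +
      matrix(rnorm(length(bold[[r]]$bold), 0, 1e-6), nrow(bold[[r]]$bold))
  tmaps <- fit_trial_tmaps(bold, cfg, cutoff_s = 100,
                           grid_shape = geom$grid_shape, mask = geom$informative_mask)
  expect_identical(nrow(tmaps$patterns), nrow(pat$patterns))
  midx <- which(geom$informative_mask)
  cors <- vapply(seq_len(nrow(pat$patterns)), function(i)
    cor(tmaps$patterns[i, midx], pat$patterns[i, midx]), numeric(1))
  expect_gt(min(cors), 0.99)
})

test_that("doubling the signal doubles the noiseless series", {
  set.seed(14)
  geom1 <- tiny_geometry("A", grid = c(5, 5, 5), block = 2:3, noise_sd = 0,
                         amplitude = 2)
  cfg <- design_config()
  set.seed(77); pat1 <- simulate_participant(cfg, geom1)
  geom2 <- geom1; geom2$signal_amplitude <- 4
  set.seed(77); pat2 <- simulate_participant(cfg, geom2)
  set.seed(5); b1 <- generate_bold(pat1, cfg, noise_sd = 0, drift_amplitude = 0)
  set.seed(5); b2 <- generate_bold(pat2, cfg, noise_sd = 0, drift_amplitude = 0)
  expect_equal(2 * b1[[1]]$bold, b2[[1]]$bold, tolerance = 1e-12)
})

test_that("uncorrelated nuisance regressors leave noiseless betas unchanged", {
  set.seed(15)
  geom <- tiny_geometry("A", grid = c(5, 5, 5), block = 2:3, noise_sd = 0)
  cfg <- design_config()
  pat <- simulate_participant(cfg, geom)
  bold <- generate_bold(pat, cfg, noise_sd = 0, drift_amplitude = 0)
  run <- bold[[1]]
  kernel <- gamma_hrf(dt = cfg$tr_s)
  n_t <- nrow(run$bold)
  des_plain <- build_design_matrix(run$events, kernel, NULL, cfg$tr_s, n_t)
  des_mot <- build_design_matrix(run$events, kernel, run$motion, cfg$tr_s, n_t)
  v <- which(geom$informative_mask)[1:5]
  f1 <- suppressWarnings(fit_tstats(run$bold[, v], des_plain))
  f2 <- suppressWarnings(fit_tstats(run$bold[, v], des_mot))
  expect_lt(max(abs(f1$beta[des_plain$trial_cols, ] -
                    f2$beta[des_mot$trial_cols, ])), 1e-6)
})
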