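test_that("detrending removes constants and linear ramps", {
  const <- fearspace:::detrend_vector(rep(2.5, 40))
  ramp <- fearspace:::detrend_vector(5 + 0.3 * (1:40))
  expect_equal(const, rep(0, 40), tolerance = 1e-12)
  expect_equal(ramp, rep(0, 40), tolerance = 1e-12)
  set.seed(51)
  v <- rnorm(60)
  d <- fearspace:::detrend_vector(v)
  expect_lt(abs(sum(d)), 1e-9)
  expect_lt(abs(sum(d * seq_along(d))), 1e-9)
})

test_that("cosine similarity follows its definition and scale invariance", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1) / sqrt(2)), 0.7071,
               tolerance = 1e-4)
  set.seed(52)
  u <- rnorm(20); v <- rnorm(20)
  expect_equal(cosine_similarity(3 * u, 0.5 * v), cosine_similarity(u, v),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(-u, v), -cosine_similarity(u, v),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("the Fisher transform rescales probabilities and is odd and monotone", {
  expect_equal(fisher_transform(0.5, "probability"), 0)
  expect_equal(fisher_transform(0, "cosine"), 0)
  expect_equal(fisher_transform(0.9, "cosine"), 1.4722, tolerance = 1e-4)
  x <- seq(-0.99, 0.99, by = 0.01)
  fx <- fisher_transform(x, "cosine")
  expect_true(all(diff(fx) > 0))
  expect_equal(fx, -rev(fx), tolerance = 1e-12)
  # boundary values stay finite through the clipping
  expect_true(all(is.finite(fisher_transform(c(0, 1), "probability"))))
})

test_that("noiseless averages reproduce the requested angles to 1e-9", {
  set.seed(53)
  geom <- tiny_geometry("D", grid = c(6, 6, 6), block = 2:4, noise_sd = 0)
  pat <- simulate_participant(design_config(), geom)
  region <- which(geom$informative_mask)
  avg <- average_and_detrend(pat, region, scheme = "searchlight",
                             detrend = "none")
  want <- phase_angles(geom)
  for (i in 1:3) {
    ph <- want$phase[i]
    expect_equal(acos(cosine_similarity(avg$NS, avg$CS[[ph]])),
                 want$theta_n[i] * pi / 180, tolerance = 1e-9)
    expect_equal(acos(cosine_similarity(avg$PS, avg$CS[[ph]])),
                 want$theta_p[i] * pi / 180, tolerance = 1e-9)
  }
  # roi scheme averages every class within each phase
  avg_roi <- average_and_detrend(pat, region, scheme = "roi",
                                 detrend = "none")
  expect_equal(acos(cosine_similarity(avg_roi$conditioned$`CS+`,
                                      avg_roi$conditioned$PS)),
               want$theta_p[2] * pi / 180, tolerance = 1e-9)
  expect_error(average_and_detrend(pat, integer(0)), "region is empty")
})

cohort_verdict <- function(model, seed, n = 12, noise_sd = 0.4, ...) {
  geom <- tiny_geometry(model, grid = c(6, 6, 6), block = 2:4,
                        noise_sd = noise_sd, ...)
  cohort <- simulate_cohort(design_config(), geom, n = n, seed = seed)
  tab <- similarity_table(cohort, which(geom$informative_mask))
  list(geom = geom, cohort = cohort, tab = tab,
       verdict = compare_models(tab))
}

test_that("model adjudication recovers the generating geometry", {
  vB <- cohort_verdict("B", seed = 61, eps2_deg = 30)
  expect_identical(vB$verdict$verdict, "B")
  expect_lt(vB$verdict$delta_theta_p_deg, 0)

  vA <- cohort_verdict("A", seed = 62)
  expect_identical(vA$verdict$verdict, "A")

  vD <- cohort_verdict("D", seed = 63)
  expect_identical(vD$verdict$verdict, "D")
  # recovered changes sit near the injected (eps1, -eps2) at small noise
  expect_lt(abs(vD$verdict$delta_theta_n_deg - vD$geom$eps1_deg), 6)
  expect_lt(abs(vD$verdict$delta_theta_p_deg + vD$geom$eps2_deg), 6)
})

test_that("similarity-decoding correlation separates driving from inert cosines", {
  # exact case: cosines equal to the rescaled probabilities correlate at 1
  tab <- data.frame(participant = rep(1:7, each = 3),
                    phase = rep(c("baseline", "conditioned", "extinction"), 7),
                    cos_n = 0, cos_p = 0)
  set.seed(64)
  prob <- runif(21)
  tab$cos_p <- 2 * prob - 1
  tab$cos_n <- rnorm(21)
  dec <- data.frame(participant = tab$participant, phase = tab$phase,
                    prob = prob)
  out <- correlate_similarity_decoding(tab, dec)
  expect_equal(out$r_p, 1, tolerance = 1e-9)
  expect_true(out$sig_p)

  # independent inputs: |r| below the n = 63 null envelope almost always
  set.seed(65)
  rs <- replicate(300, {
    f1 <- rnorm(63); f2 <- rnorm(63)
    abs(cor(f1, f2))
  })
  expect_gte(mean(rs < 0.32), 0.98)

  # model-B cohort: the PS cosine drives decoding, the NS cosine does not
  vB <- cohort_verdict("B", seed = 66, noise_sd = 1)
  nbhd <- build_neighborhoods(searchlight_spec(27, array(TRUE, c(6, 6, 6))))
  maps <- lapply(vB$cohort, cross_decode, nbhd = nbhd)
  peak <- which(vB$geom$informative_mask)[14]
  pos <- match(peak, nbhd$centers)
  dec <- do.call(rbind, lapply(seq_along(maps), function(i)
    data.frame(participant = i,
               phase = c("baseline", "conditioned", "extinction"),
               prob = maps[[i]]$prob[, pos])))
  out <- correlate_similarity_decoding(vB$tab, dec)
  expect_gt(out$r_p, 0)
  expect_true(out$sig_p)
  expect_false(out$sig_n)
})
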