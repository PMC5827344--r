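test_that("quadratic coefficients interpolate the 3-point profile exactly", {
  prof <- function(y) quadratic_coefficients(array(rep(y, each = 2),
                                                   c(2, 3, 1)))$a[1, 1]
  expect_equal(prof(c(0.3, 0.8, 0.3)), -0.5)
  expect_equal(prof(c(0.5, 0.5, 0.5)), 0)
  expect_equal(prof(c(0.2, 0.5, 0.4)), -0.2)
  # property: equals an independent least-squares quadratic fit at x = -1,0,1
  set.seed(41)
  for (i in 1:20) {
    y <- runif(3)
    ls_fit <- unname(coef(lm(y ~ poly(c(-1, 0, 1), 2, raw = TRUE))))
    expect_equal(prof(y), ls_fit[3], tolerance = 1e-10)
    expect_equal((y[1] + y[3]) / 2 - y[2], prof(y), tolerance = 1e-12)
  }
})

test_that("group t maps match t.test and handle zero variance", {
  set.seed(42)
  x <- matrix(rnorm(21 * 10), 21, 10)
  gt <- group_t_onesample(x)
  for (j in 1:10)
    expect_equal(gt$t[j], unname(t.test(x[, j])$statistic), tolerance = 1e-12)
  expect_identical(gt$dof, 20L)
  # identical values trigger the capped zero-variance branch
  expect_warning(gz <- group_t_onesample(matrix(-0.5, 21, 2)), "zero-variance")
  expect_equal(gz$t, c(-1e6, -1e6))
  # null data rarely produce |t| > 3 at n = 21
  tt <- replicate(1000, group_t_onesample(rnorm(21))$t)
  expect_gte(mean(abs(tt) < 3), 0.99)
})

test_that("TFCE matches the brute-force threshold-loop oracle", {
  # isolated voxel, closed form: 0.1 * sum_{k=1..20} (0.1 k)^2 = 2.87
  x <- array(0, c(5, 5, 5)); x[3, 3, 3] <- 2
  expect_equal(tfce(x)[3, 3, 3], 2.87, tolerance = 1e-12)
  expect_true(all(tfce(array(0, c(4, 4, 4))) == 0))

  set.seed(43)
  for (conn in c(6L, 18L, 26L)) {
    y <- array(pmax(0, rnorm(6^3, 0.3, 0.6)), c(6, 6, 6))
    got <- tfce(y, tfce_params(connectivity = conn))
    expect_equal(got, tfce_oracle(y, connectivity = conn), tolerance = 1e-9)
  }
  # scaling up the map never decreases any TFCE score
  y <- array(abs(rnorm(4^3)), c(4, 4, 4))
  expect_true(all(tfce(1.5 * y) >= tfce(y) - 1e-12))
})

test_that("sign-flip null and empirical p follow the +1/+1 convention", {
  expect_equal(empirical_p(1, rep(0, 10000)), 1 / 10001)
  expect_equal(empirical_p(0.5, c(rep(1, 19), rep(0, 980))), 0.02)
  set.seed(44)
  null <- runif(99)
  p <- empirical_p(c(-1, 2, null[5]), null)
  expect_equal(p[1], 1)                      # below every null value
  expect_equal(p[2], 1 / 100)
  expect_true(all(p >= 1 / 100 & p <= 1))

  dims <- c(4, 4, 4); v <- prod(dims)
  zero_null <- signflip_null(matrix(0, 4, v), seq_len(v), dims, m = 20)
  expect_true(all(zero_null$max_tfce == 0))
  a <- matrix(rnorm(5 * v), 5, v)
  set.seed(9); n1 <- signflip_null(a, seq_len(v), dims, m = 30)
  set.seed(9); n2 <- signflip_null(a, seq_len(v), dims, m = 30)
  expect_identical(n1$max_tfce, n2$max_tfce)
  set.seed(9)
  n3 <- signflip_null(a, seq_len(v), dims, m = 30, scheme = "coin_flip")
  expect_false(identical(n1$max_tfce, n3$max_tfce))
})

test_that("cluster extraction respects threshold, connectivity and peaks", {
  # one-tailed p = 0.005 converts to the canonical z threshold
  expect_equal(qnorm(0.005, lower.tail = FALSE), 2.5758, tolerance = 1e-4)

  dims <- c(6, 6, 6)
  centers <- seq_len(prod(dims))
  p <- rep(1, prod(dims))
  stat <- rep(0, prod(dims))
  lin <- function(i, j, k) i + (j - 1) * 6 + (k - 1) * 36
  # two voxels sharing only a corner
  p[lin(2, 2, 2)] <- 0.001; stat[lin(2, 2, 2)] <- -7.2
  p[lin(3, 3, 3)] <- 0.004; stat[lin(3, 3, 3)] <- -5.0
  t26 <- threshold_clusters(p, stat, centers, dims, connectivity = 26)
  t6 <- threshold_clusters(p, stat, centers, dims, connectivity = 6)
  expect_identical(nrow(t26), 1L)
  expect_identical(t26$n_voxels, 2L)
  expect_identical(nrow(t6), 2L)
  expect_equal(t26$peak_stat, -7.2)          # peak = smallest p, keeps sign
  expect_equal(t26$p_fwer, 0.001)
  expect_equal(t26$z_of_p, qnorm(0.001, lower.tail = FALSE))
  # single suprathreshold voxel forms a size-1 cluster
  p1 <- rep(1, prod(dims)); p1[lin(4, 4, 4)] <- 0.004
  one <- threshold_clusters(p1, stat, centers, dims)
  expect_identical(one$n_voxels, 1L)
  expect_identical(c(one$peak_i, one$peak_j, one$peak_k), c(4L, 4L, 4L))
  # nothing surviving is an empty table, not an error
  none <- threshold_clusters(rep(1, prod(dims)), stat, centers, dims)
  expect_identical(nrow(none), 0L)
  expect_error(threshold_clusters(c(0, rep(1, prod(dims) - 1)), stat,
                                  centers, dims), "in \\(0, 1\\]")
})

test_that("Wilcoxon signed-rank reproduces hand-computed and reference values", {
  w <- wilcoxon_signed_rank(rep(1, 21) + runif(21), rep(0, 21))
  expect_identical(w$W, 231)
  expect_equal(w$z, 4.0145, tolerance = 1e-4)
  expect_lt(w$p, 6e-5)
  expect_identical(wilcoxon_signed_rank(-(1:8))$W, 0)
  expect_identical(wilcoxon_signed_rank(c(1, 2, -3))$W, 3)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "all differences are zero")
  # W agrees with the reference implementation's V statistic
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    expect_identical(wilcoxon_signed_rank(x, y)$W,
                     unname(suppressWarnings(
                       stats::wilcox.test(x, y, paired = TRUE)$statistic)))
  }
})

test_that("repeated-measures F matches aov and the printed df pattern", {
  set.seed(46)
  x <- matrix(rnorm(21 * 3), 21, 3)
  out <- rm_anova_oneway(x)
  expect_identical(c(out$df1, out$df2), c(2L, 40L))
  # identical columns carry no condition effect
  same <- matrix(rnorm(10), 10, 4)
  expect_equal(rm_anova_oneway(same)$F, 0, tolerance = 1e-20)
  # oracle: stats::aov with an Error(subject) stratum, on a 4 x 3 toy table
  toy <- matrix(c(1, 4, 2, 6, 3, 2, 5, 7, 2, 2, 4, 9), 4, 3)
  ref <- summary(stats::aov(y ~ cond + Error(subj),
                            data = data.frame(y = as.vector(toy),
                                              subj = factor(rep(1:4, 3)),
                                              cond = factor(rep(1:3, each = 4)))))
  ref_row <- ref[["Error: Within"]][[1]][1, ]  # the condition effect row
  got <- rm_anova_oneway(toy)
  expect_equal(got$F, ref_row[["F value"]], tolerance = 1e-10)
  expect_equal(got$p, ref_row[["Pr(>F)"]], tolerance = 1e-10)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("the Anderson-Darling screen is calibrated and matches the formula", {
  set.seed(47)
  x8 <- rnorm(8)
  expect_equal(unname(nortest::ad.test(x8)$statistic), ad_statistic_oracle(x8),
               tolerance = 1e-10)
  gaussian <- matrix(rnorm(21 * 4000), 21, 4000)
  frac <- anderson_darling_screen(gaussian, n_sample = 4000)$fraction_normal
  expect_lt(abs(frac - 0.95), 0.015)
  heavy <- matrix(rt(21 * 1000, df = 2), 21, 1000)
  expect_lt(anderson_darling_screen(heavy, 1000)$fraction_normal, 0.9)
  sub <- anderson_darling_screen(gaussian, n_sample = 500)
  expect_identical(sub$n_tested, 500L)
})
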