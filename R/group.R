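#' TFCE parameters
#'
#' @param E extent exponent (0.5 default).
#' @param H height exponent (2 default).
#' @param dh integration step (0.1 default).
#' @param connectivity voxel neighborhood: 6 (faces), 18 (faces + edges) or
#'   26 (full cube, the default).
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = 0.1, connectivity = 26) {
  stopifnot(E > 0, H > 0, dh > 0, connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Quadratic coefficients of the three-phase decoding profile
#'
#' Fits, per participant and voxel, the quadratic `y = a x^2 + b x + c` to
#' the decoding probabilities at phase codes `x = (-1, 0, +1)` for
#' (baseline, conditioned, extinction). With three points the fit
#' interpolates exactly, so `a = (y_baseline + y_extinction) / 2 -
#' y_conditioned`: an inverted-U profile (the conditioning signature) gives
#' `a < 0`.
#'
#' @param phase_maps list of per-participant `phase_maps` objects (from
#'   [cross_decode()]), or a participant x phase x voxel array with phase
#'   dimension ordered baseline, conditioned, extinction.
#' @return list of class `quadratic_fit` with participant-by-voxel matrices
#'   `a`, `b`, `c`.
#' @export
quadratic_coefficients <- function(phase_maps) {
  arr <- as_phase_array(phase_maps)
  slice <- function(j) array(arr[, j, ], dim(arr)[c(1L, 3L)])
  y1 <- slice(1L); y2 <- slice(2L); y3 <- slice(3L)
  structure(list(a = (y1 + y3) / 2 - y2, b = (y3 - y1) / 2, c = y2),
            class = "quadratic_fit")
}

as_phase_array <- function(phase_maps) {
  if (is.array(phase_maps) && length(dim(phase_maps)) == 3L) {
    if (dim(phase_maps)[2L] != 3L) stop("need exactly 3 phases")
    return(phase_maps)
  }
  phases <- c("baseline", "conditioned", "extinction")
  mats <- lapply(phase_maps, function(pm) {
    if (!all(phases %in% rownames(pm$prob))) stop("missing phase map")
    pm$prob[phases, , drop = FALSE]
  })
  arr <- array(NA_real_, c(length(mats), 3L, ncol(mats[[1L]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' One-sample group t map
#'
#' `t = mean / (sd / sqrt(n))` against zero across participants at every
#' voxel, `dof = n - 1`. Zero-variance voxels get a capped signed surrogate
#' of +/- 1e6 (with a warning) rather than infinities.
#'
#' @param values participant-by-voxel matrix (or a vector for one voxel).
#' @param tail alternative hypothesis, recorded for downstream p conversion:
#'   `"negative"`, `"positive"`, or `"two"`.
#' @return list of class `group_t` with `t` (per-voxel), `dof`, `tail`.
#' @export
group_t_onesample <- function(values, tail = c("negative", "positive", "two")) {
  tail <- match.arg(tail)
  x <- if (is.null(dim(values))) matrix(values, ncol = 1L) else values
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 participants")
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  s[s < 0] <- 0
  t <- m / (s / sqrt(n))
  zero_var <- s <= 1e-12 * pmax(abs(m), 1)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel(s); t capped at +/- 1e6")
    t[zero_var] <- sign(m[zero_var]) * 1e6
    t[zero_var & m == 0] <- 0
  }
  structure(list(t = t, dof = n - 1L, tail = tail), class = "group_t")
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds: for voxel `v`,
#' `TFCE(v) = sum over h = dh, 2dh, ... <= x(v) of e(h, v)^E * h^H * dh`
#' where `e(h, v)` is the size of the connected component containing `v`
#' among voxels at or above `h`, under the configured connectivity. Only
#' positive values contribute; negate the map first for a negative-tail
#' hypothesis.
#'
#' @param x 3D statistic array (or vector with `dims` supplied).
#' @param params a [tfce_params()] object.
#' @param dims grid dimensions when `x` is a vector.
#' @return TFCE scores, same shape as `x`.
#' @export
tfce <- function(x, params = tfce_params(), dims = dim(x)) {
  if (is.null(dims) || length(dims) != 3L)
    stop("x must be a 3D array or dims must give 3 extents")
  if (any(!is.finite(x))) stop("statistic map must be finite")
  out <- tfce_cpp(as.numeric(x), as.integer(dims), params$E, params$H,
                  params$dh, params$connectivity)
  if (is.array(x)) array(out, dims) else out
}

# embed per-center statistic values into a full 3D volume (zeros elsewhere)
vector_to_volume <- function(values, centers, dims) {
  vol <- numeric(prod(dims))
  vol[centers] <- values
  array(vol, dims)
}

# group t -> tail-oriented volume -> TFCE, shared by the observed statistic
# and every sign-flip iteration so both take the identical path
group_tfce_stat <- function(coeff, centers, dims, params, tail) {
  gt <- suppressWarnings(group_t_onesample(coeff, tail))
  oriented <- switch(gt$tail, negative = -gt$t, positive = gt$t,
                     two = abs(gt$t))
  tf <- tfce(vector_to_volume(oriented, centers, dims), params, dims)
  list(t = gt$t, tfce = tf[centers], dof = gt$dof)
}

#' Observed group statistic with TFCE
#'
#' Computes the one-sample group t map over participants and its TFCE scores
#' with the map oriented by the alternative hypothesis (negated for
#' `tail = "negative"`, so large TFCE means strong evidence in the predicted
#' direction).
#'
#' @param coeff participant-by-voxel matrix of effect values (e.g. quadratic
#'   coefficients).
#' @param centers linear voxel indices the columns of `coeff` refer to.
#' @param dims 3D grid dimensions.
#' @param params a [tfce_params()] object.
#' @param tail alternative hypothesis direction.
#' @return list with `t` (signed, per center), `tfce` (per center), `dof`.
#' @export
group_tfce <- function(coeff, centers, dims, params = tfce_params(),
                       tail = "negative") {
  group_tfce_stat(coeff, centers, dims, params, tail)
}

#' Sign-flip Monte Carlo null distribution of the max TFCE score
#'
#' Builds the family-wise-error null: on each iteration a number `k` drawn
#' uniformly from 1..n selects, without replacement, `k` participants whose
#' effect maps are negated; the group t map, its TFCE transform, and the
#' volume-wise maximum TFCE score are recomputed and stored. The alternative
#' `scheme = "coin_flip"` negates each participant independently with
#' probability 1/2 (the uniform-over-sign-patterns scheme). The drawn subset
#' is never empty: an empty flip reproduces the observed map exactly, which
#' would bound every voxel's empirical p below by roughly `1/(n+1)` and make
#' small family-wise p values unreachable.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param coeff participant-by-voxel effect matrix.
#' @param centers,dims voxel geometry as in [group_tfce()].
#' @param m number of Monte Carlo iterations (10,000 default).
#' @param params a [tfce_params()] object.
#' @param tail alternative hypothesis direction.
#' @param scheme `"uniform_k"` (default) or `"coin_flip"`.
#' @return object of class `tfce_null`: list with `max_tfce` (length `m`),
#'   `m`, `params`, `tail`, `scheme`.
#' @export
signflip_null <- function(coeff, centers, dims, m = 10000,
                          params = tfce_params(), tail = "negative",
                          scheme = c("uniform_k", "coin_flip")) {
  scheme <- match.arg(scheme)
  n <- nrow(coeff)
  if (n < 2L) stop("need at least 2 participants")
  max_tfce <- numeric(m)
  for (i in seq_len(m)) {
    flip <- if (scheme == "uniform_k") {
      k <- sample.int(n, 1L)
      seq_len(n) %in% sample.int(n, k)
    } else {
      runif(n) < 0.5
    }
    x <- coeff
    x[flip, ] <- -x[flip, ]
    max_tfce[i] <- max(group_tfce_stat(x, centers, dims, params, tail)$tfce)
  }
  structure(list(max_tfce = max_tfce, m = m, params = params, tail = tail,
                 scheme = scheme), class = "tfce_null")
}

#' Empirical family-wise-corrected p values
#'
#' `p(v) = (#\{null max >= TFCE(v)\} + 1) / (m + 1)`: comparing each voxel's
#' observed TFCE score against the null distribution of the volume-wise
#' maximum controls the family-wise error rate; the +1/+1 correction keeps p
#' strictly positive.
#'
#' @param observed vector of observed TFCE scores.
#' @param null a `tfce_null` object (or a numeric vector of null maxima).
#' @return vector of p values in `[1/(m+1), 1]`.
#' @export
empirical_p <- function(observed, null) {
  nullv <- if (inherits(null, "tfce_null")) null$max_tfce else null
  m <- length(nullv)
  if (m == 0L) stop("null distribution is empty")
  vapply(observed, function(o) (sum(nullv >= o) + 1) / (m + 1), numeric(1))
}

#' Threshold a p map and extract clusters
#'
#' Converts p values to z scores via the standard normal inverse survival
#' function, binarizes at `z >= z_threshold` (2.5758 default, i.e.
#' p < 0.005), labels connected components, and tabulates each cluster's
#' size, peak voxel, peak statistic, corrected p, and z(p).
#'
#' @param p vector of (FWER-corrected) p values per center, in (0, 1].
#' @param stat signed statistic values per center (e.g. the group t), used to
#'   report peak statistics with their original sign.
#' @param centers,dims voxel geometry.
#' @param z_threshold cluster-defining z threshold.
#' @param connectivity 6, 18 or 26.
#' @return data frame of class `cluster_table` with columns `cluster_id`,
#'   `n_voxels`, `peak_i`, `peak_j`, `peak_k`, `peak_stat`, `p_fwer`,
#'   `z_of_p`, plus a `members` attribute (list of linear voxel indices).
#'   Empty when nothing survives.
#' @export
threshold_clusters <- function(p, stat, centers, dims,
                               z_threshold = qnorm(0.995),
                               connectivity = 26) {
  if (any(p <= 0 | p > 1)) stop("p values must lie in (0, 1]")
  z <- qnorm(p, lower.tail = FALSE)
  supra_centers <- centers[z >= z_threshold]
  empty <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0), peak_stat = numeric(0),
                      p_fwer = numeric(0), z_of_p = numeric(0))
  if (length(supra_centers) == 0L)
    return(structure(empty, members = list(), class = c("cluster_table",
                                                        "data.frame")))
  mask <- logical(prod(dims))
  mask[supra_centers] <- TRUE
  labels <- label_components_cpp(mask, as.integer(dims),
                                 as.integer(connectivity))
  lab_at <- labels[centers]
  ids <- sort(unique(lab_at[lab_at > 0L]))
  rows <- lapply(seq_along(ids), function(i) {
    sel <- which(lab_at == ids[i])
    peak <- sel[order(-z[sel], centers[sel])][1L]
    ijk <- arrayInd(centers[peak], dims)
    data.frame(cluster_id = i, n_voxels = length(sel),
               peak_i = ijk[1L], peak_j = ijk[2L], peak_k = ijk[3L],
               peak_stat = stat[peak], p_fwer = p[peak], z_of_p = z[peak])
  })
  members <- lapply(ids, function(id) centers[lab_at == id])
  out <- do.call(rbind, rows)
  ord <- order(-out$n_voxels)
  members <- members[ord]
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, members = members, class = c("cluster_table", "data.frame"))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' `W` is the sum of the ranks of the positive differences after dropping
#' zero differences and mid-ranking ties; `z` uses the normal approximation
#' with tie correction and no continuity correction, and `p` is the
#' two-sided normal tail probability.
#'
#' @param x,y paired vectors (`y` omitted for a one-sample test of `x`
#'   against zero).
#' @return list with `W`, `z`, `p`, and `n` (nonzero differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  list(W = w, z = z, p = 2 * pnorm(-abs(z)), n = n)
}

#' One-way repeated-measures ANOVA
#'
#' Classic within-subject decomposition: the condition effect is tested
#' against the subject-by-condition interaction, `F(c - 1, (c - 1)(n - 1))`.
#'
#' @param data complete participant-by-condition numeric matrix.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_oneway <- function(data) {
  x <- as.matrix(data)
  if (any(!is.finite(x))) stop("missing or non-finite cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 participants and >= 2 conditions")
  grand <- mean(x)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  # a condition effect of exactly zero is F = 0 even with a degenerate
  # error term (identical columns)
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Normality screen of per-voxel coefficient vectors
#'
#' Samples voxels without replacement and applies the Anderson-Darling
#' composite-normality test to each voxel's participant vector, reporting the
#' fraction of sampled voxels that fail to reject normality at `alpha` (the
#' sanity check justifying t-based group inference).
#'
#' Uses the current RNG state for the voxel sample.
#'
#' @param coeff participant-by-voxel matrix (needs >= 8 participants, the
#'   test's minimum).
#' @param n_sample voxels to sample (all voxels when fewer are available).
#' @param alpha per-voxel significance level.
#' @return list with `fraction_normal`, `n_tested`, `alpha`.
#' @export
anderson_darling_screen <- function(coeff, n_sample = 10000, alpha = 0.05) {
  if (nrow(coeff) < 8L) {
    warning("Anderson-Darling test needs >= 8 participants; screen skipped")
    return(list(fraction_normal = NA_real_, n_tested = 0L, alpha = alpha))
  }
  v <- ncol(coeff)
  cols <- if (v > n_sample) sample.int(v, n_sample) else seq_len(v)
  pvals <- vapply(cols, function(j) {
    x <- coeff[, j]
    if (sd(x) == 0) return(0)  # degenerate vectors count as rejections
    nortest::ad.test(x)$p.value
  }, numeric(1))
  list(fraction_normal = mean(pvals > alpha), n_tested = length(cols),
       alpha = alpha)
}
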