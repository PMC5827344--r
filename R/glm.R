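#' Hemodynamic response parameters
#'
#' Gamma-shaped HRF parameterized by a phase shift `phi`, standard deviation
#' `sigma`, and mean lag, giving a gamma density with shape
#' `(mean_lag / sigma)^2` and scale `sigma^2 / mean_lag` (shape 4, scale
#' 1.5 s under the defaults, mode at 4.5 s).
#'
#' @param phase_phi_s onset shift in seconds.
#' @param sd_sigma_s standard deviation in seconds, > 0.
#' @param mean_lag_s mean lag in seconds, > 0.
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(phase_phi_s = 0, sd_sigma_s = 3, mean_lag_s = 6) {
  stopifnot(sd_sigma_s > 0, mean_lag_s > 0)
  structure(list(phase_phi_s = phase_phi_s, sd_sigma_s = sd_sigma_s,
                 mean_lag_s = mean_lag_s), class = "hrf_params")
}

#' Sample the gamma HRF kernel
#'
#' @param params an [hrf_params()] object.
#' @param dt sampling step in seconds (> 0), typically the TR.
#' @param duration kernel support in seconds; must cover the kernel mass.
#' @return numeric kernel, non-negative, normalized to unit sum.
#' @examples
#' k <- gamma_hrf(dt = 0.1)
#' (which.max(k) - 1) * 0.1  # mode near 4.5 s
#' @export
gamma_hrf <- function(params = hrf_params(), dt = 2, duration = 32) {
  stopifnot(dt > 0, duration > dt)
  shape <- (params$mean_lag_s / params$sd_sigma_s)^2
  scale <- params$sd_sigma_s^2 / params$mean_lag_s
  t <- seq(0, duration, by = dt)
  h <- dgamma(t - params$phase_phi_s, shape = shape, scale = scale)
  if (sum(h) <= 0) stop("HRF kernel has no mass over the requested support")
  h / sum(h)
}

# discrete-cosine drift basis: intercept plus all DCT-II components with
# period longer than the cutoff
dct_drift_basis <- function(n_timepoints, cutoff_s, tr_s) {
  if (cutoff_s < 2 * tr_s)
    stop("high-pass cutoff must be at least 2 * TR")
  k_max <- floor(2 * n_timepoints * tr_s / cutoff_s)
  tt <- seq_len(n_timepoints) - 0.5
  basis <- matrix(1, n_timepoints, 1L)
  if (k_max >= 1L)
    basis <- cbind(basis, sapply(seq_len(k_max),
                                 function(k) cos(pi * k * tt / n_timepoints)))
  basis
}

#' High-pass filter a time series
#'
#' Removes slow drift by projecting out a discrete-cosine basis: the mean plus
#' every DCT component whose period exceeds `cutoff_s` (the 100 s default
#' matches conventional fMRI preprocessing).
#'
#' @param series numeric vector or time-by-voxel matrix.
#' @param cutoff_s cutoff period in seconds; must be at least `2 * tr_s`.
#' @param tr_s sampling interval in seconds.
#' @return filtered series of the same shape.
#' @export
highpass <- function(series, cutoff_s = 100, tr_s = 2) {
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1L) else series
  basis <- dct_drift_basis(nrow(x), cutoff_s, tr_s)
  out <- qr.resid(qr(basis), x)
  if (vec) drop(out) else out
}

#' Build a least-squares-all single-trial design matrix
#'
#' One HRF-convolved regressor per trial (all trials estimated in one model
#' per run), six motion nuisance columns, and an intercept. Shock-delivery
#' CS+ trials get their own regressors but are flagged as nuisance so
#' downstream decoding never tests them.
#'
#' @param events one run's event table (columns `onset_s`, `class`, `phase`,
#'   `shock`).
#' @param kernel HRF kernel sampled at the TR, e.g. [gamma_hrf()].
#' @param motion time-by-6 motion regressor matrix, or `NULL` to omit.
#' @param tr_s repetition time in seconds.
#' @param n_timepoints number of volumes in the run's series.
#' @return list with `x` (the design matrix), `trial_cols` (column index of
#'   each trial's regressor) and `trial_nuisance` (logical, `TRUE` for shock
#'   trials).
#' @export
build_design_matrix <- function(events, kernel, motion = NULL, tr_s,
                                n_timepoints) {
  n_trials <- nrow(events)
  if (n_trials > 0 &&
      any(round(events$onset_s / tr_s) + 1L > n_timepoints))
    stop("event onsets extend beyond the series duration")
  trial_reg <- if (n_trials > 0) {
    sapply(events$onset_s, function(on) {
      u <- numeric(n_timepoints)
      u[round(on / tr_s) + 1L] <- 1
      convolve_hrf(u, kernel)
    })
  } else matrix(numeric(0), n_timepoints, 0L)
  if (n_trials > 0)
    colnames(trial_reg) <- sprintf("trial_%03d", seq_len(n_trials))
  nuisance <- NULL
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_timepoints)
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    nuisance <- motion
  }
  x <- cbind(trial_reg, nuisance, intercept = 1)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[seq.int(qx$rank + 1L, ncol(x))]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  list(x = x, trial_cols = seq_len(n_trials),
       trial_nuisance = if (n_trials > 0) events$shock else logical(0))
}

#' Fit per-voxel ordinary least squares and t statistics
#'
#' Per voxel: OLS over the full design, `t = beta / SE(beta)` with the
#' standard error from the residual variance and the diagonal of the
#' normal-equations inverse. Voxels with (numerically) zero residual variance
#' get a capped signed surrogate of +/- 1e6 instead of infinities, with a
#' warning.
#'
#' @param series time-by-voxel data matrix.
#' @param design a design matrix or the list from [build_design_matrix()].
#' @return list of class `glm_result`: `beta` and `t` (regressor x voxel
#'   matrices), `dof` (residual degrees of freedom), plus the trial column
#'   bookkeeping when a [build_design_matrix()] list was supplied.
#' @export
fit_tstats <- function(series, design) {
  info <- NULL
  if (is.list(design) && !is.null(design$x)) {
    info <- design
    design <- design$x
  }
  series <- as.matrix(series)
  stopifnot(nrow(series) == nrow(design))
  if (nrow(design) <= ncol(design))
    stop("need more timepoints than regressors")
  qx <- qr(design)
  beta <- qr.coef(qx, series)
  res <- qr.resid(qx, series)
  dof <- nrow(design) - qx$rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tiny <- sigma2 < 1e-24 * max(colSums(series^2), 1)
  tmap <- beta / se
  if (any(tiny)) {
    warning(sum(tiny), " voxel(s) with zero residual variance; ",
            "t capped at +/- 1e6")
    tmap[, tiny] <- sign(beta[, tiny]) * 1e6
  }
  tmap[is.nan(tmap)] <- 0
  structure(list(beta = beta, t = tmap, dof = dof,
                 trial_cols = info$trial_cols,
                 trial_nuisance = info$trial_nuisance),
            class = "glm_result")
}

#' Per-trial t-score maps from BOLD runs
#'
#' The GLM stage of the pipeline: for each run, high-pass filters the data
#' and the trial/motion regressors (equivalent to adding the drift basis to
#' the model), fits the least-squares-all single-trial GLM, and collects each
#' trial's t-score map. The result has the same shape as the generator's
#' `trial_patterns`, so every downstream stage runs unchanged on it.
#'
#' @param bold_runs list of per-run lists with `bold`, `motion`, `events`
#'   (as from [generate_bold()], or assembled from files).
#' @param config a [design_config()] (for the TR).
#' @param hrf HRF kernel sampled at the TR.
#' @param cutoff_s high-pass cutoff in seconds; `NA` disables filtering.
#' @param grid_shape,mask carried into the returned object.
#' @return a `trial_patterns` object whose `patterns` are t-score maps.
#' @export
fit_trial_tmaps <- function(bold_runs, config,
                            hrf = gamma_hrf(dt = config$tr_s),
                            cutoff_s = 100, grid_shape = NULL, mask = NULL) {
  per_run <- lapply(bold_runs, function(run) {
    n_t <- nrow(run$bold)
    des <- build_design_matrix(run$events, hrf, run$motion, config$tr_s, n_t)
    y <- run$bold
    if (!is.na(cutoff_s)) {
      y <- highpass(y, cutoff_s, config$tr_s)
      keep <- seq_len(ncol(des$x) - 1L)  # filter all but the intercept
      des$x[, keep] <- highpass(des$x[, keep, drop = FALSE], cutoff_s,
                                config$tr_s)
    }
    fit <- fit_tstats(y, des)
    fit$t[des$trial_cols, , drop = FALSE]
  })
  events <- do.call(rbind, lapply(bold_runs, `[[`, "events"))
  structure(list(patterns = do.call(rbind, per_run), events = events,
                 grid_shape = grid_shape, mask = mask),
            class = "trial_patterns")
}
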