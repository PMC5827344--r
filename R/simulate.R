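#' Generate per-trial voxel patterns
#'
#' Builds the trial-by-voxel pattern matrix the decoding analysis consumes
#' (a stand-in for single-trial t-score maps): every trial's map is
#' `signal_amplitude` times its class prototype embedded at the informative
#' voxels, plus i.i.d. Gaussian noise of standard deviation `noise_sd` at
#' every voxel of the grid; voxels outside the informative mask carry pure
#' noise. CS+ trials use the prototype of their phase (conditioning-run CS+
#' trials use the conditioned-phase prototype).
#'
#' @param schedule event table from [generate_schedule()].
#' @param prototypes output of [make_phase_prototypes()].
#' @param geometry the [representational_geometry()] the prototypes came from.
#' @return an object of class `trial_patterns`: list with `patterns` (trial x
#'   voxel matrix over the flattened grid), `events` (the schedule),
#'   `grid_shape`, and `mask` (the informative mask).
#' @export
generate_trial_patterns <- function(schedule, prototypes, geometry) {
  v <- prod(geometry$grid_shape)
  n <- nrow(schedule)
  mask_idx <- which(geometry$informative_mask)
  x <- matrix(rnorm(n * v, 0, geometry$noise_sd), n, v)
  cls <- geometry_class_labels(schedule, geometry)
  for (key in unique(cls)) {
    proto <- prototype_for(key, prototypes)
    rows <- which(cls == key)
    x[rows, mask_idx] <- x[rows, mask_idx] +
      matrix(geometry$signal_amplitude * proto, length(rows),
             length(mask_idx), byrow = TRUE)
  }
  structure(list(patterns = x, events = schedule,
                 grid_shape = geometry$grid_shape,
                 mask = geometry$informative_mask),
            class = "trial_patterns")
}

# one signal key per trial: "NS", "PS", or "CS.<phase>"
geometry_class_labels <- function(schedule, geometry) {
  phase <- ifelse(schedule$phase == "conditioning", "conditioned",
                  schedule$phase)
  ifelse(schedule$class == "CS+", paste0("CS.", phase), schedule$class)
}

prototype_for <- function(key, prototypes) {
  if (key %in% c("NS", "PS")) return(prototypes[[key]])
  prototypes$CS[[sub("^CS\\.", "", key)]]
}

#' Simulate one participant
#'
#' Generates a fresh event schedule and, with a participant-specific random
#' prototype frame, the trial pattern set. Uses the current RNG state.
#'
#' @param design a [design_config()] object.
#' @param geometry a [representational_geometry()] object.
#' @return a `trial_patterns` object.
#' @export
simulate_participant <- function(design, geometry) {
  schedule <- generate_schedule(design)
  prototypes <- make_phase_prototypes(geometry)
  generate_trial_patterns(schedule, prototypes, geometry)
}

#' Simulate a cohort
#'
#' @param design a [design_config()] object.
#' @param geometry a [representational_geometry()] object.
#' @param n cohort size; defaults to `design$n_participants`.
#' @param seed optional integer seed; all randomness of the cohort flows
#'   from it.
#' @return list of `trial_patterns`, one per participant.
#' @export
simulate_cohort <- function(design, geometry, n = design$n_participants,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) simulate_participant(design, geometry))
}

#' Generate BOLD-like 4D time series from trial patterns
#'
#' Lays each trial's pattern onto the time axis as an HRF-convolved event
#' regressor sampled at the TR grid, adds slow cosine drift with random
#' per-voxel weights, i.i.d. Gaussian noise, and returns six smooth
#' random-walk motion regressors. Intended for end-to-end testing of the GLM
#' stage; it does not model scanner physics or spatially correlated noise.
#'
#' @param patterns a `trial_patterns` object (use `noise_sd = 0` in the
#'   geometry for noiseless round-trip tests).
#' @param config the [design_config()] the schedule came from (for the TR).
#' @param hrf HRF kernel sampled at the TR, e.g. `gamma_hrf(dt = config$tr_s)`.
#' @param noise_sd temporal noise standard deviation.
#' @param drift_amplitude scale of the low-frequency drift (0 disables).
#' @param pad_s seconds of rest appended after the last trial.
#' @return list of per-run lists, each with `bold` (time x voxel matrix),
#'   `motion` (time x 6), and `events` (that run's schedule).
#' @export
generate_bold <- function(patterns, config, hrf = gamma_hrf(dt = config$tr_s),
                          noise_sd = 0.5, drift_amplitude = 1, pad_s = 16) {
  ev <- patterns$events
  lapply(unique(ev$run), function(r) {
    rows <- which(ev$run == r)
    evr <- ev[rows, , drop = FALSE]
    tr <- config$tr_s
    n_t <- ceiling((max(evr$onset_s + evr$duration_s) + pad_s) / tr)
    reg <- sapply(evr$onset_s, function(on) {
      u <- numeric(n_t)
      u[min(n_t, round(on / tr) + 1L)] <- 1
      convolve_hrf(u, hrf)
    })
    bold <- reg %*% patterns$patterns[rows, , drop = FALSE]
    v <- ncol(bold)
    if (drift_amplitude > 0) {
      tt <- seq_len(n_t)
      slow <- cbind(cos(pi * tt / n_t), cos(2 * pi * tt / n_t))
      bold <- bold + slow %*% matrix(rnorm(2 * v, 0, drift_amplitude), 2, v)
    }
    if (noise_sd > 0) bold <- bold + matrix(rnorm(n_t * v, 0, noise_sd), n_t, v)
    steps <- matrix(rnorm(n_t * 6, 0, 0.02), n_t, 6)
    motion <- apply(steps, 2, cumsum)
    motion <- apply(motion, 2, function(m)
      stats::filter(m, rep(1 / 5, 5), sides = 2, circular = TRUE))
    list(bold = bold, motion = motion, events = evr)
  })
}

# causal convolution with a unit-sum kernel, truncated to the input length
convolve_hrf <- function(u, kernel) {
  n <- length(u)
  out <- stats::convolve(u, rev(kernel), type = "open")[seq_len(n)]
  out
}
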