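#' Experimental design configuration
#'
#' Describes the two-factorial event-related design: experimental phase
#' (baseline, conditioning, conditioned, extinction) crossed with stimulus
#' class (NS neutral, PS phobic, CS+ conditioned). Eight runs are acquired:
#' 2 baseline, 1 conditioning, 3 conditioned, 2 extinction. Every run except
#' the conditioning run presents 6 images per class, twice each, for all
#' three classes (36 trials); the conditioning run omits the phobic class
#' (24 trials). A trial is a 2 s fixation, a 1.5 s stimulus, then an
#' inter-trial interval of `iti_base_s + X` seconds with
#' `X ~ geometric(iti_geom_p)` truncated at 10 s (8 s during conditioning).
#' Shocks reinforce 6 of the 12 CS+ trials in the conditioning run and 4 of
#' the 12 CS+ trials in each conditioned run.
#'
#' @param n_participants default cohort size for simulation.
#' @param runs_per_phase named integer vector: runs per experimental phase.
#'   Exactly one conditioning run is required.
#' @param classes stimulus class labels; the first is the neutral class, the
#'   second the phobic class, the third the to-be-conditioned class.
#' @param images_per_class,repetitions_per_image trials per class per run are
#'   `images_per_class * repetitions_per_image`.
#' @param shock_per_run named vector: number of shock-reinforced CS+ trials in
#'   a run of each listed phase; phases not listed receive no shocks.
#' @param fixation_s,stimulus_s,iti_base_s event durations in seconds.
#' @param iti_geom_p success probability of the geometric jitter.
#' @param iti_truncation_s named vector with elements `conditioning` and
#'   `other`: cap (seconds) applied to the geometric jitter X.
#' @param tr_s repetition time of the simulated acquisition, seconds.
#' @return an object of class `fear_design` (a validated list).
#' @examples
#' design <- design_config()
#' run_table(design)
#' @export
design_config <- function(n_participants = 12,
                          runs_per_phase = c(baseline = 2, conditioning = 1,
                                             conditioned = 3, extinction = 2),
                          classes = c("NS", "PS", "CS+"),
                          images_per_class = 6,
                          repetitions_per_image = 2,
                          shock_per_run = c(conditioning = 6, conditioned = 4),
                          fixation_s = 2,
                          stimulus_s = 1.5,
                          iti_base_s = 6,
                          iti_geom_p = 0.3,
                          iti_truncation_s = c(conditioning = 8, other = 10),
                          tr_s = 2) {
  stopifnot(length(classes) == 3L, !anyDuplicated(classes))
  phases <- c("baseline", "conditioning", "conditioned", "extinction")
  if (!all(phases %in% names(runs_per_phase)))
    stop("runs_per_phase must name baseline, conditioning, conditioned, extinction")
  if (runs_per_phase[["conditioning"]] != 1L)
    stop("exactly one conditioning run is required")
  if (any(runs_per_phase[c("baseline", "conditioned", "extinction")] < 1))
    stop("each analyzed phase needs at least one run")
  durations <- c(fixation_s, stimulus_s, iti_base_s, tr_s)
  if (any(durations <= 0)) stop("all durations must be > 0")
  if (iti_geom_p <= 0 || iti_geom_p >= 1) stop("iti_geom_p must lie in (0, 1)")
  if (any(iti_truncation_s < 0)) stop("iti truncation must be >= 0")
  cfg <- list(n_participants = as.integer(n_participants),
              runs_per_phase = runs_per_phase,
              classes = classes,
              images_per_class = as.integer(images_per_class),
              repetitions_per_image = as.integer(repetitions_per_image),
              shock_per_run = shock_per_run,
              fixation_s = fixation_s, stimulus_s = stimulus_s,
              iti_base_s = iti_base_s, iti_geom_p = iti_geom_p,
              iti_truncation_s = iti_truncation_s, tr_s = tr_s)
  class(cfg) <- "fear_design"
  cfg
}

#' Run-to-phase lookup
#'
#' @param config a [design_config()] object.
#' @return data frame with columns `run` (1-based index) and `phase`, in
#'   acquisition order: baseline runs, the conditioning run, conditioned runs,
#'   extinction runs.
#' @export
run_table <- function(config) {
  phases <- c("baseline", "conditioning", "conditioned", "extinction")
  phase <- rep(phases, times = config$runs_per_phase[phases])
  data.frame(run = seq_along(phase), phase = phase,
             stringsAsFactors = FALSE)
}

#' Sample inter-trial intervals
#'
#' Draws `iti_base_s + X` with `X ~ geometric(iti_geom_p)` counting failures
#' before the first success (support 0, 1, 2, ...), clipped at the phase's
#' truncation bound: 8 s during conditioning, 10 s elsewhere, so the total
#' interval lies in \[6, 14\] or \[6, 16\] seconds under the defaults.
#'
#' @param phase experimental phase label.
#' @param config a [design_config()] object.
#' @param n number of draws.
#' @return numeric vector of intervals in seconds.
#' @export
sample_iti <- function(phase, config, n = 1) {
  cap <- if (identical(phase, "conditioning"))
    config$iti_truncation_s[["conditioning"]]
  else config$iti_truncation_s[["other"]]
  x <- pmin(rgeom(n, config$iti_geom_p), cap)
  config$iti_base_s + x
}

# Pseudorandomized class sequence: no class more than twice in a row,
# by rejection sampling (bounded attempts).
pseudorandom_classes <- function(classes, n_per_class, max_attempts = 10000) {
  pool <- rep(classes, each = n_per_class)
  for (attempt in seq_len(max_attempts)) {
    s <- sample(pool)
    if (max(rle(s)$lengths) <= 2L) return(s)
  }
  stop("pseudorandomization failed after ", max_attempts,
       " attempts; constraint infeasible for this class balance")
}

#' Generate the event schedule of one run
#'
#' Builds the trial list of a single run: class order pseudorandomized so that
#' no class appears more than twice consecutively, image identities balanced
#' (each image of each class shown `repetitions_per_image` times), onsets laid
#' out as fixation + stimulus + jittered inter-trial interval, and shock flags
#' assigned uniformly at random to the configured number of CS+ trials. The
#' conditioning run omits the phobic class.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param config a [design_config()] object.
#' @param run_index run number, 1 to the total number of runs.
#' @return data frame with columns `run`, `phase`, `class`, `image_id`,
#'   `onset_s`, `duration_s`, `shock`. Onsets are seconds from run start
#'   (stimulus onset; the preceding fixation starts `fixation_s` earlier).
#' @examples
#' set.seed(1)
#' sched <- generate_event_schedule(design_config(), run_index = 1)
#' nrow(sched)  # 36
#' @export
generate_event_schedule <- function(config, run_index) {
  rt <- run_table(config)
  if (!run_index %in% rt$run) stop("run_index out of range")
  phase <- rt$phase[rt$run == run_index]
  cls <- config$classes
  if (identical(phase, "conditioning")) cls <- setdiff(cls, cls[2L])
  n_per_class <- config$images_per_class * config$repetitions_per_image
  class_seq <- pseudorandom_classes(cls, n_per_class)
  n_trials <- length(class_seq)

  image_id <- integer(n_trials)
  for (cl in cls) {
    idx <- which(class_seq == cl)
    image_id[idx] <- sample(rep(seq_len(config$images_per_class),
                                config$repetitions_per_image))
  }

  iti <- sample_iti(phase, config, n_trials)
  # onset of trial i = previous onset + stimulus + previous ITI + fixation
  gaps <- config$stimulus_s + iti[-n_trials] + config$fixation_s
  onset <- config$fixation_s + c(0, cumsum(gaps))

  shock <- rep(FALSE, n_trials)
  if (phase %in% names(config$shock_per_run)) {
    k <- config$shock_per_run[[phase]]
    cs_idx <- which(class_seq == config$classes[3L])
    if (k > length(cs_idx)) stop("more shocks requested than CS+ trials")
    shock[sample(cs_idx, k)] <- TRUE
  }

  data.frame(run = run_index, phase = phase, class = class_seq,
             image_id = image_id, onset_s = onset,
             duration_s = config$stimulus_s, shock = shock,
             stringsAsFactors = FALSE)
}

#' Generate the full-session event schedule
#'
#' @param config a [design_config()] object.
#' @return data frame: the row-bound schedules of all runs.
#' @export
generate_schedule <- function(config) {
  rt <- run_table(config)
  do.call(rbind, lapply(rt$run, function(r) generate_event_schedule(config, r)))
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`, `image_id`,
#' `run`, `phase`, `shock`, so schedules round-trip losslessly and real
#' BIDS-dialect event tables can be dropped in.
#'
#' @param events a schedule data frame as from [generate_schedule()].
#' @param path file path.
#' @return `read_events` returns the schedule data frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset = events$onset_s, duration = events$duration_s,
                    trial_type = events$class, image_id = events$image_id,
                    run = events$run, phase = events$phase,
                    shock = as.integer(events$shock))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "run", "phase")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("events table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  data.frame(run = tab$run, phase = tab$phase, class = tab$trial_type,
             image_id = if ("image_id" %in% names(tab)) tab$image_id else NA,
             onset_s = tab$onset, duration_s = tab$duration,
             shock = if ("shock" %in% names(tab)) as.logical(tab$shock) else FALSE,
             stringsAsFactors = FALSE)
}
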