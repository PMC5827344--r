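#' Read and write NIfTI volumes
#'
#' Thin lossless wrappers around RNifti for 3D maps and 4D trial stacks.
#' Volumes carry an identity affine by default; world-coordinate handling is
#' pass-through only.
#'
#' @param x numeric 3D or 4D array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns the array; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI volume ",
                                           path, ": ", conditionMessage(e)))
  as.array(img)
}

#' Write / read a per-trial map stack with its label sidecar
#'
#' Stores the trial-by-voxel matrix as a 4D volume (one 3D map per trial)
#' next to a JSON sidecar mapping volume index to (run, phase, class, shock),
#' so trial labels stay order-aligned with the maps.
#'
#' @param patterns a `trial_patterns` object.
#' @param path volume path; the sidecar replaces the extension with `.json`.
#' @return `read_trial_stack` returns a `trial_patterns` object;
#'   `write_trial_stack` returns `path` invisibly.
#' @export
write_trial_stack <- function(patterns, path) {
  dims <- patterns$grid_shape
  arr <- array(t(patterns$patterns), c(dims, nrow(patterns$patterns)))
  write_volume(arr, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(patterns$events[c("run", "phase", "class", "image_id",
                                         "onset_s", "duration_s", "shock")],
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_stack
#' @export
read_trial_stack <- function(path) {
  arr <- read_volume(path)
  if (length(dim(arr)) != 4L) stop("expected a 4D trial stack in ", path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing trial-label sidecar: ", sidecar)
  events <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  dims <- dim(arr)[1:3]
  n <- dim(arr)[4L]
  if (nrow(events) != n)
    stop("sidecar ", sidecar, ": ", nrow(events), " trial labels for ", n,
         " volumes")
  structure(list(patterns = t(matrix(arr, prod(dims), n)), events = events,
                 grid_shape = dims, mask = NULL),
            class = "trial_patterns")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file with optional blocks `design`, `geometry`, `pipeline`
#' (each holding arguments of [design_config()],
#' [representational_geometry()] and [pipeline_config()]) onto a validated
#' [pipeline_config()] object.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- do.call(design_config, as_plain_args(raw$design))
  geometry <- do.call(representational_geometry, as_plain_args(raw$geometry))
  args <- as_plain_args(raw$pipeline)
  args$design <- design
  args$geometry <- geometry
  do.call(pipeline_config, args)
}

as_plain_args <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}
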