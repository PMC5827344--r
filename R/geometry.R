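#' Representational geometry of the synthetic cohort
#'
#' Fixes the ground-truth geometry that the analysis is meant to recover.
#' Stimulus classes are represented by unit prototype vectors over the
#' informative voxels. The angle between NS and CS+ is `theta_n`, between PS
#' and CS+ is `theta_p`. Four models describe how the CS+ prototype moves
#' after conditioning:
#' \describe{
#'   \item{A (static)}{no change: the CS+ representation ignores conditioning.}
#'   \item{B (toward PS)}{`theta_p` shrinks by `eps2` while `theta_n` is
#'     unchanged: CS+ becomes more similar to the phobic class.}
#'   \item{C (away from NS)}{`theta_n` grows by `eps1` while `theta_p` is
#'     unchanged.}
#'   \item{D (both)}{`theta_n` grows by `eps1` and `theta_p` shrinks by
#'     `eps2`.}
#' }
#' In every model the extinction-phase angles return to their baseline
#' values. NS and PS prototypes never move.
#'
#' @param model one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param theta_n_deg baseline angle NS--CS+ in degrees, in (0, 180).
#' @param theta_p_deg baseline angle PS--CS+ in degrees, in (0, 180).
#' @param theta_np_deg fixed angle NS--PS in degrees; must keep every phase's
#'   `(theta_n, theta_p)` pair inside the spherical triangle inequality.
#' @param eps1_deg conditioning-induced increase of `theta_n` (models C, D).
#' @param eps2_deg conditioning-induced decrease of `theta_p` (models B, D).
#'   `NULL` picks the model's default (0 where the model forbids change,
#'   20 / 40 degrees otherwise).
#' @param signal_amplitude multiplier applied to the unit prototype when a
#'   trial pattern is built (arbitrary t-score-like units).
#' @param noise_sd standard deviation of the i.i.d. Gaussian voxel noise.
#' @param grid_shape 3 integers, the voxel grid.
#' @param informative_mask logical array of `grid_shape`; `NULL` places a
#'   5x5x5 block at the grid center.
#' @return an object of class `fear_geometry`.
#' @examples
#' geom <- representational_geometry("B")
#' phase_angles(geom)
#' @export
representational_geometry <- function(model = c("B", "A", "C", "D"),
                                      theta_n_deg = 40,
                                      theta_p_deg = 60,
                                      theta_np_deg = 50,
                                      eps1_deg = NULL,
                                      eps2_deg = NULL,
                                      signal_amplitude = 3,
                                      noise_sd = 1,
                                      grid_shape = c(20, 20, 20),
                                      informative_mask = NULL) {
  model <- match.arg(model)
  if (is.null(eps1_deg)) eps1_deg <- if (model %in% c("C", "D")) 20 else 0
  if (is.null(eps2_deg)) eps2_deg <- if (model %in% c("B", "D")) 40 else 0
  ok <- switch(model,
               A = eps1_deg == 0 && eps2_deg == 0,
               B = eps1_deg == 0 && eps2_deg > 0,
               C = eps1_deg > 0 && eps2_deg == 0,
               D = eps1_deg > 0 && eps2_deg > 0)
  if (!ok) stop("eps1/eps2 inconsistent with model ", model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (is.null(informative_mask)) {
    if (any(grid_shape < 5L))
      stop("grid too small for the default 5x5x5 informative block; ",
           "supply informative_mask")
    informative_mask <- array(FALSE, grid_shape)
    lo <- floor((grid_shape - 5L) / 2) + 1L
    informative_mask[lo[1]:(lo[1] + 4L), lo[2]:(lo[2] + 4L),
                     lo[3]:(lo[3] + 4L)] <- TRUE
  }
  stopifnot(identical(dim(informative_mask), grid_shape))
  geom <- list(model = model, theta_n_deg = theta_n_deg,
               theta_p_deg = theta_p_deg, theta_np_deg = theta_np_deg,
               eps1_deg = eps1_deg, eps2_deg = eps2_deg,
               signal_amplitude = signal_amplitude, noise_sd = noise_sd,
               grid_shape = grid_shape, informative_mask = informative_mask)
  class(geom) <- "fear_geometry"
  pa <- phase_angles(geom)
  if (any(pa$theta_n <= 0 | pa$theta_n >= 180 |
          pa$theta_p <= 0 | pa$theta_p >= 180))
    stop("phase angles must stay inside (0, 180) degrees")
  # fail early if any phase's triple is unrealizable
  for (i in seq_len(nrow(pa)))
    cs_coords(theta_np_deg, pa$theta_n[i], pa$theta_p[i])
  geom
}

#' @rdname representational_geometry
#' @param geometry a `fear_geometry` object.
#' @return `phase_angles` returns a data frame with the per-phase
#'   (`theta_n`, `theta_p`) in degrees for the three analyzed phases.
#' @export
phase_angles <- function(geometry) {
  data.frame(phase = c("baseline", "conditioned", "extinction"),
             theta_n = c(geometry$theta_n_deg,
                         geometry$theta_n_deg + geometry$eps1_deg,
                         geometry$theta_n_deg),
             theta_p = c(geometry$theta_p_deg,
                         geometry$theta_p_deg - geometry$eps2_deg,
                         geometry$theta_p_deg),
             stringsAsFactors = FALSE)
}

# Coordinates of a unit CS+ vector in the orthonormal frame (e1 = NS,
# e2 completing span(NS, PS), e3 orthogonal) that realizes angles
# theta_n to NS and theta_p to PS exactly; errors when the spherical
# triangle inequality is violated.
cs_coords <- function(theta_np_deg, theta_n_deg, theta_p_deg) {
  psi <- theta_np_deg * pi / 180
  tn <- theta_n_deg * pi / 180
  tp <- theta_p_deg * pi / 180
  x <- cos(tn)
  y <- (cos(tp) - cos(psi) * cos(tn)) / sin(psi)
  z2 <- 1 - x^2 - y^2
  if (z2 < -1e-12)
    stop("angle triple (theta_np = ", theta_np_deg, ", theta_n = ",
         theta_n_deg, ", theta_p = ", theta_p_deg,
         ") violates the spherical triangle inequality")
  c(x, y, sqrt(max(z2, 0)))
}

#' Construct per-phase class prototype vectors
#'
#' Draws a random orthonormal 3-frame in the informative subspace and places
#' unit prototypes in it: NS along the first axis, PS at `theta_np` from NS in
#' the plane of the first two axes, and the CS+ of each phase in the full
#' 3-space so that its angles to NS and PS equal the model's
#' (`theta_n`, `theta_p`) for that phase exactly. The construction is exact
#' (orthonormalization, then closed-form coordinates), not approximate.
#'
#' Uses the current RNG state for the random frame.
#'
#' @param geometry a [representational_geometry()] object.
#' @return list with unit vectors `NS`, `PS` (length = number of informative
#'   voxels) and `CS`, a list of per-phase unit vectors named `baseline`,
#'   `conditioned`, `extinction`.
#' @export
make_phase_prototypes <- function(geometry) {
  d <- sum(geometry$informative_mask)
  if (d < 3L) stop("informative mask must contain at least 3 voxels")
  qrq <- qr.Q(qr(matrix(rnorm(d * 3L), d, 3L)))
  psi <- geometry$theta_np_deg * pi / 180
  ns <- qrq[, 1L]
  ps <- cos(psi) * qrq[, 1L] + sin(psi) * qrq[, 2L]
  pa <- phase_angles(geometry)
  cs <- lapply(seq_len(nrow(pa)), function(i) {
    co <- cs_coords(geometry$theta_np_deg, pa$theta_n[i], pa$theta_p[i])
    drop(qrq %*% co)
  })
  names(cs) <- pa$phase
  list(NS = ns, PS = ps, CS = cs)
}
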