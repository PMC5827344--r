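#' Searchlight specification
#'
#' @param n_voxels neighborhood size: each searchlight is the `n_voxels`
#'   nearest in-mask voxels around its center (50 by default), not a fixed
#'   radius, so edge and corner centers keep full-size neighborhoods.
#' @param mask logical 3D array: the analysis mask.
#' @return list of class `searchlight_spec`.
#' @export
searchlight_spec <- function(n_voxels = 50, mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (sum(mask) < n_voxels)
    stop("mask contains fewer voxels than the searchlight size")
  structure(list(n_voxels = as.integer(n_voxels), mask = mask),
            class = "searchlight_spec")
}

#' Build searchlight neighborhoods
#'
#' For every in-mask voxel, finds the `n_voxels` nearest in-mask voxels by
#' Euclidean distance on the integer voxel indices, center included. Distance
#' ties are broken by ascending linear voxel index, making the neighborhoods
#' deterministic.
#'
#' @param spec a [searchlight_spec()] object.
#' @return list of class `searchlight_neighborhoods` with `centers` (linear
#'   indices of the in-mask centers), `nb` (an `n_voxels` x n-centers integer
#'   matrix of linear voxel indices), `dims`, and `n_voxels`.
#' @export
build_neighborhoods <- function(spec) {
  dims <- dim(spec$mask)
  centers <- which(spec$mask)
  n <- spec$n_voxels
  coords <- arrayInd(centers, dims)
  # offset table out to a Chebyshev radius that (for a full mask) surely
  # contains n voxels; grown adaptively for sparse masks
  radius <- 1L
  while ((2L * radius + 1L)^3 < 4L * n) radius <- radius + 1L

  offsets_for <- function(r) {
    g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
    d2 <- g$dx^2 + g$dy^2 + g$dz^2
    ord <- order(d2)
    list(off = as.matrix(g)[ord, , drop = FALSE], d2 = d2[ord])
  }

  nb <- matrix(0L, n, length(centers))
  idx_mult <- c(1L, dims[1L], dims[1L] * dims[2L])
  mask_vec <- as.vector(spec$mask)
  base_ofs <- offsets_for(radius)
  for (i in seq_along(centers)) {
    r <- radius
    repeat {
      ofs <- if (r == radius) base_ofs else offsets_for(r)
      cand <- sweep(ofs$off, 2L, coords[i, ], `+`)
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= dims[1L] &
            cand[, 2L] >= 1L & cand[, 2L] <= dims[2L] &
            cand[, 3L] >= 1L & cand[, 3L] <= dims[3L]
      lin <- (cand[ok, , drop = FALSE] - 1L) %*% idx_mult + 1L
      lin <- as.integer(lin)
      inm <- mask_vec[lin]
      lin <- lin[inm]
      d2 <- ofs$d2[ok][inm]
      # drop candidates farther than the covered inscribed ball: they could
      # be beaten by voxels outside the current cube
      safe <- d2 <= r^2
      if (sum(safe) >= n) {
        lin <- lin[safe]
        d2 <- d2[safe]
        ord <- order(d2, lin)[seq_len(n)]
        nb[, i] <- lin[ord]
        break
      }
      r <- r * 2L
      if (r > max(dims) * 2L)
        stop("cannot assemble a ", n, "-voxel neighborhood within the mask")
    }
  }
  structure(list(centers = centers, nb = nb, dims = dims, n_voxels = n),
            class = "searchlight_neighborhoods")
}
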