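# shared fixture builders (all synthetic, generated at test time)

# small geometry: block informative region inside a compact grid
tiny_geometry <- function(model = "B", grid = c(8, 8, 8), block = 3:5,
                          noise_sd = 1, amplitude = 3, ...) {
  mask <- array(FALSE, grid)
  mask[block, block, block] <- TRUE
  representational_geometry(model, grid_shape = grid,
                            informative_mask = mask,
                            signal_amplitude = amplitude,
                            noise_sd = noise_sd, ...)
}

# two well-separated Gaussian clouds for classifier tests
separable_clouds <- function(n_per_class = 20, p = 50, sep = 10, sd = 1) {
  mu <- rnorm(p)
  x <- rbind(matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p),
             matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p) +
               matrix(sep * mu / sqrt(sum(mu^2)), n_per_class, p,
                      byrow = TRUE))
  list(x = x, labels = rep(c("NS", "PS"), each = n_per_class))
}

# training set whose pooled within-class sample covariance is exactly the
# identity (classes whitened around their means)
identity_cov_clouds <- function(n_per_class = 20, p = 5) {
  lab <- rep(c("NS", "PS"), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  means <- list(NS = rnorm(p), PS = rnorm(p))
  for (cl in c("NS", "PS")) {
    rows <- lab == cl
    xc <- scale(x[rows, ], center = TRUE, scale = FALSE)
    x[rows, ] <- xc
  }
  s <- crossprod(x) / (2 * n_per_class - 2)
  x <- x %*% solve(chol(s))
  for (cl in c("NS", "PS")) x[lab == cl, ] <-
      sweep(x[lab == cl, ], 2, means[[cl]], `+`)
  list(x = x, labels = lab, means = means)
}

# independent R oracle for TFCE: explicit threshold loop with igraph
# connected components
tfce_oracle <- function(x, E = 0.5, H = 2, dh = 0.1, connectivity = 26) {
  dims <- dim(x)
  out <- array(0, dims)
  xmax <- max(x)
  if (xmax <= 0) return(out)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  for (k in seq_len(floor(xmax / dh + 1e-9))) {
    h <- k * dh
    keep <- which(as.vector(x) >= h - 1e-12)
    if (!length(keep)) next
    cc <- coords[keep, , drop = FALSE]
    d <- as.matrix(dist(cc, method = "maximum"))
    cheb_adj <- d <= 1 & d > 0
    if (connectivity != 26) {
      man <- as.matrix(dist(cc, method = "manhattan"))
      lim <- if (connectivity == 6) 1 else 2
      cheb_adj <- cheb_adj & man <= lim
    }
    g <- igraph::graph_from_adjacency_matrix(cheb_adj, mode = "undirected")
    comp <- igraph::components(g)
    out[keep] <- out[keep] + comp$csize[comp$membership]^E * h^H * dh
  }
  out
}

# brute-force Anderson-Darling A^2 for composite normality
ad_statistic_oracle <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(pnorm(z)) + log(1 - pnorm(rev(z)))))
}
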