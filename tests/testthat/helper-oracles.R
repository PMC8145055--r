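# Shared helpers: independent brute-force oracles and tiny geometry builders.

# exhaustive O(N*M) nearest-neighbour search, independent of the kd-tree
brute_nn <- function(reference, query) {
  ref <- unclass(reference); qry <- unclass(query)
  idx <- integer(nrow(qry)); dst <- numeric(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    d2 <- rowSums(sweep(ref, 2L, qry[i, ])^2)
    idx[i] <- which.min(d2)
    dst[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dst)
}

random_rotation <- function() {
  ax <- rnorm(3)
  rotation_about_axis(ax, runif(1, 0, 180))
}

# cylinder along +z centred at origin; surface- or volume-sampled
cylinder_cloud <- function(n, length_mm, radius_mm, noise_sd = 0,
                           solid = FALSE) {
  z <- runif(n, -length_mm / 2, length_mm / 2)
  th <- runif(n, 0, 2 * pi)
  r <- if (solid) radius_mm * sqrt(runif(n)) else radius_mm
  m <- cbind(r * cos(th), r * sin(th), z)
  if (noise_sd > 0) m <- m + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  point_cloud(m)
}

unitize <- function(v) v / sqrt(sum(v^2))

zero_migration <- list(proximal = list(axial_mm = 0, tilt_deg = 0),
                       distal = list(axial_mm = 0, tilt_deg = 0))
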