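# Independent Monte-Carlo occlusion oracle for solvent-accessible surface
# area: per atom, sample points uniformly at random on the expanded sphere
# and keep the fraction not occluded by any other expanded sphere. Shares
# no code with the quadrature implementation.

mc_sasa <- function(xyz, radii, probe = 1.4, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(xyz)
  er <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * n_samples), n_samples, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * er[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= er[j]^2
    }
    out[i] <- 4 * pi * er[i]^2 * mean(free)
  }
  out
}

# random compact atom cluster (coordinates in a box, standard radii)
random_cluster <- function(n_atoms, seed, spread = 4) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n_atoms, 0, spread), n_atoms, 3)
  radii <- sample(c(1.52, 1.55, 1.70, 1.80), n_atoms, replace = TRUE)
  list(xyz = xyz, radii = radii)
}
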