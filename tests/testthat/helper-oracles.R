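# Independent oracles used across the suite.

# dense grid scan of the maximum-responsibility component of a 1-D Gaussian
# mixture; returns the intensities where the winning component switches
grid_scan_crossings <- function(weights, means, vars, n_grid = 2e5) {
  lo <- min(means) - 8 * sqrt(max(vars))
  hi <- max(means) + 8 * sqrt(max(vars))
  x <- seq(lo, hi, length.out = n_grid)
  dens <- sapply(seq_along(means), function(k)
    log(weights[k]) + dnorm(x, means[k], sqrt(vars[k]), log = TRUE))
  win <- max.col(dens, ties.method = "last")
  sw <- which(diff(win) != 0)
  (x[sw] + x[sw + 1]) / 2
}

# pixelwise normal-equations least squares: solve (S S^T) a = S y per pixel
normal_equations_unmix <- function(Y, S) {
  G <- S %*% t(S)
  t(apply(Y, 1, function(y) solve(G, S %*% y)))
}

# brute-force per-particle accumulation of channel sums and areas
brute_force_particle_sums <- function(labels, planes) {
  P <- max(labels)
  fl <- dimnames(planes)[[3]]
  out <- matrix(0, P, length(fl), dimnames = list(NULL, fl))
  area <- integer(P)
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    p <- labels[i, j]
    if (p > 0) {
      area[p] <- area[p] + 1L
      for (f in fl) out[p, f] <- out[p, f] + planes[i, j, f]
    }
  }
  list(sums = pmax(out, 0), area = area)
}

# small organelle-preset table for landscape tests
small_organelle_table <- function(n = 1400, seed = 0, gains = c(1, 1.3, 1.8),
                                  ...) {
  sc <- sim_config(n_particles = n, seed = seed,
                   batch_gains = gains, n_batches = length(gains), ...)
  gt <- sample_particles(sc, nonoverlap = FALSE)
  make_feature_matrix(gt, sc)
}

# majority true class per reference cluster (for label-transfer accuracy)
cluster_to_class <- function(cluster, truth) {
  sapply(sort(unique(cluster)), function(c)
    names(which.max(table(truth[cluster == c]))))
}
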