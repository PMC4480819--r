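# Independent brute-force references used to cross-check the package's
# statistics and segmentation code paths. These deliberately avoid the
# functions (and packages) they are checking.

# Exhaustive per-voxel four-way truth table, explicit loop.
ref_partition <- function(maa, sc, env) {
  d <- dim(maa)
  out <- array(NA_integer_, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    m <- maa[i, j, k]
    s <- sc[i, j, k]
    out[i, j, k] <-
      if (m && !s) 1L else if (m && s) 2L else if (!m && s) 3L else if (env[i, j, k]) 4L else 0L
  }
  out
}

# Pearson chi-squared from first principles.
ref_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - e)^2 / e),
       df = (nrow(m) - 1) * (ncol(m) - 1))
}

# Two-group log-rank by direct hypergeometric tabulation over event times.
ref_logrank2 <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (t in times) {
    n1 <- sum(t1 >= t)
    n2 <- sum(t2 >= t)
    n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1)
    d <- d1 + sum(t2 == t & e2 == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(statistic = (O - E)^2 / V, o_minus_e = O - E, var = V)
}

# Empirical survivor function (valid KM reference when nothing is censored).
ref_empirical_surv <- function(times, t) mean(times > t)

# Direct voxel count of a sphere mask on the phantom grid (voxel-centre
# coordinates), independent of the phantom internals.
ref_sphere_voxels <- function(grid_shape, spacing, centre, radius) {
  x <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  n <- 0L
  for (i in seq_along(x)) for (j in seq_along(y)) for (k in seq_along(z)) {
    if ((x[i] - centre[1])^2 + (y[j] - centre[2])^2 + (z[k] - centre[3])^2 <= radius^2)
      n <- n + 1L
  }
  n
}

ref_ellipsoid_voxels <- function(grid_shape, spacing, centre, axes) {
  x <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  n <- 0L
  for (i in seq_along(x)) for (j in seq_along(y)) for (k in seq_along(z)) {
    if (((x[i] - centre[1]) / axes[1])^2 + ((y[j] - centre[2]) / axes[2])^2 +
        ((z[k] - centre[3]) / axes[3])^2 <= 1)
      n <- n + 1L
  }
  n
}
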