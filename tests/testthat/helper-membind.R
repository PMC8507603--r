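# Shared fixtures for the test suite; everything is built in code.

# A tiny non-degenerate neutral body (tetrahedron-like) for integrator tests.
tiny_body <- function(charges = rep(0, 4)) {
  protein_body(
    rbind(c(0, 0, 0.02), c(0.02, 0, 0), c(0, 0.02, 0), c(0, 0, -0.02)),
    charges, rep("core", 4)
  )
}

std_fracs <- c(PC = 0.8, PS = 0.15, PIP2 = 0.05)

# Hand-built trajectory from a sequence of poses (list of list(com, R)).
pose_trajectory <- function(body, bilayer, poses, dt = 1) {
  com <- do.call(rbind, lapply(poses, `[[`, "com"))
  quat <- do.call(rbind, lapply(poses, function(p) {
    if (is.matrix(p$R)) matrix_to_quat(p$R) else p$R
  }))
  trajectory(seq_len(nrow(com)) * dt, com, quat, body, bilayer)
}

# Brute-force minimum bead-lipid distance over all 9 periodic xy images.
min_dist_9_images <- function(bead_xyz, lipid_xy, box, plane_z) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) {
    for (i in seq_len(nrow(bead_xyz))) {
      dx <- lipid_xy[, 1] + sx * box[1] - bead_xyz[i, 1]
      dy <- lipid_xy[, 2] + sy * box[2] - bead_xyz[i, 2]
      dz <- plane_z - bead_xyz[i, 3]
      best <- min(best, min(dx^2 + dy^2 + dz^2))
    }
  }
  sqrt(best)
}

# Draw n i.i.d. samples from density prop. to exp(-u(x)/kt) on a fine grid.
sample_from_potential <- function(u_fun, lo, hi, n, kt, grid_n = 4000) {
  x <- seq(lo, hi, length.out = grid_n)
  p <- exp(-(u_fun(x) - min(u_fun(x))) / kt)
  idx <- sample.int(grid_n, n, replace = TRUE, prob = p)
  x[idx] + stats::runif(n, -1, 1) * (x[2] - x[1]) / 2
}

# Bin-averaged free energy of a potential on WHAM bin centres:
# the estimand of a histogram-based PMF estimator.
bin_average_potential <- function(u_fun, mids, h, kt, sub = 21) {
  vapply(mids, function(m) {
    u <- u_fun(seq(m - h / 2, m + h / 2, length.out = sub))
    u0 <- min(u)
    u0 - kt * log(mean(exp(-(u - u0) / kt)))
  }, numeric(1))
}
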