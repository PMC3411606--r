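# Independent oracles used to cross-check the package's numerics.

# Horn's quaternion method for optimal superposition RMSD: independent of the
# SVD-based Kabsch path it checks.
horn_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lambda)) / nrow(P))
}

# Naive double-loop Gaussian-product KDE evaluated at probe points.
naive_kde2d <- function(x, y, h, px, py) {
  vapply(seq_along(px), function(k) {
    mean(dnorm((px[k] - x) / h[1]) * dnorm((py[k] - y) / h[2])) / (h[1] * h[2])
  }, numeric(1))
}

# Direct-sum radius of gyration.
naive_rg <- function(coords, w) {
  ctr <- c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w)) / sum(w)
  s <- 0
  for (i in seq_len(nrow(coords))) s <- s + w[i] * sum((coords[i, ] - ctr)^2)
  sqrt(s / sum(w))
}

# O(i)..N(i+4) distances measured straight off the coordinates, bypassing the
# package's hydrogen-bond detector.
direct_on_distances <- function(traj) {
  top <- traj$topology
  co <- traj$frames[[1]]
  res <- sort(unique(top$res_id))
  n <- length(res)
  vapply(seq_len(n - 4), function(i) {
    o <- which(top$res_id == res[i] & top$name == "O")[1]
    nn <- which(top$res_id == res[i + 4] & top$name == "N")[1]
    sqrt(sum((co[o, ] - co[nn, ])^2))
  }, numeric(1))
}

random_rigid_motion <- function(coords) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sweep(coords %*% R, 2, runif(3, -20, 20), "+")
}

# Two-peak deterministic reference system for offset checks: quadratic
# spreads whose binned counts are an exact parabola, so interpolated peaks
# recover the stated centers exactly.
offset_test_system <- function(po4_z, helix_z) {
  deterministic_peak_system(tibble::tibble(
    label = c("PO4", "PO4", "HCA"),
    name = c("P", "P", "CA"),
    element = c("P", "P", "C"),
    z_number = c(15L, 15L, 6L),
    center_z = c(po4_z, -po4_z, helix_z)
  ))
}

measure_offset <- function(po4_z, helix_z) {
  sys <- offset_test_system(po4_z, helix_z)
  zr <- c(-30, 30)
  pp <- electron_density_profile(sys, "res_name=PO4", z_range = zr)
  ph <- electron_density_profile(sys, "res_name=HCA", z_range = zr)
  helix_offset(ph, pp, leaflet = "upper")$offset
}
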