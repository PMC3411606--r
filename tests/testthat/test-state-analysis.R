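gauss_cloud <- function(n, mx, my, s = 0.3, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    frame = seq_len(n), rmsd = rnorm(n, mx, s), rg = rnorm(n, my, s)))
}

test_that("the grid density matches a brute-force direct sum", {
  cloud <- gauss_cloud(200, 2, 6, seed = 3)
  kde <- kde2d_features(cloud, grid_size = 64)
  withr::with_seed(5, {
    pi_ <- sample(64, 25, replace = TRUE)
    pj <- sample(64, 25, replace = TRUE)
  })
  ours <- kde$z[cbind(pi_, pj)]
  naive <- naive_kde2d(cloud$rmsd, cloud$rg, kde$bandwidth,
                       kde$x[pi_], kde$y[pj])
  expect_lt(max(abs(ours - naive)), 1e-10)
})

test_that("the density integrates to the kernel mass inside the grid", {
  cloud <- gauss_cloud(40, 1.5, 5.5, seed = 7)
  h <- c(0.5, 0.5)
  kde <- kde2d_features(cloud, bandwidth = h, grid_size = 513)
  # Simpson weights per dimension (odd node count)
  simpson <- function(m) {
    w <- rep(c(2, 4), length.out = m); w[1] <- 1; w[m] <- 1
    w / 3
  }
  wx <- simpson(length(kde$x)) * (kde$x[2] - kde$x[1])
  wy <- simpson(length(kde$y)) * (kde$y[2] - kde$y[1])
  integral <- as.numeric(t(wx) %*% kde$z %*% wy)
  mass_in <- mean(
    (pnorm((max(kde$x) - cloud$rmsd) / h[1]) - pnorm((min(kde$x) - cloud$rmsd) / h[1])) *
      (pnorm((max(kde$y) - cloud$rg) / h[2]) - pnorm((min(kde$y) - cloud$rg) / h[2])))
  expect_lt(abs(integral - mass_in), 1e-6)
  expect_true(all(kde$z >= 0))
})

test_that("bandwidth handling covers rules, fixed values and degenerate input", {
  cloud <- gauss_cloud(100, 2, 6, seed = 1)
  k1 <- kde2d_features(cloud, "scott")
  expect_equal(unname(k1$bandwidth[1]), sd(cloud$rmsd) * 100^(-1 / 6))
  k2 <- kde2d_features(cloud, bandwidth = c(0.2, 0.4))
  expect_equal(unname(k2$bandwidth), c(0.2, 0.4))
  flat <- tibble::tibble(rmsd = rep(1, 50), rg = rnorm(50))
  expect_error(kde2d_features(flat), "fixed")
  expect_silent(kde2d_features(flat, bandwidth = 0.3))
})

test_that("mode detection finds one mode for unimodal data", {
  kde <- kde2d_features(gauss_cloud(2000, 2, 6, seed = 11))
  modes <- find_modes(kde)
  expect_equal(nrow(modes), 1)
  # peak near the true mean (3 SE margin is generous at this n and bandwidth)
  expect_lt(abs(modes$rmsd - 2), 0.1)
  expect_lt(abs(modes$rg - 6), 0.1)
})

test_that("assignment is deterministic, exhaustive and sums to one", {
  cloud <- generate_feature_cloud(mixture_preset("chol_rich", n_samples = 1500, seed = 3))
  m1 <- identify_states(cloud)
  m2 <- identify_states(cloud)
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(length(m1$assignment), 1500)
  expect_false(anyNA(m1$assignment))
  expect_equal(sum(m1$probabilities$probability), 1)
})

test_that("two equal clusters split frames about evenly", {
  comp <- tibble::tibble(weight = c(0.5, 0.5), mean_rmsd = c(1, 5),
                         mean_rg = c(5, 8), sd_rmsd = 0.3, sd_rg = 0.3,
                         correlation = 0)
  n <- 2000
  cloud <- generate_feature_cloud(mixture_spec(comp, n_samples = n, seed = 6))
  model <- identify_states(cloud)
  expect_equal(nrow(model$modes), 2)
  # binomial 4-sigma band around 0.5
  tol <- 4 * sqrt(0.25 / n)
  expect_lt(abs(model$probabilities$probability[1] - 0.5), tol)
})

test_that("frames outside the density grid are clamped, never dropped", {
  cloud <- gauss_cloud(500, 2, 6, seed = 9)
  kde <- kde2d_features(cloud)
  wide <- dplyr::bind_rows(cloud, tibble::tibble(frame = 501, rmsd = 50, rg = 50))
  expect_message(model <- assign_frames(wide, kde), "clamped")
  expect_equal(length(model$assignment), 501)
  expect_equal(model$n_clamped, 1)
})

test_that("state-average structures report the helicity of their state", {
  traj <- generate_helix_trajectory(tibble::tibble(n_break = c(0, 5),
                                                   n_frames = c(20, 20)), seed = 12)
  feats <- compute_features(traj)
  model <- identify_states(feats)
  expect_equal(nrow(model$modes), 2)
  hd <- helix_definition(traj)
  helicities <- sort(vapply(model$modes$state, function(s) {
    state_average_structure(traj, model, s, hd)$helicity$percent_folded
  }, numeric(1)))
  expect_equal(helicities, c(28.57, 100.00))
})

test_that("averaging identical frames returns that frame and ignores member order", {
  helix <- build_ideal_helix(helix_spec())
  co <- frame_coords(helix)
  traj <- trajectory(helix$topology, list(co, co, co))
  feats <- compute_features(traj)
  model <- identify_states(feats, bandwidth = 0.1)
  avg <- state_average_structure(traj, model, 1)
  expect_equal(frame_coords(avg$trajectory), co, tolerance = 1e-10)
  expect_equal(avg$helicity$percent_folded, 100)
  med <- state_average_structure(traj, model, 1, method = "medoid")
  expect_equal(frame_coords(med$trajectory), co, tolerance = 1e-10)
  expect_error(state_average_structure(traj, model, 99), "no member frames")
})
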