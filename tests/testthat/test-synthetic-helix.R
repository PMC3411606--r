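test_that("the ideal helix forms exactly n-4 i->i+4 contacts", {
  # distances measured directly off the coordinates, not via the detector
  d11 <- direct_on_distances(build_ideal_helix(helix_spec()))
  expect_length(d11, 7)
  expect_true(all(d11 <= 3.2))

  d5 <- direct_on_distances(build_ideal_helix(helix_spec("ILFQP")))
  expect_length(d5, 1)
  expect_lte(d5, 3.2)

  stretched <- build_ideal_helix(helix_spec(rise_per_residue = 4.5))
  expect_true(all(direct_on_distances(stretched) > 3.5))

  expect_error(helix_spec("ILFQ"), "at least 5")
})

test_that("helix build is invariant (up to rigid motion) under start_res_id", {
  a <- build_ideal_helix(helix_spec(start_res_id = 817))
  b <- build_ideal_helix(helix_spec(start_res_id = 1))
  fit <- kabsch_superpose(frame_coords(b), frame_coords(a))
  expect_lt(fit$rmsd, 1e-10)
})

test_that("perturb_unfold breaks exactly n_break contacts from either terminus", {
  helix <- build_ideal_helix(helix_spec())
  expect_identical(frame_coords(perturb_unfold(helix, 0)), frame_coords(helix))
  for (mode in c("c_term", "n_term")) {
    for (nb in 0:7) {
      d <- direct_on_distances(perturb_unfold(helix, nb, mode))
      expect_equal(sum(d > 3.5), nb)
      broken <- which(d > 3.5)
      if (nb > 0 && mode == "c_term") expect_equal(broken, (7 - nb + 1):7)
      if (nb > 0 && mode == "n_term") expect_equal(broken, 1:nb)
    }
  }
  expect_error(perturb_unfold(helix, 8), "between 0 and 7")
  expect_error(perturb_unfold(helix, -1), "between 0 and 7")
})

test_that("helicity is monotone non-increasing in n_break", {
  helix <- build_ideal_helix(helix_spec())
  hd <- helix_definition(helix)
  vals <- vapply(0:7, function(nb) {
    helicity_percent(perturb_unfold(helix, nb), hd)$percent_folded
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("trajectory generation is a pure function of (schedule, spec, seed)", {
  sched <- tibble::tibble(n_break = c(0, 4), n_frames = c(5, 5))
  a <- generate_helix_trajectory(sched, seed = 3)
  b <- generate_helix_trajectory(sched, seed = 3)
  expect_identical(a$frames, b$frames)
  c <- generate_helix_trajectory(sched, seed = 4)
  expect_false(identical(a$frames, c$frames))
  expect_equal(n_frames(a), 10)
  expect_equal(attr(a, "n_break"), rep(c(0, 4), each = 5))
  # list-of-pairs schedule form is accepted
  d <- generate_helix_trajectory(list(c(0, 5), c(4, 5)), seed = 3)
  expect_identical(a$frames, d$frames)
})

test_that("jitter and rigid motion never flip hydrogen-bond states", {
  traj <- generate_helix_trajectory(tibble::tibble(n_break = c(0, 2, 5),
                                                   n_frames = c(4, 4, 4)),
                                    seed = 9)
  hd <- helix_definition(traj)
  tr <- helicity_trace(traj, hd)
  expect_equal(tr$n_intact, rep(c(7, 5, 2), each = 4))
})
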