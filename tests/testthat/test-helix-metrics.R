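test_that("helicity lives on the k/7 lattice and matches printed precision", {
  helix <- build_ideal_helix(helix_spec())
  hd <- helix_definition(helix)
  lattice <- round(100 * (0:7) / 7, 2)
  for (nb in 0:7) {
    h <- helicity_percent(perturb_unfold(helix, nb), hd)
    expect_equal(h$reference_count, 7)
    expect_true(h$percent_folded %in% lattice)
    expect_equal(nrow(h$intact), 7 - nb)
  }
  expect_equal(helicity_percent(perturb_unfold(helix, 2), hd)$percent_folded, 71.43)
  expect_equal(helicity_percent(perturb_unfold(helix, 4), hd)$percent_folded, 42.86)
})

test_that("missing backbone atoms are reported by residue", {
  helix <- build_ideal_helix(helix_spec())
  hd <- helix_definition(helix)
  keep <- !(helix$topology$res_id == 820 & helix$topology$name == "O")
  maimed <- trajectory(
    dplyr::mutate(helix$topology[keep, ], index = dplyr::row_number() - 1L),
    list(frame_coords(helix)[keep, ]))
  expect_error(detect_backbone_hbonds(maimed, hd), "820")
})

test_that("radius of gyration has its closed forms and matches a direct sum", {
  two <- trajectory(
    tibble::tibble(index = 0:1, name = "X", res_name = "XXX", res_id = 1:2,
                   chain = "A", element = "C", z_number = 6L,
                   partial_charge = 0, mass = 12.011),
    list(matrix(c(0, 0, 0, 6, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(radius_of_gyration(two), 3)          # two equal masses 2a apart -> a
  coincident <- trajectory(two$topology, list(matrix(1, 2, 3)))
  expect_equal(radius_of_gyration(coincident), 0)

  helix <- build_ideal_helix(helix_spec())
  idx <- select_atoms(helix$topology, "name=CA")
  for (mw in c(TRUE, FALSE)) {
    w <- if (mw) helix$topology$mass[idx] else rep(1, length(idx))
    expect_equal(radius_of_gyration(helix, idx, mass_weighted = mw),
                 naive_rg(frame_coords(helix)[idx, ], w), tolerance = 1e-10)
  }
  expect_error(radius_of_gyration(helix, idx[1]), "at least 2")
})

test_that("RMSD and Rg are invariant under global rigid motion", {
  helix <- build_ideal_helix(helix_spec())
  co <- frame_coords(helix)
  withr::with_seed(21, {
    for (k in 1:20) {
      moved <- trajectory(helix$topology, list(random_rigid_motion(co)))
      expect_lt(kabsch_superpose(frame_coords(moved), co)$rmsd, 1e-8)
      expect_equal(radius_of_gyration(moved), radius_of_gyration(helix),
                   tolerance = 1e-8)
    }
  })
})

test_that("compute_features records one (rmsd, rg) pair per frame", {
  helix <- build_ideal_helix(helix_spec())
  co <- frame_coords(helix)
  frames <- withr::with_seed(13, lapply(1:6, function(i) random_rigid_motion(co)))
  rigid <- trajectory(helix$topology, c(list(co), frames))
  f <- compute_features(rigid)
  expect_equal(nrow(f), 7)
  expect_true(all(f$rmsd < 1e-8))
  expect_equal(sd(f$rg), 0, tolerance = 1e-8)

  single <- compute_features(helix)
  expect_equal(nrow(single), 1)
  expect_equal(single$rmsd, 0)
})

test_that("a folded/unfolded schedule separates cleanly in feature space", {
  traj <- generate_helix_trajectory(tibble::tibble(n_break = c(0, 4),
                                                   n_frames = c(25, 25)), seed = 2)
  f <- compute_features(traj)
  folded <- f$rmsd[1:25]; unfolded <- f$rmsd[26:50]
  # the two blocks are far apart relative to their spreads
  expect_gt(mean(unfolded) - mean(folded),
            5 * (sd(folded) + sd(unfolded)))
  expect_gt(min(unfolded), max(folded))
})

test_that("the two hydrophobic-face assignments are both available", {
  hd_main <- helix_definition(res_id_range = c(817, 827))
  expect_setequal(hd_main$hydrophobic_face, c(821, 822, 824, 825, 826, 828, 829))
  hd_alt <- helix_definition(res_id_range = c(817, 827), hydrophobic_face = "alt")
  expect_setequal(hd_alt$hydrophobic_face, c(821, 823, 824, 825, 826, 829, 830))
})
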