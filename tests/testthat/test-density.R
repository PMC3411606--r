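single_atom_traj <- function(z = 0.5, z_number = 8L, q = 0) {
  trajectory(
    tibble::tibble(index = 0L, name = "O", res_name = "WAT", res_id = 1L,
                   chain = "A", element = "O", z_number = z_number,
                   partial_charge = q, mass = 15.999),
    list(matrix(c(1, 1, z), 1, 3)), box = c(10, 10, 10))
}

test_that("one atom contributes Z - q electrons to its slab", {
  tr <- single_atom_traj(z = 0.5, z_number = 8L, q = 0)
  prof <- electron_density_profile(tr, 1, z_range = c(-2, 2))
  expect_equal(sum(prof$density > 0), 1)
  expect_equal(max(prof$density), 8 / (100 * 1))
  expect_equal(prof$z_center[which.max(prof$density)], 0.5)

  charged <- single_atom_traj(z = 0.5, z_number = 15L, q = 1.5)
  p_sub <- electron_density_profile(charged, 1, z_range = c(-2, 2))
  expect_equal(max(p_sub$density) * 100, 13.5)
  p_add <- electron_density_profile(charged, 1, z_range = c(-2, 2),
                                    electron_mode = "add")
  expect_equal(max(p_add$density) * 100, 16.5)
})

test_that("slab sums conserve the selection's total electron count exactly", {
  bil <- generate_bilayer(bilayer_preset("chol_rich", atoms_per_leaflet = 400), 5)
  idx <- select_atoms(bil$topology, "res_name=PO4")
  prof <- electron_density_profile(bil, "res_name=PO4")
  per_frame <- attr(prof, "per_frame")
  area <- attr(prof, "area")
  expected <- sum(bil$topology$z_number[idx] - bil$topology$partial_charge[idx])
  for (f in seq_len(ncol(per_frame))) {
    expect_equal(sum(per_frame[, f]) * area * 1, expected, tolerance = 1e-12)
  }
  expect_equal(sum(prof$density) * area, expected, tolerance = 1e-12)
})

test_that("profiles are symmetric for mirror bilayers and equivariant under z shifts", {
  bil <- generate_bilayer(bilayer_preset("chol_rich", atoms_per_leaflet = 3000), 10)
  prof <- electron_density_profile(bil, "res_name=PO4", z_range = c(-30, 30))
  peaks <- leaflet_peaks(prof)
  expect_lt(abs(peaks[["upper"]] + peaks[["lower"]]), 3 * 0.1)

  shifted <- trajectory(bil$topology,
                        lapply(bil$frames, function(f) {
                          f[, 3] <- f[, 3] + 5; f
                        }), box = bil$box)
  prof_s <- electron_density_profile(shifted, "res_name=PO4", z_range = c(-25, 35))
  peaks_s <- leaflet_peaks(prof_s)
  expect_equal(unname(peaks_s - peaks), c(5, 5), tolerance = 0.05)
})

test_that("interpolated peaks are stable when the slab width is halved", {
  bil <- generate_bilayer(bilayer_preset("chol_rich"), 10)
  p1 <- peak_to_peak(electron_density_profile(bil, "res_name=PO4", slab_width = 1))
  p05 <- peak_to_peak(electron_density_profile(bil, "res_name=PO4", slab_width = 0.5))
  expect_lt(abs(p1$distance - p05$distance), 2 * 0.1)
})

test_that("Gaussian leaflet peaks are recovered with sub-slab bias", {
  spec <- bilayer_spec(tibble::tibble(
    label = "PO4", name = "P", element = "P", atoms_per_leaflet = 5000,
    leaflet_mean_z = 20, leaflet_sd_z = 2, z_number = 15L,
    partial_charge = 0, mass = 30.974), seed = 31)
  bil <- generate_bilayer(spec, 10)
  peaks <- leaflet_peaks(electron_density_profile(bil, "name=P"))
  expect_lt(abs(peaks[["upper"]] - 20), 0.2)
  expect_lt(abs(peaks[["lower"]] + 20), 0.2)
})

test_that("degenerate profiles and selections are rejected", {
  tr <- single_atom_traj()
  expect_error(electron_density_profile(tr, "name=ZZ"), "[Ee]mpty")
  noboxtr <- trajectory(tr$topology, tr$frames)
  expect_error(electron_density_profile(noboxtr, 1), "area")
  expect_silent(electron_density_profile(noboxtr, 1, area = 50))

  mono <- tibble::tibble(z_center = seq(-5, 5), density = seq(0, 10))
  expect_error(leaflet_peaks(mono), "monotone")
  onesided <- tibble::tibble(z_center = seq(-5.5, 5.5),
                             density = c(rep(0, 6), 1, 3, 1, 0.5, 0.2, 0))
  expect_error(leaflet_peaks(onesided), "one side")
})

test_that("offset sign convention: negative means buried toward the bilayer center", {
  expect_equal(measure_offset(21.9, 21.9), 0, tolerance = 1e-9)
  expect_equal(measure_offset(21.9, 20.3), -1.6, tolerance = 1e-9)
  expect_equal(measure_offset(20.68, 22.41), 1.73, tolerance = 1e-9)
  # lower leaflet: same convention
  sys <- deterministic_peak_system(tibble::tibble(
    label = c("PO4", "PO4", "HCA"), name = c("P", "P", "CA"),
    element = c("P", "P", "C"), z_number = c(15L, 15L, 6L),
    center_z = c(21.9, -21.9, -20.3)))
  pp <- electron_density_profile(sys, "res_name=PO4", z_range = c(-30, 30))
  ph <- electron_density_profile(sys, "res_name=HCA", z_range = c(-30, 30))
  expect_equal(helix_offset(ph, pp, "lower")$offset, -1.6, tolerance = 1e-9)
  expect_error(helix_offset(ph, pp, "upper"), "leaflet")
})

test_that("offset requires a shared slab grid", {
  sys <- offset_test_system(21.9, 20.3)
  pp <- electron_density_profile(sys, "res_name=PO4", z_range = c(-30, 30))
  ph <- electron_density_profile(sys, "res_name=HCA", z_range = c(-28, 30))
  expect_error(helix_offset(ph, pp), "share")
})
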