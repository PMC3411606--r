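pdb_line <- function(serial, name, res, resid, x, y, z, elem) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, sprintf(" %-3s", name), res, resid, x, y, z, elem)
}

test_that("single-model and multi-model PDB files parse with correct shapes", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", 1, 1.0, 2.0, 3.0, "N"),
    pdb_line(2, "CA", "ALA", 1, 2.5, 2.0, 3.0, "C"),
    pdb_line(3, "C", "ALA", 1, 3.0, 3.5, 3.0, "C"),
    "END"), f)
  tr <- read_multi_model_pdb(f)
  expect_equal(n_frames(tr), 1)
  expect_equal(n_atoms(tr), 3)
  expect_equal(frame_coords(tr)[2, ], c(2.5, 2.0, 3.0))
  expect_equal(tr$topology$z_number, c(7L, 6L, 6L))

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line(1, "CA", "GLY", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "GLY", 2, 1, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "GLY", 1, 0, 0, 1, "C"),
    pdb_line(2, "CA", "GLY", 2, 1, 0, 1, "C"),
    "ENDMDL", "END"), f2)
  tr2 <- read_multi_model_pdb(f2)
  expect_equal(n_frames(tr2), 2)
  expect_equal(frame_coords(tr2, 2)[, 3], c(1, 1))
})

test_that("a model with a missing atom is rejected naming the model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line(1, "CA", "GLY", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "GLY", 2, 1, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "GLY", 1, 0, 0, 1, "C"),
    "ENDMDL", "END"), f)
  expect_error(read_multi_model_pdb(f), "model 2")

  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_multi_model_pdb(empty), "[Ee]mpty")
})

test_that("write/read round trip preserves order and coordinates to 0.001 A", {
  traj <- generate_helix_trajectory(tibble::tibble(n_break = c(0, 3),
                                                   n_frames = c(2, 2)), seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multi_model_pdb(traj, f)
  back <- read_multi_model_pdb(f)
  expect_equal(n_frames(back), 4)
  expect_equal(back$topology$name, traj$topology$name)
  expect_equal(back$topology$res_id, traj$topology$res_id)
  for (k in seq_len(4)) {
    expect_lt(max(abs(frame_coords(back, k) - frame_coords(traj, k))), 5e-4 + 1e-9)
  }
})

test_that("written PDB agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  traj <- build_ideal_helix(helix_spec())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multi_model_pdb(traj, f)
  ref <- bio3d::read.pdb(f)
  xyz <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(xyz - frame_coords(traj))), 5e-4 + 1e-9)
  expect_equal(ref$atom$resid[1:4], rep("ILE", 4))
})

test_that("topology tables read with validation and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("index,name,res_name,res_id,chain,element,z_number,partial_charge,mass",
               "0,P,SDP,1,M,P,15,1.5,30.97"), f)
  top <- read_topology_table(f)
  expect_equal(top$z_number, 15L)
  expect_equal(top$partial_charge, 1.5)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("index,name,res_name,res_id,chain,element,partial_charge,mass",
               "0,P,SDP,1,M,P,1.5,30.97"), f2)
  expect_error(read_topology_table(f2), "z_number")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("index,name,res_name,res_id,chain,element,z_number,partial_charge,mass", f3)
  expect_error(read_topology_table(f3), "[Ee]mpty")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("index,name,res_name,res_id,chain,element,z_number,partial_charge,mass",
               "0,P,SDP,1,M,P,15,1.5,30.97",
               "1,P,SDP,2,M,P,xx,1.5,30.97"), f4)
  expect_error(read_topology_table(f4), "row.*2")

  top5 <- build_ideal_helix(helix_spec())$topology
  f5 <- withr::local_tempfile(fileext = ".tsv")
  write_topology_table(top5, f5)
  expect_equal(read_topology_table(f5), top5)
})
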