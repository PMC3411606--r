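# Per-frame observables: backbone hydrogen-bond helicity, superposed RMSD
# from a reference structure, and radius of gyration.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Define the helical segment under analysis
#'
#' Freezes the residue range, the reference i to i+4 hydrogen-bond pairs and
#' the hydrophobic-face residue set. By default the reference bonds are all
#' i to i+4 pairs inside the range — the bond set of a fully formed helix —
#' so an n-residue segment has n-4 reference bonds and helicity percentages
#' live on the lattice k/(n-4).
#'
#' The default hydrophobic face is `{821, 822, 824, 825, 826, 828, 829}`
#' (Q821, K822, V824, V825, S826, R828, A829). An alternative assignment of
#' the same face, `{821, 823, 824, 825, 826, 829, 830}`, circulates for this
#' segment; pass `hydrophobic_face = "alt"` to use it.
#'
#' @param x A [trajectory()] whose topology covers the helix (used to infer
#'   the residue range), or `NULL` if `res_id_range` is given.
#' @param res_id_range Inclusive `c(first, last)` residue ids.
#' @param reference_bonds Optional tibble with columns `acceptor_res` (residue
#'   i, backbone O) and `donor_res` (residue i+4, backbone N).
#' @param hydrophobic_face Residue-id vector, or `"main"` / `"alt"` for the
#'   two published assignments.
#' @return A `helix_definition` list.
#' @export
helix_definition <- function(x = NULL, res_id_range = NULL,
                             reference_bonds = NULL,
                             hydrophobic_face = "main") {
  if (is.null(res_id_range)) {
    if (is.null(x)) abort("Give a trajectory or an explicit `res_id_range`")
    res_id_range <- range(x$topology$res_id)
  }
  res_id_range <- as.integer(res_id_range)
  if (length(res_id_range) != 2 || diff(res_id_range) < 4) {
    abort("`res_id_range` must span at least 5 residues")
  }
  if (is.null(reference_bonds)) {
    first <- res_id_range[1]; last <- res_id_range[2]
    acceptor <- seq(first, last - 4L)
    reference_bonds <- tibble(acceptor_res = acceptor, donor_res = acceptor + 4L)
  }
  reference_bonds <- as_tibble(reference_bonds)
  if (nrow(reference_bonds) == 0) abort("`reference_bonds` must be non-empty")
  if (any(reference_bonds$acceptor_res < res_id_range[1]) ||
      any(reference_bonds$donor_res > res_id_range[2])) {
    abort("Reference bonds must lie inside `res_id_range`")
  }
  if (identical(hydrophobic_face, "main")) {
    hydrophobic_face <- c(821L, 822L, 824L, 825L, 826L, 828L, 829L)
  } else if (identical(hydrophobic_face, "alt")) {
    hydrophobic_face <- c(821L, 823L, 824L, 825L, 826L, 829L, 830L)
  }
  structure(
    list(res_id_range = res_id_range, reference_bonds = reference_bonds,
         hydrophobic_face = as.integer(hydrophobic_face)),
    class = "helix_definition"
  )
}

#' Hydrogen-bond detection criterion
#'
#' The default is a hydrogen-free heavy-atom criterion: a reference bond is
#' intact when the backbone O(i)..N(i+4) distance is at most `max_on_distance`
#' (3.5 A, the conventional heavy-atom hydrogen-bond cutoff). When topologies
#' carry amide hydrogens, `require_hydrogen = TRUE` additionally demands an
#' N-H..O angle of at least `min_nho_angle` degrees.
#'
#' @param max_on_distance Heavy-atom O..N cutoff in Angstrom.
#' @param require_hydrogen Also check the N-H..O angle (needs H atoms named
#'   `H` or `HN` on the donor residue).
#' @param min_nho_angle Minimum N-H..O angle in degrees.
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(max_on_distance = 3.5, require_hydrogen = FALSE,
                            min_nho_angle = 120) {
  if (max_on_distance <= 0) abort("`max_on_distance` must be positive")
  structure(list(max_on_distance = max_on_distance,
                 require_hydrogen = require_hydrogen,
                 min_nho_angle = min_nho_angle),
            class = "hbond_criterion")
}

backbone_atom_row <- function(topology, res, name) {
  hit <- which(topology$res_id == res & topology$name == name)
  if (length(hit) == 0) {
    abort(paste0("Residue ", res, " lacks a backbone `", name, "` atom"))
  }
  hit[1]
}

#' Detect intact reference backbone hydrogen bonds in a frame
#'
#' @param x A [trajectory()].
#' @param helixdef A [helix_definition()].
#' @param criterion An [hbond_criterion()].
#' @param frame Frame number.
#' @return A tibble of the intact reference pairs with columns `acceptor_res`,
#'   `donor_res`, `distance`.
#' @export
detect_backbone_hbonds <- function(x, helixdef = helix_definition(x),
                                   criterion = hbond_criterion(), frame = 1) {
  stopifnot(inherits(x, "trajectory"), inherits(helixdef, "helix_definition"))
  co <- frame_coords(x, frame)
  top <- x$topology
  bonds <- helixdef$reference_bonds
  o_rows <- map_int(bonds$acceptor_res, ~ backbone_atom_row(top, .x, "O"))
  n_rows <- map_int(bonds$donor_res, ~ backbone_atom_row(top, .x, "N"))
  d <- sqrt(rowSums((co[o_rows, , drop = FALSE] - co[n_rows, , drop = FALSE])^2))
  intact <- d <= criterion$max_on_distance
  if (criterion$require_hydrogen) {
    for (k in which(intact)) {
      h <- which(top$res_id == bonds$donor_res[k] & top$name %in% c("H", "HN"))
      if (length(h) == 0) {
        abort(paste0("Residue ", bonds$donor_res[k],
                     " has no amide hydrogen but `require_hydrogen` is TRUE"))
      }
      v1 <- co[n_rows[k], ] - co[h[1], ]
      v2 <- co[o_rows[k], ] - co[h[1], ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < criterion$min_nho_angle) intact[k] <- FALSE
    }
  }
  mutate(bonds[intact, ], distance = d[intact])
}

#' Helicity as the percentage of intact reference hydrogen bonds
#'
#' The helicity of a conformation is `100 * intact / reference` where
#' `reference` counts the i to i+4 backbone hydrogen bonds of the fully
#' folded helix. For an 11-residue segment (7 reference bonds) the metric
#' can only take the values 0, 14.29, 28.57, 42.86, 57.14, 71.43, 85.71,
#' 100. Percentages are reported rounded half-up to 2 decimals.
#'
#' @inheritParams detect_backbone_hbonds
#' @return A `helicity_result` with fields `percent_folded`, `intact`
#'   (tibble of intact pairs), `reference_count`.
#' @export
helicity_percent <- function(x, helixdef = helix_definition(x),
                             criterion = hbond_criterion(), frame = 1) {
  intact <- detect_backbone_hbonds(x, helixdef, criterion, frame)
  ref <- nrow(helixdef$reference_bonds)
  structure(
    list(percent_folded = round_half_up(100 * nrow(intact) / ref, 2),
         intact = intact, reference_count = ref),
    class = "helicity_result"
  )
}

#' @export
print.helicity_result <- function(x, ...) {
  cat(sprintf("<helicity> %.2f%% folded (%d/%d reference H-bonds intact)\n",
              x$percent_folded, nrow(x$intact), x$reference_count))
  invisible(x)
}

#' Per-frame helicity trace over a trajectory
#'
#' @inheritParams detect_backbone_hbonds
#' @return A tibble with columns `frame`, `percent_folded`, `n_intact`,
#'   `reference_count`.
#' @export
helicity_trace <- function(x, helixdef = helix_definition(x),
                           criterion = hbond_criterion()) {
  res <- map(seq_len(n_frames(x)), function(f) {
    h <- helicity_percent(x, helixdef, criterion, frame = f)
    tibble(frame = f, percent_folded = h$percent_folded,
           n_intact = nrow(h$intact), reference_count = h$reference_count)
  })
  list_rbind(res)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between the
#' `subset` rows of `mobile` and `reference`, via singular value
#' decomposition of the cross-covariance matrix with the usual determinant
#' correction so reflections are never returned.
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param subset Optional row indices used to fit (and report the RMSD over);
#'   default all rows. At least 3 non-collinear points are required.
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom over the subset), and `aligned` (all of `mobile`
#'   transformed by row-vector convention `x %*% rotation + translation`).
#' @export
kabsch_superpose <- function(mobile, reference, subset = NULL) {
  if (!is.matrix(mobile) || !is.matrix(reference) ||
      ncol(mobile) != 3 || ncol(reference) != 3 ||
      nrow(mobile) != nrow(reference)) {
    abort("`mobile` and `reference` must be N x 3 matrices of equal size")
  }
  subset <- subset %||% seq_len(nrow(mobile))
  if (length(subset) < 3) abort("Superposition needs at least 3 atoms")
  P <- mobile[subset, , drop = FALSE]
  Q <- reference[subset, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P <- sweep(P, 2, cp); Q <- sweep(Q, 2, cq)
  sv_check <- svd(P)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1e-12)) {
    abort("Degenerate (collinear or coincident) atom subset; cannot superpose")
  }
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(sum((P %*% rot - Q)^2) / length(subset))
  translation <- cq - as.numeric(cp %*% rot)
  list(rotation = rot, translation = translation, rmsd = rmsd,
       aligned = sweep(mobile %*% rot, 2, translation, "+"))
}

#' Radius of gyration of an atom subset
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with `w_i` the atomic mass
#' (default) or 1, and `rbar` the w-weighted centroid.
#'
#' @param x A [trajectory()].
#' @param selection Selection expression or row indices; default all atoms.
#' @param mass_weighted Weight by atomic mass (default) or uniformly.
#' @param frame Frame number.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x, selection = NULL, mass_weighted = TRUE,
                               frame = 1) {
  stopifnot(inherits(x, "trajectory"))
  idx <- if (is.null(selection)) seq_len(n_atoms(x)) else
    resolve_selection(x$topology, selection)
  if (length(idx) < 2) abort("Radius of gyration needs at least 2 atoms")
  co <- frame_coords(x, frame)[idx, , drop = FALSE]
  w <- if (mass_weighted) x$topology$mass[idx] else rep(1, length(idx))
  ctr <- colSums(co * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(co, 2, ctr)^2)) / sum(w))
}

helix_backbone_rows <- function(topology, helixdef) {
  which(topology$res_id >= helixdef$res_id_range[1] &
          topology$res_id <= helixdef$res_id_range[2] &
          topology$name %in% c("N", "CA", "C", "O"))
}

helix_heavy_rows <- function(topology, helixdef) {
  which(topology$res_id >= helixdef$res_id_range[1] &
          topology$res_id <= helixdef$res_id_range[2] &
          topology$element != "H")
}

#' Per-frame (RMSD, Rg) features of the helix
#'
#' For every frame, the helix backbone (N, CA, C, O of the helix residues) is
#' superposed on the same atoms of the reference frame and the RMSD recorded
#' over that atom set; the radius of gyration is computed over the helix heavy
#' atoms. This is the two-dimensional feature space in which conformational
#' states are detected.
#'
#' @param x A [trajectory()].
#' @param helixdef A [helix_definition()].
#' @param reference_frame Frame number of the reference structure, or an
#'   external single-frame [trajectory()] sharing the topology.
#' @param mass_weighted Passed to [radius_of_gyration()].
#' @return A tibble with columns `frame`, `rmsd`, `rg` (Angstrom).
#' @export
compute_features <- function(x, helixdef = helix_definition(x),
                             reference_frame = 1, mass_weighted = TRUE) {
  stopifnot(inherits(x, "trajectory"))
  bb <- helix_backbone_rows(x$topology, helixdef)
  if (length(bb) < 3) abort("Helix backbone atoms not found in topology")
  heavy <- helix_heavy_rows(x$topology, helixdef)
  ref <- if (inherits(reference_frame, "trajectory")) {
    if (nrow(reference_frame$topology) != n_atoms(x)) {
      abort("Reference trajectory does not share the topology")
    }
    frame_coords(reference_frame, 1)
  } else {
    frame_coords(x, reference_frame)
  }
  out <- map(seq_len(n_frames(x)), function(f) {
    co <- frame_coords(x, f)
    fit <- kabsch_superpose(co, ref, subset = bb)
    tibble(frame = f, rmsd = fit$rmsd,
           rg = radius_of_gyration(x, heavy, mass_weighted, frame = f))
  })
  out <- list_rbind(out)
  attr(out, "res_id_range") <- helixdef$res_id_range
  out
}
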