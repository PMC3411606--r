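# Synthetic helix conformers with a controlled number of intact backbone
# hydrogen bonds. These stand in for MD trajectories of an amphipathic
# interfacial helix: geometry is idealized (heavy backbone atoms only), but
# the observables computed downstream — O(i)..N(i+4) distances, RMSD, radius
# of gyration — behave as they do on real unfolding events.

AA_3LETTER <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN", E = "GLU",
  G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS", M = "MET", F = "PHE",
  P = "PRO", S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Cylindrical offsets of backbone atoms relative to the C-alpha lattice of an
# ideal alpha helix (radius 2.3 A, rise 1.5 A, twist 100 degrees). Fitted once
# so that covalent bond lengths are standard (N-CA 1.46, CA-C 1.52, C-O 1.23,
# C-N' 1.33 A) and every O(i)..N(i+4) distance comes out at 2.90 A.
BACKBONE_OFFSETS <- list(
  N  = c(r = 1.635, dphi = -0.447, dz = -0.974),
  CA = c(r = 2.300, dphi =  0.000, dz =  0.000),
  C  = c(r = 1.639, dphi =  0.509, dz =  0.957),
  O  = c(r = 1.370, dphi =  0.468, dz =  2.156)
)

#' Specification of a synthetic alpha-helical segment
#'
#' Defaults describe the 11-residue helical core (residues 817-827,
#' `ILFQPQKNVVS`) of the helix-8 segment of the metabotropic glutamate
#' receptor 2, the system this package was built around. Any sequence of at
#' least 5 residues (the minimum for one i to i+4 hydrogen bond) is accepted.
#'
#' @param sequence One-letter residue sequence.
#' @param rise_per_residue Axial rise in Angstrom (1.5 for an alpha helix).
#' @param twist_per_residue Rotation per residue in degrees (100 for an alpha
#'   helix).
#' @param ca_radius Radius of the C-alpha cylinder in Angstrom.
#' @param start_res_id Residue id of the first residue.
#' @return A `helix_spec` list.
#' @export
helix_spec <- function(sequence = "ILFQPQKNVVS", rise_per_residue = 1.5,
                       twist_per_residue = 100, ca_radius = 2.3,
                       start_res_id = 817L) {
  residues <- strsplit(toupper(sequence), "")[[1]]
  if (length(residues) < 5) {
    abort("Helix sequence must have at least 5 residues for one i->i+4 bond")
  }
  if (!all(residues %in% names(AA_3LETTER))) {
    abort(paste0("Unknown residue letter(s): ",
                 paste(setdiff(residues, names(AA_3LETTER)), collapse = ", ")))
  }
  structure(
    list(sequence = residues, rise_per_residue = rise_per_residue,
         twist_per_residue = twist_per_residue, ca_radius = ca_radius,
         start_res_id = as.integer(start_res_id)),
    class = "helix_spec"
  )
}

#' Build an ideal alpha-helical conformer
#'
#' Backbone heavy atoms (N, CA, C, O) are placed on the helix cylinder: the
#' C-alpha of residue i sits at angle `i * twist` and height `i * rise`, and
#' N, C, O at fixed cylindrical offsets fitted to standard covalent geometry
#' (see the package source for the constants). At the default alpha-helical
#' parameters every O(i)..N(i+4) distance is 2.90 A, i.e. all n-4 reference
#' hydrogen bonds are formed. The topology carries element-correct atomic
#' numbers and zero partial charges.
#'
#' @param spec A [helix_spec()].
#' @return A single-frame [trajectory()].
#' @examples
#' helix <- build_ideal_helix(helix_spec())
#' helicity_percent(helix, helix_definition(helix))
#' @export
build_ideal_helix <- function(spec = helix_spec()) {
  stopifnot(inherits(spec, "helix_spec"))
  nres <- length(spec$sequence)
  twist <- spec$twist_per_residue * pi / 180
  atom_names <- c("N", "CA", "C", "O")
  elements <- c("N", "C", "C", "O")

  rows <- vector("list", nres)
  coords <- matrix(0, nres * 4, 3)
  for (i in seq_len(nres)) {
    for (a in seq_along(atom_names)) {
      off <- BACKBONE_OFFSETS[[atom_names[a]]]
      r <- if (atom_names[a] == "CA") spec$ca_radius else off[["r"]]
      phi <- (i - 1) * twist + off[["dphi"]]
      coords[(i - 1) * 4 + a, ] <- c(
        r * cos(phi), r * sin(phi),
        (i - 1) * spec$rise_per_residue + off[["dz"]]
      )
    }
    rows[[i]] <- tibble(
      name = atom_names,
      res_name = AA_3LETTER[[spec$sequence[i]]],
      res_id = spec$start_res_id + i - 1L,
      chain = "A", element = elements
    )
  }
  top <- bind_rows(rows)
  props <- element_properties(top$element)
  top <- mutate(top,
                index = row_number() - 1L,
                z_number = props$z_number,
                partial_charge = 0,
                mass = props$mass)
  trajectory(top[, TOPOLOGY_COLUMNS], list(coords))
}

n_reference_bonds <- function(spec) length(spec$sequence) - 4L

#' Break a chosen number of backbone hydrogen bonds
#'
#' Deterministically extends the backbone from one terminus so that exactly
#' `n_break` of the n-4 reference O(i)..N(i+4) contacts exceed the hydrogen-
#' bond cutoff while all remaining contacts are untouched. Residues beyond the
#' pivot are translated along the helix axis by an extra 2.5 A per residue,
#' mimicking terminal fraying toward an extended conformation; the margin is
#' large enough that the default 3.5 A criterion classifies bonds unambiguously
#' even after coordinate jitter.
#'
#' @param helix A single-frame [trajectory()] from [build_ideal_helix()].
#' @param n_break Number of bonds to break, `0..(n_residues - 4)`.
#' @param mode `"c_term"` (default) frays the C-terminus, `"n_term"` the
#'   N-terminus.
#' @return A single-frame [trajectory()] with the same topology.
#' @export
perturb_unfold <- function(helix, n_break, mode = c("c_term", "n_term")) {
  stopifnot(inherits(helix, "trajectory"))
  mode <- match.arg(mode)
  res_ids <- unique(helix$topology$res_id)
  nres <- length(res_ids)
  nbonds <- nres - 4L
  if (n_break < 0 || n_break > nbonds) {
    abort(paste0("`n_break` must be between 0 and ", nbonds,
                 " for a ", nres, "-residue helix"))
  }
  coords <- frame_coords(helix, 1)
  if (n_break > 0) {
    res_pos <- match(helix$topology$res_id, res_ids) # 1..nres per atom
    if (mode == "c_term") {
      pivot <- nres - n_break
      shift <- pmax(res_pos - pivot, 0) * 2.5
    } else {
      shift <- -pmax(n_break + 1 - res_pos, 0) * 2.5
    }
    coords[, 3] <- coords[, 3] + shift
  }
  trajectory(helix$topology, list(coords), box = helix$box)
}

random_rotation_matrix <- function() {
  # uniform over SO(3) via normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic helix trajectory from an unfolding schedule
#'
#' Concatenates blocks of frames, each block at a fixed number of broken
#' reference bonds. Every frame receives small Gaussian coordinate jitter and
#' an independent random rigid-body rotation and translation, so downstream
#' superposition is exercised while hydrogen-bond states never flip (the
#' default jitter is far below the cutoff margin).
#'
#' @param schedule A data frame (or tibble) with columns `n_break` and
#'   `n_frames`, one row per block; also accepts a list of `c(n_break,
#'   n_frames)` pairs.
#' @param spec A [helix_spec()].
#' @param seed Integer seed; the whole trajectory is a pure function of
#'   `(schedule, spec, seed)`.
#' @param jitter_sd Per-coordinate Gaussian jitter in Angstrom.
#' @param mode Terminus passed to [perturb_unfold()].
#' @return A [trajectory()] with `sum(n_frames)` frames. The generating
#'   `n_break` of each frame is kept in `attr(, "n_break")`.
#' @examples
#' traj <- generate_helix_trajectory(
#'   tibble::tibble(n_break = c(0, 4), n_frames = c(30, 30)), seed = 1)
#' @export
generate_helix_trajectory <- function(schedule, spec = helix_spec(), seed = 1,
                                      jitter_sd = 0.05,
                                      mode = c("c_term", "n_term")) {
  mode <- match.arg(mode)
  if (is.list(schedule) && !is.data.frame(schedule)) {
    schedule <- tibble(n_break = map_int(schedule, ~ as.integer(.x[1])),
                       n_frames = map_int(schedule, ~ as.integer(.x[2])))
  }
  schedule <- as_tibble(schedule)
  if (nrow(schedule) == 0) abort("Unfolding schedule must be non-empty")
  if (!all(c("n_break", "n_frames") %in% names(schedule))) {
    abort("Schedule needs columns `n_break` and `n_frames`")
  }
  if (any(schedule$n_frames < 1)) abort("Each schedule block needs n_frames >= 1")

  base <- build_ideal_helix(spec)
  frames <- vector("list", sum(schedule$n_frames))
  n_break_of <- integer(0)
  withr::with_seed(seed, {
    k <- 0
    for (b in seq_len(nrow(schedule))) {
      conf <- frame_coords(perturb_unfold(base, schedule$n_break[b], mode), 1)
      for (f in seq_len(schedule$n_frames[b])) {
        k <- k + 1
        jittered <- conf + matrix(rnorm(length(conf), sd = jitter_sd),
                                  nrow(conf), 3)
        rot <- random_rotation_matrix()
        trans <- runif(3, -10, 10)
        frames[[k]] <- sweep(jittered %*% t(rot), 2, trans, "+")
      }
      n_break_of <- c(n_break_of, rep(schedule$n_break[b], schedule$n_frames[b]))
    }
  })
  out <- trajectory(base$topology, frames)
  attr(out, "n_break") <- n_break_of
  out
}
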