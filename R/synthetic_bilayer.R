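# Synthetic bilayer atom clouds. Lipids are represented as independent point
# atoms per chemical marker species (phosphate-like, carbonyl-like,
# sterol-like): an electron-density profile along the membrane normal depends
# only on z positions, atomic numbers, partial charges and slab volume, so
# packed lipid conformers are unnecessary for validating that stage.

#' Specification of a synthetic bilayer
#'
#' Each species places `atoms_per_leaflet` atoms in each leaflet, with z drawn
#' from `Normal(+/- leaflet_mean_z, leaflet_sd_z)` and x, y uniform over the
#' box cross-section. Leaflets are symmetric about z = 0.
#'
#' @param species A tibble with columns `label`, `name` (atom name), `element`,
#'   `atoms_per_leaflet`, `leaflet_mean_z` (positive; mirrored to the lower
#'   leaflet), `leaflet_sd_z`, `z_number`, `partial_charge`, `mass`.
#' @param box `c(Lx, Ly)` box cross-section in Angstrom.
#' @param seed Integer seed.
#' @return A `bilayer_spec` list.
#' @export
bilayer_spec <- function(species, box = c(94, 94), seed = 42L) {
  species <- as_tibble(species)
  needed <- c("label", "name", "element", "atoms_per_leaflet", "leaflet_mean_z",
              "leaflet_sd_z", "z_number", "partial_charge", "mass")
  missing <- setdiff(needed, names(species))
  if (length(missing) > 0) {
    abort(paste0("Bilayer species table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(species) == 0) abort("Bilayer spec needs at least one species")
  if (any(species$atoms_per_leaflet < 1)) abort("atoms_per_leaflet must be >= 1")
  if (any(species$leaflet_sd_z < 0)) abort("leaflet_sd_z must be >= 0")
  if (length(box) != 2 || any(box <= 0)) abort("`box` must be two positive lengths (zero box area is invalid)")
  structure(list(species = species, box = as.numeric(box), seed = as.integer(seed)),
            class = "bilayer_spec")
}

#' Bilayer presets mirroring cholesterol-rich and -depleted membranes
#'
#' Leaflet positions reproduce the reference geometry of a polyunsaturated
#' phosphatidylcholine (SDPC) membrane with and without 25% cholesterol:
#' phosphate planes at +/- 21.9 A (cholesterol-rich) vs +/- 20.68 A
#' (cholesterol-depleted), ester-carbonyl planes at +/- 17.5 vs +/- 15.0 A,
#' so the recovered peak-to-peak distances are 43.8 / 41.36 A (phosphate)
#' and 35.0 / 30.0 A (carbonyl). The cholesterol-rich preset additionally
#' carries a sterol-like species deeper in the leaflet. Leaflet widths are
#' plausible thermal spreads for a fluid membrane (2-2.5 A), not fitted
#' values.
#'
#' @param preset `"chol_rich"` or `"chol_depleted"`.
#' @param atoms_per_leaflet Atoms per species per leaflet.
#' @param seed Integer seed.
#' @return A [bilayer_spec()].
#' @export
bilayer_preset <- function(preset = c("chol_rich", "chol_depleted"),
                           atoms_per_leaflet = 5000, seed = 42L) {
  preset <- match.arg(preset)
  base <- tibble(
    label = c("PO4", "carbonyl", "sterol"),
    name = c("P", "C21", "O3"),
    element = c("P", "C", "O"),
    z_number = c(15L, 6L, 8L),
    partial_charge = c(1.5, 0.63, -0.65),
    mass = c(30.974, 12.011, 15.999)
  )
  if (preset == "chol_rich") {
    base$leaflet_mean_z <- c(21.9, 17.5, 12.0)
    base$leaflet_sd_z <- c(2.0, 2.0, 3.0)
  } else {
    base <- base[base$label != "sterol", ]
    base$leaflet_mean_z <- c(20.68, 15.0)
    base$leaflet_sd_z <- c(2.5, 2.5)
  }
  base$atoms_per_leaflet <- atoms_per_leaflet
  bilayer_spec(base, box = c(94, 94), seed = seed)
}

#' Generate a synthetic bilayer trajectory
#'
#' Atom order (and hence the topology) is fixed by the spec; only coordinates
#' are redrawn per frame, sequentially from one seeded random stream, so a
#' given `(spec, n_frames)` pair always yields the identical trajectory and
#' frames within it differ.
#'
#' @param spec A [bilayer_spec()] or [bilayer_preset()].
#' @param n_frames Number of frames.
#' @return A [trajectory()] with `box = c(Lx, Ly, Lz)` where Lz spans the
#'   leaflets plus 6 sd of headroom.
#' @examples
#' bil <- generate_bilayer(bilayer_preset("chol_rich", atoms_per_leaflet = 200), 2)
#' @export
generate_bilayer <- function(spec, n_frames = 20) {
  stopifnot(inherits(spec, "bilayer_spec"))
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  sp <- spec$species
  per_species <- 2L * sp$atoms_per_leaflet
  n <- sum(per_species)

  top <- tibble(
    index = seq_len(n) - 1L,
    name = rep(sp$name, per_species),
    res_name = rep(sp$label, per_species),
    res_id = rep(seq_len(nrow(sp)), per_species),
    chain = "M",
    element = rep(toupper(sp$element), per_species),
    z_number = rep(sp$z_number, per_species),
    partial_charge = rep(sp$partial_charge, per_species),
    mass = rep(sp$mass, per_species)
  )
  leaflet_sign <- unlist(map(per_species, function(k) rep(c(1, -1), each = k / 2)))
  mean_z <- rep(sp$leaflet_mean_z, per_species) * leaflet_sign
  sd_z <- rep(sp$leaflet_sd_z, per_species)

  lz <- 2 * max(sp$leaflet_mean_z + 3 * sp$leaflet_sd_z)
  frames <- withr::with_seed(spec$seed, {
    lapply(seq_len(n_frames), function(f) {
      cbind(runif(n, 0, spec$box[1]),
            runif(n, 0, spec$box[2]),
            rnorm(n, mean_z, sd_z))
    })
  })
  trajectory(top, frames, box = c(spec$box, lz))
}

#' Deterministically placed density-peak system
#'
#' Places point atoms at 1 A slab centers with integer multiplicities
#' following a quadratic (Epanechnikov-like) spread `K * (1 - d^2/width2)`
#' around each requested peak center, where `d` is the distance from the slab
#' center to the peak. Because the binned counts are then an exact parabola
#' in the slab center, 3-point parabolic peak refinement recovers each center
#' exactly, which makes this system the reference construction for validating
#' peak positions and signed offsets without sampling noise.
#'
#' @param species A tibble with columns `label`, `name`, `element`,
#'   `z_number`, `center_z` (one peak per row; use both signs for two
#'   leaflets).
#' @param width2 Squared half-width of the quadratic spread in A^2.
#' @param scale Peak multiplicity `K`.
#' @param box `c(Lx, Ly)` cross-section; atoms are placed on an x-y lattice.
#' @return A single-frame [trajectory()].
#' @export
deterministic_peak_system <- function(species, width2 = 5, scale = 2000,
                                      box = c(94, 94)) {
  species <- as_tibble(species)
  rows <- pmap(species, function(label, name, element, z_number, center_z) {
    slab_centers <- seq(floor(center_z - sqrt(width2)) + 0.5,
                        ceiling(center_z + sqrt(width2)) - 0.5, by = 1)
    d2 <- (slab_centers - center_z)^2
    counts <- round(scale * (1 - d2 / width2))
    keep <- counts > 0
    tibble(label = label, name = name, element = element,
           z_number = as.integer(z_number),
           z = rep(slab_centers[keep], counts[keep]))
  })
  atoms <- bind_rows(rows)
  n <- nrow(atoms)
  top <- tibble(
    index = seq_len(n) - 1L, name = atoms$name, res_name = atoms$label,
    res_id = match(atoms$label, unique(atoms$label)), chain = "M",
    element = toupper(atoms$element), z_number = atoms$z_number,
    partial_charge = 0,
    mass = element_properties(atoms$element)$mass
  )
  # deterministic x-y lattice, irrelevant to z profiles
  gx <- (seq_len(n) - 1) %% 97
  gy <- (seq_len(n) - 1) %/% 97 %% 97
  coords <- cbind(box[1] * (gx + 0.5) / 97, box[2] * (gy + 0.5) / 97, atoms$z)
  trajectory(top, list(coords), box = c(box, 2 * max(abs(atoms$z)) + 10))
}
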