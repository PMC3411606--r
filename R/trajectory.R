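# Element bookkeeping used when building topologies from PDB files or
# synthetic specs. Masses in amu, z_number = atomic number.
ELEMENTS <- tibble::tibble(
  element  = c("H", "C", "N", "O", "P", "S", "NA", "CL", "K", "MG", "CA", "ZN", "FE"),
  z_number = c(1L, 6L, 7L, 8L, 15L, 16L, 11L, 17L, 19L, 12L, 20L, 30L, 26L),
  mass     = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 22.990, 35.45,
               39.098, 24.305, 40.078, 65.38, 55.845)
)

TOPOLOGY_COLUMNS <- c("index", "name", "res_name", "res_id", "chain",
                      "element", "z_number", "partial_charge", "mass")

element_properties <- function(element) {
  i <- match(toupper(element), ELEMENTS$element)
  if (anyNA(i)) {
    abort(paste0("Unknown element symbol(s): ",
                 paste(unique(element[is.na(i)]), collapse = ", ")))
  }
  ELEMENTS[i, ]
}

validate_topology <- function(topology) {
  missing <- setdiff(TOPOLOGY_COLUMNS, names(topology))
  if (length(missing) > 0) {
    abort(paste0("Topology is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(topology) == 0) abort("Topology has no atoms")
  if (!all(topology$index == seq_len(nrow(topology)) - 1L)) {
    abort("Topology `index` must be the contiguous 0-based atom ordinal")
  }
  if (any(topology$z_number < 1)) abort("Atomic numbers must be >= 1")
  if (any(topology$mass <= 0)) abort("Atomic masses must be > 0")
  invisible(topology)
}

#' Construct a trajectory
#'
#' A trajectory couples an ordered atom table (the topology) with one or more
#' coordinate frames. Atom order in the topology matches row order in every
#' coordinate matrix; coordinates are Cartesian and in Angstrom, with the z
#' axis taken as the bilayer normal throughout the package.
#'
#' @param topology A tibble with columns `index` (0-based ordinal), `name`,
#'   `res_name`, `res_id`, `chain`, `element`, `z_number`, `partial_charge`
#'   and `mass`.
#' @param frames A list of N x 3 numeric matrices, one per frame, where N is
#'   the number of atoms in `topology`.
#' @param box Optional numeric vector `c(Lx, Ly, Lz)` in Angstrom. The x-y
#'   cross-section is used to normalise electron-density profiles.
#' @param time_ps Optional numeric vector of frame times in picoseconds.
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, box = NULL, time_ps = NULL) {
  topology <- as_tibble(topology)
  validate_topology(topology)
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of coordinate matrices")
  }
  n_atoms <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3) {
      abort(paste0("Frame ", i, " is not an N x 3 coordinate matrix"))
    }
    if (nrow(f) != n_atoms) {
      abort(paste0("Frame ", i, " has ", nrow(f), " atoms but the topology has ",
                   n_atoms))
    }
    if (!all(is.finite(f))) abort(paste0("Frame ", i, " contains non-finite coordinates"))
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      abort("`box` must be three positive lengths c(Lx, Ly, Lz)")
    }
  }
  structure(
    list(topology = topology, frames = frames, box = box, time_ps = time_ps),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frame(s), ", n_atoms(x), " atoms",
      if (!is.null(x$box)) paste0(", box ", paste(signif(x$box, 4), collapse = " x "), " A"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param x A `trajectory`.
#' @return An integer count.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$topology)

#' Extract one coordinate frame
#' @param x A `trajectory`.
#' @param i Frame number (1-based).
#' @return An N x 3 coordinate matrix in Angstrom.
#' @export
frame_coords <- function(x, i = 1) {
  if (i < 1 || i > n_frames(x)) abort(paste0("Frame ", i, " is out of range"))
  x$frames[[i]]
}

#' Keep a subset of frames
#' @param x A `trajectory`.
#' @param idx Frame numbers to keep, in the order given.
#' @return A `trajectory`.
#' @export
subset_frames <- function(x, idx) {
  trajectory(x$topology, x$frames[idx], box = x$box,
             time_ps = if (!is.null(x$time_ps)) x$time_ps[idx])
}
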