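# Electron density profiles along the bilayer normal, peak-to-peak bilayer
# thickness, and the signed offset of the helix density peak from the
# phosphate plane.

#' Electron density profile along the bilayer normal
#'
#' For every frame, each selected atom contributes its electron count to the
#' 1 A-thick (by default) slab containing its z coordinate, and the slab sum
#' is normalized by slab volume (box cross-section times slab width). The
#' profile is the per-slab mean over frames, with the across-frame standard
#' deviation reported per slab.
#'
#' The electron count of an atom with atomic number Z and partial charge q is
#' `Z - q` by default: a positive partial charge depletes the atom's electron
#' cloud. Set `electron_mode = "add"` for the literal sum `Z + q` used by
#' some density tools.
#'
#' @param x A [trajectory()]. Its `box` provides the cross-sectional area
#'   unless `area` is given.
#' @param selection Selection expression (see [select_atoms()]) or atom row
#'   indices.
#' @param slab_width Slab thickness in Angstrom.
#' @param area Cross-sectional area in Angstrom^2; overrides the trajectory
#'   box.
#' @param z_range Optional `c(zmin, zmax)` for the slab grid (rounded outward
#'   to whole slabs); defaults to the data range. Use a common `z_range` when
#'   two profiles must share a grid.
#' @param electron_mode `"subtract"` (`Z - q`, default) or `"add"` (`Z + q`).
#' @return A `density_profile` tibble with columns `z_center`, `density`
#'   (e/A^3), `sd`; slab edges, the per-frame slab matrix, area, slab width
#'   and the selection label are carried as attributes.
#' @export
electron_density_profile <- function(x, selection, slab_width = 1,
                                     area = NULL, z_range = NULL,
                                     electron_mode = c("subtract", "add")) {
  stopifnot(inherits(x, "trajectory"))
  electron_mode <- match.arg(electron_mode)
  idx <- resolve_selection(x$topology, selection)
  if (length(idx) == 0) abort("Empty atom selection for density profile")
  if (slab_width <= 0) abort("`slab_width` must be positive")
  if (is.null(area)) {
    if (is.null(x$box)) {
      abort("Trajectory has no box; supply `area` (A^2) explicitly")
    }
    area <- x$box[1] * x$box[2]
  }
  top <- x$topology[idx, ]
  electrons <- if (electron_mode == "subtract") {
    top$z_number - top$partial_charge
  } else {
    top$z_number + top$partial_charge
  }
  nf <- n_frames(x)
  zs <- matrix(vapply(seq_len(nf), function(f) frame_coords(x, f)[idx, 3],
                      numeric(length(idx))), nrow = length(idx))
  if (is.null(z_range)) z_range <- range(zs)
  edges <- seq(floor(z_range[1] / slab_width) * slab_width,
               ceiling(z_range[2] / slab_width) * slab_width,
               by = slab_width)
  if (length(edges) < 2) edges <- c(edges, edges + slab_width)
  nslab <- length(edges) - 1
  per_frame <- matrix(0, nslab, nf)
  for (f in seq_len(nf)) {
    slab <- findInterval(zs[, f], edges, rightmost.closed = TRUE)
    inside <- slab >= 1 & slab <= nslab
    per_frame[, f] <- vapply(seq_len(nslab), function(s) {
      sum(electrons[inside & slab == s])
    }, numeric(1)) / (area * slab_width)
  }
  out <- tibble(
    z_center = (edges[-1] + edges[-length(edges)]) / 2,
    density = rowMeans(per_frame),
    sd = if (nf > 1) apply(per_frame, 1, sd) else rep(NA_real_, nslab)
  )
  structure(out, class = c("density_profile", class(out)),
            edges = edges, per_frame = per_frame, area = area,
            slab_width = slab_width,
            selection_label = selection_label(selection),
            electron_mode = electron_mode)
}

# Parabolic (3-point) refinement of a discrete peak position.
refine_peak <- function(z, v, i) {
  if (i <= 1 || i >= length(v)) return(z[i])
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(z[i])
  z[i] + 0.5 * (v[i - 1] - v[i + 1]) / denom * (z[2] - z[1])
}

half_peak <- function(z, v) {
  if (all(v <= 0) || max(v) == 0) return(NA_real_)
  i <- which.max(v)
  refine_peak(z, v, i)
}

#' Locate the two leaflet peaks of a density profile
#'
#' The profile is split at its grid midpoint; in each half the maximum slab is
#' refined to sub-slab precision by 3-point parabolic interpolation (the
#' printed precision of peak-to-peak distances is far finer than the slab
#' width).
#'
#' @param profile A [electron_density_profile()] result, or any tibble with
#'   `z_center` and `density`.
#' @return Named numeric `c(lower, upper)` peak positions in Angstrom.
#' @export
leaflet_peaks <- function(profile) {
  z <- profile$z_center
  v <- profile$density
  if (all(diff(v) >= 0) || all(diff(v) <= 0)) {
    abort("Density profile is monotone; no leaflet peaks to locate")
  }
  mid <- (min(z) + max(z)) / 2
  lower <- z <= mid
  if (sum(v[lower]) == 0 || sum(v[!lower]) == 0) {
    abort("Density profile has mass on only one side of its midpoint")
  }
  lo <- half_peak(z[lower], v[lower])
  hi <- half_peak(z[!lower], v[!lower])
  c(lower = lo, upper = hi)
}

#' Bilayer thickness as the leaflet peak-to-peak distance
#'
#' Thickness is the distance between the two leaflet maxima of the profile
#' (e.g. the phosphate-phosphate distance D_PO4-PO4 when the selection is the
#' phosphate group). The uncertainty is the standard deviation of the
#' per-frame peak-to-peak distances when the profile carries per-frame slabs.
#'
#' @param profile A [electron_density_profile()] result.
#' @return A `thickness_result`: list with `peak_z_lower`, `peak_z_upper`,
#'   `distance`, `sd`, `n_frames`.
#' @export
peak_to_peak <- function(profile) {
  peaks <- leaflet_peaks(profile)
  per_frame <- attr(profile, "per_frame")
  sd_val <- NA_real_
  nf <- if (is.null(per_frame)) 1L else ncol(per_frame)
  if (!is.null(per_frame) && nf > 1) {
    z <- profile$z_center
    mid <- (min(z) + max(z)) / 2
    lower <- z <= mid
    dists <- vapply(seq_len(nf), function(f) {
      v <- per_frame[, f]
      half_peak(z[!lower], v[!lower]) - half_peak(z[lower], v[lower])
    }, numeric(1))
    sd_val <- sd(dists)
  }
  structure(
    list(peak_z_lower = unname(peaks["lower"]),
         peak_z_upper = unname(peaks["upper"]),
         distance = unname(peaks["upper"] - peaks["lower"]),
         sd = sd_val, n_frames = nf),
    class = "thickness_result"
  )
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness> %.2f A (peaks %.2f / %.2f A%s)\n",
              x$distance, x$peak_z_lower, x$peak_z_upper,
              if (!is.na(x$sd)) sprintf(", sd %.2f A over %d frames", x$sd, x$n_frames) else ""))
  invisible(x)
}

#' Signed offset of the helix density peak from the phosphate peak
#'
#' Both profiles must share the same slab grid. On the chosen leaflet, the
#' offset is the distance of the helix peak from the bilayer center minus
#' that of the phosphate peak: negative values mean the helix peak sits
#' interior to the phosphate plane (displaced toward the bilayer center,
#' i.e. buried in the membrane), positive values toward the solvent. The
#' bilayer center is taken as the midpoint of the shared grid.
#'
#' @param profile_helix Density profile of the helix atoms (typically the
#'   hydrophobic-face C-alpha atoms).
#' @param profile_po4 Density profile of the phosphate group.
#' @param leaflet `"upper"` (z > center) or `"lower"`.
#' @return An `offset_result`: list with `offset` (signed, Angstrom),
#'   `leaflet`, `helix_peak_z`, `po4_peak_z`.
#' @export
helix_offset <- function(profile_helix, profile_po4,
                         leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  zh <- profile_helix$z_center
  zp <- profile_po4$z_center
  if (length(zh) != length(zp) || max(abs(zh - zp)) > 1e-9) {
    abort("Helix and phosphate profiles do not share a slab grid")
  }
  mid <- (min(zp) + max(zp)) / 2
  side <- if (leaflet == "upper") zp > mid else zp <= mid
  vh <- profile_helix$density[side]
  if (sum(vh) == 0) {
    abort(paste0("Helix density has no mass on the ", leaflet, " leaflet"))
  }
  if (sum(vh) < 0.5 * sum(profile_helix$density)) {
    abort(paste0("Helix density mass lies mostly on the other leaflet; ",
                 "use leaflet = '", setdiff(c("upper", "lower"), leaflet), "'"))
  }
  # unimodality guard: a second comparable local maximum means the helix
  # profile cannot be summarized by one peak
  vmax <- max(vh)
  interior <- which(diff(sign(diff(vh))) == -2) + 1
  strong <- sum(vh[interior] >= 0.5 * vmax)
  if (strong > 1) {
    abort("Helix density is not unimodal on the chosen leaflet")
  }
  zs <- zp[side]
  helix_peak <- half_peak(zs, vh)
  po4_peak <- half_peak(zs, profile_po4$density[side])
  if (is.na(po4_peak)) abort("Phosphate density has no mass on the chosen leaflet")
  structure(
    list(offset = abs(helix_peak - mid) - abs(po4_peak - mid),
         leaflet = leaflet, helix_peak_z = helix_peak, po4_peak_z = po4_peak),
    class = "offset_result"
  )
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("<offset> %+.2f A (%s leaflet; helix peak %.2f, PO4 peak %.2f): helix %s\n",
              x$offset, x$leaflet, x$helix_peak_z, x$po4_peak_z,
              if (x$offset < 0) "buried toward bilayer center" else "displaced toward solvent"))
  invisible(x)
}

#' Export a density profile as TSV
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("z_center", "density", "sd")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
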