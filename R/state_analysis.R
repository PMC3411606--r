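# Conformational-state detection: 2D kernel density estimation over
# (RMSD, Rg), mode finding, and basin assignment by steepest ascent on the
# density grid.

#' Bandwidth rules for the 2D kernel density estimate
#'
#' Scott's rule per dimension, `h_j = sd_j * n^(-1/6)`, is the default. The
#' Silverman variant replaces the sample standard deviation by
#' `min(sd, IQR/1.349)`, which is more robust to well-separated clusters;
#' note that in two dimensions the Silverman and Scott prefactors coincide.
#'
#' @param x Numeric data vector.
#' @param n Sample size.
#' @param rule `"scott"` or `"silverman"`.
#' @return A bandwidth (kernel standard deviation) in data units.
#' @keywords internal
bandwidth_rule <- function(x, n = length(x), rule = c("scott", "silverman")) {
  rule <- match.arg(rule)
  s <- sd(x)
  if (rule == "silverman") {
    iqr <- diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))
    s <- min(s, iqr / 1.349)
  }
  s * n^(-1 / 6)
}

#' 2D kernel density estimate over the (RMSD, Rg) feature space
#'
#' Gaussian product kernel evaluated on a regular grid spanning the data
#' range plus 3 bandwidths of margin per side. The reported `bandwidth` is
#' the kernel standard deviation per dimension. The density integrates to
#' the kernel mass lying inside the grid (close to 1 with the default
#' margins).
#'
#' @param features A tibble with columns `rmsd` and `rg` (one row per frame),
#'   e.g. from [compute_features()] or [generate_feature_cloud()].
#' @param bandwidth `"scott"`, `"silverman"`, or a numeric vector of one or
#'   two fixed kernel standard deviations `(h_rmsd, h_rg)`.
#' @param grid_size Number of grid nodes per dimension.
#' @return A `kde2d_result`: list with `x`, `y` (grid node coordinates), `z`
#'   (density matrix, x by y), `bandwidth`, `n`.
#' @export
kde2d_features <- function(features, bandwidth = "scott", grid_size = 128) {
  features <- as_tibble(features)
  if (!all(c("rmsd", "rg") %in% names(features))) {
    abort("`features` needs columns `rmsd` and `rg`")
  }
  u <- features$rmsd; v <- features$rg
  if (length(u) < 2) abort("Kernel density estimation needs at least 2 frames")
  if (is.character(bandwidth)) {
    if (sd(u) == 0 || sd(v) == 0) {
      abort(paste0("Zero variance in one feature dimension; automatic ",
                   "bandwidth rules fail - supply a fixed numeric bandwidth"))
    }
    h <- c(bandwidth_rule(u, rule = bandwidth), bandwidth_rule(v, rule = bandwidth))
  } else {
    h <- rep(as.numeric(bandwidth), length.out = 2)
    if (any(h <= 0)) abort("Fixed bandwidths must be positive")
  }
  lims <- c(range(u) + c(-3, 3) * h[1], range(v) + c(-3, 3) * h[2])
  # MASS::kde2d parameterizes the Gaussian kernel with sd = h/4
  k <- MASS::kde2d(u, v, h = 4 * h, n = grid_size, lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bandwidth = setNames(h, c("rmsd", "rg")),
                 n = length(u)),
            class = "kde2d_result")
}

#' @export
print.kde2d_result <- function(x, ...) {
  cat(sprintf("<kde2d> %d x %d grid over rmsd [%.2f, %.2f], rg [%.2f, %.2f]; h = (%.3g, %.3g); n = %d\n",
              length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y),
              x$bandwidth[1], x$bandwidth[2], x$n))
  invisible(x)
}

neighbor_offsets <- expand.grid(di = -1:1, dj = -1:1)
neighbor_offsets <- neighbor_offsets[!(neighbor_offsets$di == 0 & neighbor_offsets$dj == 0), ]

#' Detect density modes (conformational states)
#'
#' A mode is a grid cell that is a strict local maximum over its
#' 8-neighborhood with density at least `min_rel_density` times the global
#' maximum. Local maxima that are not separated from a denser mode's basin by
#' a density dip of at least `min_saddle_drop` (relative to the shallower
#' maximum) are merged into that mode: an undersmoothed kernel estimate of a
#' genuinely unimodal cloud shows twin summits with an almost flat ridge
#' between them, and a state boundary should require a real valley. Modes are
#' labelled 1, 2, ... in order of decreasing density.
#'
#' If the density has no strict local maximum (a perfectly flat or
#' symmetric-plateau estimate from degenerate input), the single global
#' maximum cell (lowest cell index among ties) is returned.
#'
#' @param kde A [kde2d_features()] result.
#' @param min_rel_density Minimum density relative to the global maximum.
#' @param min_saddle_drop Minimum relative density dip separating two modes.
#' @return A tibble with columns `state`, `rmsd`, `rg`, `density` (plus the
#'   grid cell indices of each mode).
#' @export
find_modes <- function(kde, min_rel_density = 0.05, min_saddle_drop = 0.05) {
  stopifnot(inherits(kde, "kde2d_result"))
  z <- kde$z
  nx <- nrow(z); ny <- ncol(z)
  zp <- matrix(-Inf, nx + 2, ny + 2)
  zp[2:(nx + 1), 2:(ny + 1)] <- z
  is_max <- matrix(TRUE, nx, ny)
  for (k in seq_len(nrow(neighbor_offsets))) {
    di <- neighbor_offsets$di[k]; dj <- neighbor_offsets$dj[k]
    is_max <- is_max & (z > zp[2:(nx + 1) + di, 2:(ny + 1) + dj])
  }
  is_max <- is_max & (z >= min_rel_density * max(z))
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    cell <- which(z == max(z))[1]
    idx <- cbind(row = ((cell - 1) %% nx) + 1, col = ((cell - 1) %/% nx) + 1)
  }
  out <- tibble(
    rmsd = kde$x[idx[, 1]], rg = kde$y[idx[, 2]],
    density = z[idx],
    cell_i = as.integer(idx[, 1]), cell_j = as.integer(idx[, 2])
  )
  out <- arrange(out, dplyr::desc(.data$density), .data$cell_i, .data$cell_j)
  out <- merge_shallow_modes(out, z, min_saddle_drop)
  mutate(out, state = row_number(), .before = 1)
}

# Merge candidate maxima whose separating saddle is within `min_saddle_drop`
# (relative) of their own height. Saddles are measured between steepest-ascent
# basins on the grid: for every pair of adjacent cells in different basins,
# the saddle height is the best (highest) min(z1, z2) on the shared boundary.
merge_shallow_modes <- function(modes, z, min_saddle_drop) {
  if (nrow(modes) < 2 || min_saddle_drop <= 0) return(modes)
  nx <- nrow(z); ny <- ncol(z)
  summit <- grid_summits(z)
  mode_cell <- (modes$cell_j - 1) * nx + modes$cell_i
  # basin id per cell = index into `modes` (candidates only; other summits
  # belong to sub-threshold ripples and are ignored for saddle purposes)
  basin <- match(summit, mode_cell)

  # collect the highest saddle between every pair of adjacent basins
  saddle <- list()
  add_pairs <- function(c1, c2) {
    b1 <- basin[c1]; b2 <- basin[c2]
    ok <- !is.na(b1) & !is.na(b2) & b1 != b2
    if (!any(ok)) return()
    h <- pmin(z[c1[ok]], z[c2[ok]])
    key <- paste(pmin(b1[ok], b2[ok]), pmax(b1[ok], b2[ok]))
    agg <- tapply(h, key, max)
    for (k in names(agg)) {
      saddle[[k]] <<- max(saddle[[k]] %||% -Inf, agg[[k]])
    }
  }
  cell_id <- matrix(seq_len(nx * ny), nx, ny)
  add_pairs(as.vector(cell_id[-nx, ]), as.vector(cell_id[-1, ]))           # down
  add_pairs(as.vector(cell_id[, -ny]), as.vector(cell_id[, -1]))           # right
  add_pairs(as.vector(cell_id[-nx, -ny]), as.vector(cell_id[-1, -1]))     # diag
  add_pairs(as.vector(cell_id[-1, -ny]), as.vector(cell_id[-nx, -1]))     # anti-diag

  group <- seq_len(nrow(modes))   # merge target per candidate, by rank
  find_group <- function(i) { while (group[i] != i) i <- group[i]; i }
  # shallowest first; modes are sorted by decreasing density
  for (m in rev(seq_len(nrow(modes)))[-nrow(modes)]) {
    best <- -Inf; target <- NA_integer_
    for (other in seq_len(nrow(modes))[-m]) {
      key <- paste(min(m, other), max(m, other))
      s <- saddle[[key]]
      if (!is.null(s) && modes$density[other] >= modes$density[m] && s > best) {
        best <- s; target <- other
      }
    }
    if (!is.na(target) && best >= (1 - min_saddle_drop) * modes$density[m]) {
      group[m] <- find_group(target)
    }
  }
  keep <- vapply(seq_len(nrow(modes)), function(i) find_group(i) == i, logical(1))
  modes[keep, ]
}

# Steepest-ascent summit of every grid cell, computed by processing cells in
# decreasing density order so each cell's best uphill neighbor is already
# resolved. Ties among equally dense best neighbors break toward the lowest
# linear cell index, making assignment deterministic.
grid_summits <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  ncell <- nx * ny
  summit <- integer(ncell)
  ord <- order(z, seq_len(ncell), decreasing = c(TRUE, FALSE), method = "radix")
  di <- neighbor_offsets$di; dj <- neighbor_offsets$dj
  for (cell in ord) {
    i <- ((cell - 1) %% nx) + 1
    j <- ((cell - 1) %/% nx) + 1
    ni <- i + di; nj <- j + dj
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
    ncells <- (nj[ok] - 1) * nx + ni[ok]
    nz <- z[ncells]
    best <- max(nz)
    if (best > z[cell]) {
      up <- ncells[nz == best]
      summit[cell] <- summit[min(up)]
    } else {
      summit[cell] <- cell
    }
  }
  summit
}

#' Assign frames to conformational states
#'
#' Each frame is mapped to its containing grid cell (frames outside the grid
#' are clamped to the nearest cell and counted in `n_clamped`), then climbed
#' by steepest ascent on the density grid to a summit. Summits that coincide
#' with a detected mode take that state label; summits filtered out by the
#' mode threshold are merged into the nearest detected mode (grid distance).
#'
#' @param features The feature tibble used for the KDE.
#' @param kde A [kde2d_features()] result.
#' @param modes A [find_modes()] tibble.
#' @return A `state_model`: list with `modes` (with `probability` added),
#'   `assignment` (per-frame state labels), `probabilities` tibble, `kde`,
#'   `features`, `n_clamped`.
#' @export
assign_frames <- function(features, kde, modes = find_modes(kde)) {
  stopifnot(inherits(kde, "kde2d_result"))
  features <- as_tibble(features)
  if (nrow(modes) < 1) abort("Need at least one mode to assign frames")
  nx <- length(kde$x); ny <- length(kde$y)
  ci <- findInterval(features$rmsd, kde$x, all.inside = TRUE)
  cj <- findInterval(features$rg, kde$y, all.inside = TRUE)
  # snap to nearest node rather than lower node
  ci <- ci + (ci < nx & abs(features$rmsd - kde$x[ci + pmin(1, nx - ci)]) <
                abs(features$rmsd - kde$x[ci]))
  cj <- cj + (cj < ny & abs(features$rg - kde$y[cj + pmin(1, ny - cj)]) <
                abs(features$rg - kde$y[cj]))
  n_clamped <- sum(features$rmsd < min(kde$x) | features$rmsd > max(kde$x) |
                     features$rg < min(kde$y) | features$rg > max(kde$y))
  if (n_clamped > 0) {
    inform(paste0(n_clamped, " frame(s) outside the density grid were ",
                  "clamped to the nearest cell"))
  }
  summit <- grid_summits(kde$z)
  mode_cell <- (modes$cell_j - 1) * nx + modes$cell_i
  # map every summit cell to a state label
  summit_cells <- unique(summit)
  state_of_summit <- map_int(summit_cells, function(cell) {
    hit <- match(cell, mode_cell)
    if (!is.na(hit)) return(modes$state[hit])
    si <- ((cell - 1) %% nx) + 1; sj <- ((cell - 1) %/% nx) + 1
    d2 <- (modes$cell_i - si)^2 + (modes$cell_j - sj)^2
    modes$state[which.min(d2)]
  })
  frame_summit <- summit[(cj - 1) * nx + ci]
  assignment <- state_of_summit[match(frame_summit, summit_cells)]
  counts <- tabulate(assignment, nbins = nrow(modes))
  probabilities <- tibble(state = modes$state, n_frames = counts,
                          probability = counts / length(assignment))
  structure(
    list(modes = left_join(modes, probabilities, by = "state"),
         assignment = assignment, probabilities = probabilities,
         kde = kde, features = features, n_clamped = n_clamped),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> ", nrow(x$modes), " state(s) over ",
      length(x$assignment), " frames\n", sep = "")
  print(x$probabilities)
  invisible(x)
}

#' Identify conformational states in one call
#'
#' Convenience wrapper: KDE, mode detection, frame assignment.
#'
#' @inheritParams kde2d_features
#' @inheritParams find_modes
#' @return A `state_model`.
#' @export
identify_states <- function(features, bandwidth = "scott", grid_size = 128,
                            min_rel_density = 0.05) {
  kde <- kde2d_features(features, bandwidth, grid_size)
  assign_frames(features, kde, find_modes(kde, min_rel_density))
}

#' Average structure (and its helicity) of one state
#'
#' Member frames are superposed on the first member frame via the helix
#' backbone, coordinates averaged atom-wise, and the helicity of the average
#' structure reported. Coordinate averaging (rather than medoid selection)
#' matches the usual presentation of cluster-average structures; pass
#' `method = "medoid"` for the member frame closest to that average.
#'
#' @param x The [trajectory()] the state model was computed from.
#' @param model A `state_model` from [assign_frames()].
#' @param state State label.
#' @param helixdef A [helix_definition()].
#' @param criterion An [hbond_criterion()].
#' @param method `"mean"` or `"medoid"`.
#' @return A list with `trajectory` (single averaged frame), `helicity`
#'   (a `helicity_result`), `n_frames`, `member_frames`.
#' @export
state_average_structure <- function(x, model, state,
                                    helixdef = helix_definition(x),
                                    criterion = hbond_criterion(),
                                    method = c("mean", "medoid")) {
  stopifnot(inherits(x, "trajectory"), inherits(model, "state_model"))
  method <- match.arg(method)
  members <- which(model$assignment == state)
  if (length(members) == 0) abort(paste0("State ", state, " has no member frames"))
  if (length(members) != length(model$assignment) &&
      n_frames(x) != length(model$assignment)) {
    abort("Trajectory frame count does not match the state model")
  }
  bb <- helix_backbone_rows(x$topology, helixdef)
  ref <- frame_coords(x, members[1])
  aligned <- map(members, function(f) {
    kabsch_superpose(frame_coords(x, f), ref, subset = bb)$aligned
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  if (method == "medoid") {
    dev <- map_dbl(aligned, ~ sqrt(mean((.x[bb, ] - avg[bb, ])^2)))
    avg <- aligned[[which.min(dev)]]
  }
  out <- trajectory(x$topology, list(avg))
  list(trajectory = out,
       helicity = helicity_percent(out, helixdef, criterion),
       n_frames = length(members), member_frames = members)
}
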