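# broom-style tidiers for the package's result objects.

#' Tidy a state model
#'
#' One row per detected conformational state, with mode position, density and
#' occupancy.
#'
#' @param x A `state_model` from [assign_frames()] or [identify_states()].
#' @param ... Unused.
#' @return A tibble with columns `state`, `rmsd`, `rg`, `density`,
#'   `n_frames`, `probability`.
#' @export
tidy.state_model <- function(x, ...) {
  select(x$modes, "state", "rmsd", "rg", "density", "n_frames", "probability")
}

#' Glance at a state model
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return A one-row tibble with `n_states`, `n_frames`, `h_rmsd`, `h_rg`,
#'   `grid_size`, `entropy` (Shannon entropy of the state occupancies, nats).
#' @export
glance.state_model <- function(x, ...) {
  p <- x$probabilities$probability
  p <- p[p > 0]
  tibble(
    n_states = nrow(x$modes),
    n_frames = length(x$assignment),
    h_rmsd = unname(x$kde$bandwidth[1]),
    h_rg = unname(x$kde$bandwidth[2]),
    grid_size = length(x$kde$x),
    entropy = -sum(p * log(p))
  )
}

#' Augment features with their state assignment
#'
#' @param x A `state_model`.
#' @param data The feature tibble used to fit the model (default: the one
#'   stored in the model).
#' @param ... Unused.
#' @return `data` with a `.state` column appended.
#' @export
augment.state_model <- function(x, data = x$features, ...) {
  mutate(as_tibble(data), .state = x$assignment)
}

#' @export
tidy.helicity_result <- function(x, ...) {
  tibble(percent_folded = x$percent_folded, n_intact = nrow(x$intact),
         reference_count = x$reference_count)
}

#' @export
tidy.thickness_result <- function(x, ...) {
  tibble(peak_z_lower = x$peak_z_lower, peak_z_upper = x$peak_z_upper,
         distance = x$distance, sd = x$sd, n_frames = x$n_frames)
}

#' @export
tidy.offset_result <- function(x, ...) {
  tibble(offset = x$offset, leaflet = x$leaflet,
         helix_peak_z = x$helix_peak_z, po4_peak_z = x$po4_peak_z)
}
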