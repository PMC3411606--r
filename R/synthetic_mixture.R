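# Feature-space mixtures. The conformational-state stage works on per-frame
# (RMSD, radius of gyration) pairs; these generators draw such pairs from
# Gaussian mixtures so the kernel-density and mode-detection machinery can be
# validated against a known number of states.

#' Specification of a bivariate Gaussian mixture over (RMSD, Rg)
#'
#' @param components A tibble with columns `weight`, `mean_rmsd`, `mean_rg`,
#'   `sd_rmsd`, `sd_rg`, `correlation`. Weights must be positive and sum to 1;
#'   standard deviations positive; |correlation| < 1.
#' @param n_samples Number of draws.
#' @param seed Integer seed.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(components, n_samples = 4000, seed = 7L) {
  components <- as_tibble(components)
  needed <- c("weight", "mean_rmsd", "mean_rg", "sd_rmsd", "sd_rg", "correlation")
  missing <- setdiff(needed, names(components))
  if (length(missing) > 0) {
    abort(paste0("Mixture table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(components) == 0) abort("Mixture needs at least one component")
  if (any(components$weight <= 0) || abs(sum(components$weight) - 1) > 1e-8) {
    abort("Mixture weights must be positive and sum to 1")
  }
  if (any(components$sd_rmsd <= 0) || any(components$sd_rg <= 0)) {
    abort("Mixture standard deviations must be positive")
  }
  if (any(abs(components$correlation) >= 1)) {
    abort("Mixture correlations must satisfy |rho| < 1")
  }
  if (n_samples < 1) abort("`n_samples` must be >= 1")
  structure(list(components = components, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Feature-space mixture presets for the two membrane conditions
#'
#' `"chol_rich"` has two well-separated components (the helix is folded
#' throughout: a dominant state and a minor one), `"chol_depleted"` has six —
#' three high-weight, one medium-weight and two low-weight — mirroring the
#' state structure seen in cholesterol-depleted membranes. Component
#' locations are synthetic: plausible (RMSD, Rg) values for an 11-residue
#' helix unfolding from its ~5 A-Rg folded form, chosen well-separated
#' relative to the component widths; they are not taken from any published
#' state map.
#'
#' @param preset `"chol_rich"` or `"chol_depleted"`.
#' @param n_samples Number of draws (default 4000 for the 2-state preset,
#'   6000 for the 6-state preset).
#' @param seed Integer seed.
#' @return A [mixture_spec()].
#' @export
mixture_preset <- function(preset = c("chol_rich", "chol_depleted"),
                           n_samples = NULL, seed = 7L) {
  preset <- match.arg(preset)
  if (preset == "chol_rich") {
    comp <- tibble(
      weight = c(0.65, 0.35),
      mean_rmsd = c(0.8, 2.6), mean_rg = c(4.9, 5.4),
      sd_rmsd = 0.30, sd_rg = 0.25, correlation = 0
    )
    n_samples <- n_samples %||% 4000
  } else {
    comp <- tibble(
      weight = c(0.24, 0.22, 0.18, 0.16, 0.11, 0.09),
      mean_rmsd = c(0.8, 3.0, 5.2, 3.4, 6.6, 1.2),
      mean_rg = c(4.9, 5.3, 5.8, 7.6, 7.9, 7.3),
      sd_rmsd = 0.30, sd_rg = 0.25, correlation = 0
    )
    n_samples <- n_samples %||% 6000
  }
  mixture_spec(comp, n_samples = n_samples, seed = seed)
}

#' Draw a feature series from a Gaussian mixture
#'
#' @param spec A [mixture_spec()] or [mixture_preset()].
#' @return A tibble with columns `frame`, `rmsd`, `rg` and the generating
#'   `component`, one row per draw.
#' @examples
#' feats <- generate_feature_cloud(mixture_preset("chol_rich", n_samples = 500))
#' @export
generate_feature_cloud <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  comp <- spec$components
  withr::with_seed(spec$seed, {
    id <- sample.int(nrow(comp), spec$n_samples, replace = TRUE,
                     prob = comp$weight)
    z1 <- rnorm(spec$n_samples)
    z2 <- rnorm(spec$n_samples)
    rho <- comp$correlation[id]
    rmsd <- comp$mean_rmsd[id] + comp$sd_rmsd[id] * z1
    rg <- comp$mean_rg[id] +
      comp$sd_rg[id] * (rho * z1 + sqrt(1 - rho^2) * z2)
  })
  tibble(frame = seq_len(spec$n_samples), rmsd = rmsd, rg = rg, component = id)
}
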