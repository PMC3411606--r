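# End-to-end orchestration: synthesize (or load) a system, compute features,
# detect states, measure density profiles, and write a reproducible report.

#' Pipeline run configuration
#'
#' Exactly one of `preset` or `input` must be given. A preset run synthesizes
#' every input: a helix trajectory following `schedule`, a bilayer from
#' [bilayer_preset()], and a feature-space cloud from [mixture_preset()]. An
#' input run reads a multi-model PDB plus topology table and computes
#' features, states and profiles from them.
#'
#' @param preset `"chol_rich"` or `"chol_depleted"`, or `NULL`.
#' @param input A list `list(pdb = path, topology = path)`, or `NULL`.
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Integer master seed; sub-stage seeds are derived from it.
#' @param schedule Unfolding schedule for the synthetic helix trajectory; the
#'   default depends on the preset (all-folded for `chol_rich`; a folded /
#'   partially unfolded ladder for `chol_depleted`).
#' @param atoms_per_leaflet Bilayer size per species per leaflet.
#' @param n_bilayer_frames Bilayer frames.
#' @param kde List of state-analysis settings: `bandwidth`, `grid_size`,
#'   `min_rel_density`.
#' @param density List of density settings: `slab_width`, `po4_selection`,
#'   `carbonyl_selection`, `helix_ca_selection`, `electron_mode`.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input = NULL, output_dir = tempfile("helix8_run_"),
                       seed = 1L, schedule = NULL,
                       atoms_per_leaflet = 5000, n_bilayer_frames = 20,
                       kde = list(), density = list()) {
  if (is.null(preset) == is.null(input)) {
    abort("Give exactly one of `preset` or `input`")
  }
  if (!is.null(preset)) preset <- match.arg(preset, c("chol_rich", "chol_depleted"))
  if (!is.null(input) && !all(c("pdb", "topology") %in% names(input))) {
    abort("`input` must be list(pdb = , topology = )")
  }
  kde <- utils::modifyList(
    list(bandwidth = "scott", grid_size = 128, min_rel_density = 0.05), kde)
  density <- utils::modifyList(
    list(slab_width = 1, po4_selection = "res_name=PO4",
         carbonyl_selection = "res_name=carbonyl",
         helix_ca_selection = NULL, electron_mode = "subtract"), density)
  if (is.null(schedule) && !is.null(preset)) {
    schedule <- if (preset == "chol_rich") {
      tibble(n_break = 0L, n_frames = 200L)
    } else {
      tibble(n_break = c(0L, 2L, 4L, 5L), n_frames = c(80L, 60L, 40L, 20L))
    }
  }
  structure(
    list(preset = preset, input = input, output_dir = output_dir,
         seed = as.integer(seed), schedule = schedule,
         atoms_per_leaflet = atoms_per_leaflet,
         n_bilayer_frames = n_bilayer_frames, kde = kde, density = density),
    class = "run_config"
  )
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Helix immersion geometry emulated in preset runs: the hydrophobic-face
# C-alpha plane sits 1.60 A interior to the phosphate plane in the
# cholesterol-rich membrane and 1.73 A exterior in the depleted one.
PRESET_HELIX_OFFSET <- c(chol_rich = -1.60, chol_depleted = 1.73)

preset_helix_ca_cloud <- function(preset, po4_mean_z, n_atoms, n_frames, seed) {
  mean_z <- po4_mean_z + PRESET_HELIX_OFFSET[[preset]]
  top <- tibble(
    index = seq_len(n_atoms) - 1L, name = "CA", res_name = "HLX",
    res_id = 1L, chain = "H", element = "C", z_number = 6L,
    partial_charge = 0, mass = 12.011
  )
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      cbind(runif(n_atoms, 0, 94), runif(n_atoms, 0, 94),
            rnorm(n_atoms, mean_z, 1.2))
    })
  })
  trajectory(top, frames, box = c(94, 94, 2 * (mean_z + 6)))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load), helicity trace, features, conformational
#' states, per-state average structures, electron density profiles, bilayer
#' thickness, helix offset, summary. All stage outputs are written under
#' `config$output_dir`; a `summary.json` echoes the headline numbers together
#' with a provenance block (seed, config hash, package version). Any stage
#' error writes a `FAILED` marker naming the stage and re-raises; outputs of
#' completed stages are retained.
#'
#' @param config A [run_config()].
#' @return The run report (named list mirroring `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  report <- list()
  tryCatch({
    seed <- config$seed

    if (!is.null(config$preset)) {
      stage <- "simulate"
      helix_traj <- generate_helix_trajectory(config$schedule, seed = seed)
      bilayer <- generate_bilayer(
        bilayer_preset(config$preset, config$atoms_per_leaflet, seed = seed + 1L),
        config$n_bilayer_frames)
      cloud <- generate_feature_cloud(
        mixture_preset(config$preset, seed = seed + 2L))
      write_multi_model_pdb(helix_traj, file.path(config$output_dir, "helix.pdb"))
      write_topology_table(helix_traj$topology,
                           file.path(config$output_dir, "helix_topology.csv"))
    } else {
      stage <- "load"
      helix_traj <- read_multi_model_pdb(config$input$pdb)
      helix_traj$topology <- read_topology_table(config$input$topology)
      validate_topology(helix_traj$topology)
      bilayer <- NULL
      cloud <- NULL
    }

    stage <- "helicity"
    helixdef <- helix_definition(helix_traj)
    trace <- helicity_trace(helix_traj, helixdef)
    write_tsv_plain(trace, file.path(config$output_dir, "helicity_trace.tsv"))

    stage <- "features"
    feats <- compute_features(helix_traj, helixdef)
    write_tsv_plain(feats, file.path(config$output_dir, "features_helix.tsv"))
    state_feats <- cloud %||% feats
    if (!is.null(cloud)) {
      write_tsv_plain(cloud, file.path(config$output_dir, "features_cloud.tsv"))
    }

    stage <- "states"
    model <- identify_states(state_feats, config$kde$bandwidth,
                             config$kde$grid_size, config$kde$min_rel_density)
    helix_model <- identify_states(feats, config$kde$bandwidth,
                                   config$kde$grid_size, config$kde$min_rel_density)

    stage <- "state_structures"
    per_state <- map(helix_model$modes$state, function(s) {
      avg <- state_average_structure(helix_traj, helix_model, s, helixdef)
      write_multi_model_pdb(avg$trajectory, file.path(
        config$output_dir, sprintf("state_%d_average.pdb", s)))
      list(state = s, n_frames = avg$n_frames,
           percent_folded = avg$helicity$percent_folded)
    })
    state_json <- list(
      feature_space = list(
        n_states = nrow(model$modes),
        modes = as.data.frame(select(model$modes, "state", "rmsd", "rg",
                                     "density", "probability"))),
      helix_trajectory = list(
        n_states = nrow(helix_model$modes),
        per_state_helicity = per_state)
    )
    jsonlite::write_json(state_json, file.path(config$output_dir, "state_model.json"),
                         auto_unbox = TRUE, digits = NA)

    thickness <- NULL; offset <- NULL
    if (!is.null(bilayer)) {
      stage <- "density"
      lz <- bilayer$box[3]
      z_range <- c(-lz / 2, lz / 2)
      prof_po4 <- electron_density_profile(
        bilayer, config$density$po4_selection, config$density$slab_width,
        z_range = z_range, electron_mode = config$density$electron_mode)
      prof_carb <- electron_density_profile(
        bilayer, config$density$carbonyl_selection, config$density$slab_width,
        z_range = z_range, electron_mode = config$density$electron_mode)
      write_density_profile(prof_po4, file.path(config$output_dir, "profile_po4.tsv"))
      write_density_profile(prof_carb, file.path(config$output_dir, "profile_carbonyl.tsv"))

      stage <- "thickness"
      th_po4 <- peak_to_peak(prof_po4)
      th_carb <- peak_to_peak(prof_carb)
      thickness <- list(
        po4 = list(distance = th_po4$distance, sd = th_po4$sd),
        carbonyl = list(distance = th_carb$distance, sd = th_carb$sd))

      stage <- "offset"
      po4_mean <- bilayer_preset(config$preset)$species$leaflet_mean_z[1]
      helix_cloud <- preset_helix_ca_cloud(
        config$preset, po4_mean, 2000, config$n_bilayer_frames, seed + 3L)
      prof_hca <- electron_density_profile(
        helix_cloud, "name=CA", config$density$slab_width,
        area = attr(prof_po4, "area"), z_range = z_range,
        electron_mode = config$density$electron_mode)
      write_density_profile(prof_hca, file.path(config$output_dir, "profile_helix_ca.tsv"))
      off <- helix_offset(prof_hca, prof_po4, leaflet = "upper")
      offset <- list(offset = off$offset, leaflet = off$leaflet,
                     helix_peak_z = off$helix_peak_z, po4_peak_z = off$po4_peak_z)
      jsonlite::write_json(list(thickness = thickness, offset = offset),
                           file.path(config$output_dir, "density.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "summary"
    cfg_for_hash <- config
    cfg_for_hash$output_dir <- NULL
    report <- list(
      provenance = list(
        package = "helix8",
        version = as.character(utils::packageVersion("helix8")),
        seed = config$seed,
        preset = config$preset %||% "external-input",
        config_hash = rlang::hash(cfg_for_hash)
      ),
      n_states = nrow(model$modes),
      state_probabilities = model$probabilities$probability,
      per_state_helicity = map_dbl(per_state, "percent_folded"),
      mean_percent_folded = mean(trace$percent_folded),
      thickness = thickness,
      offset = offset
    )
    jsonlite::write_json(report, file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$output_dir, "FAILED"))
    abort(paste0("Pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)), parent = e)
  })
}

#' Concatenate feature series from several runs
#'
#' Mirrors the common practice of pooling independent MD runs of the same
#' system before estimating the conformational-state density.
#'
#' @param runs A (optionally named) list of feature tibbles (columns `frame`,
#'   `rmsd`, `rg`), e.g. from [compute_features()].
#' @return One tibble with a `run` label column prepended; frame numbers are
#'   kept per-run.
#' @export
concat_runs <- function(runs) {
  if (!is.list(runs) || length(runs) == 0) abort("Need at least one run")
  ranges <- map(runs, ~ attr(.x, "res_id_range"))
  known <- ranges[!vapply(ranges, is.null, logical(1))]
  if (length(known) > 1 &&
      !all(vapply(known, identical, logical(1), y = known[[1]]))) {
    abort("Runs were computed with different helix definitions (residue ranges differ)")
  }
  out <- list_rbind(imap(runs, function(df, nm) {
    mutate(as_tibble(df), run = as.character(nm), .before = 1)
  }))
  if (length(known) > 0) attr(out, "res_id_range") <- known[[1]]
  out
}
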