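# Structured run configuration and the pipeline entry points used by the
# command-line script (inst/scripts/tfa-cli.R).  A run is fully determined
# by (config, master seed); every run writes its resolved configuration
# next to its outputs.

default_run_config <- function() {
  list(
    model = list(name = "ole", s_pos = 1, s_neg = 1, variants = list()),
    stimulus = list(duration = 3000, dt = 1, n_segments_range = c(5L, 30L),
                    freq_range = c(1 / 1500, 1 / 20), n_components = 3L,
                    noise_sd_frac = 0.05),
    ensemble = list(n_block = 33L, n_saw = 33L, n_sine = 34L),
    stft = list(window_length = 256L, hop = 128L, threshold_db = 80,
                scaling = "nm_uniform"),
    simulation = list(rel_tol = 1e-6, abs_tol = 1e-8,
                      equilibrate_time = 6000,
                      delay_handling = "history_interpolation",
                      chain_length = 3L),
    sweep = list(from = 1e-2, to = 1e2, n = 7L, by_family = FALSE),
    epsilon = 1e-12,
    seed = 1L,
    out_dir = "tfa-run"
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a run configuration file
#'
#' YAML key-value configuration; missing fields fall back to package
#' defaults, and `overrides` (e.g. from command-line flags) take
#' precedence over the file.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top of the file values.
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

#' Write a resolved configuration
#' @param config A configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

config_stimulus <- function(cfg, family = "block", seed = NULL) {
  s <- cfg$stimulus
  stimulus_config(family = family, duration = s$duration, dt = s$dt,
                  max_amplitude = 1,
                  n_segments_range = unlist(s$n_segments_range),
                  freq_range = unlist(s$freq_range),
                  n_components = s$n_components,
                  noise_sd_frac = s$noise_sd_frac, seed = seed)
}

config_model <- function(cfg, s_pos = NULL, s_neg = NULL) {
  m <- cfg$model
  sp <- if (is.null(s_pos)) m$s_pos else s_pos
  sn <- if (is.null(s_neg)) m$s_neg else s_neg
  switch(m$name,
         gal = gal_model(sp, sn),
         ole = ole_model(sp, sn, variants = unlist(m$variants)),
         lps = lps_model(sp, sn),
         identity = identity_model(),
         rlang::abort(paste0("unknown model name: ", m$name),
                      class = "tfanet_config_error"))
}

config_stft <- function(cfg) {
  s <- cfg$stft
  stft_config(s$window_length, s$hop, s$threshold_db, s$scaling)
}

config_settings <- function(cfg) {
  s <- cfg$simulation
  simulation_settings(s$rel_tol, s$abs_tol, s$equilibrate_time,
                      s$delay_handling, s$chain_length)
}

config_ensemble <- function(cfg) {
  e <- cfg$ensemble
  generate_ensemble(e$n_block, e$n_saw, e$n_sine, config_stimulus(cfg),
                    seed = cfg$seed)
}

#' Simulate an ensemble and write stimulus/response files
#'
#' @param config A resolved configuration list (see [read_run_config()]).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_model(config)
  settings <- config_settings(config)
  ens <- config_ensemble(config)
  y0 <- if (model$kind == "identity") NULL else basal_state(model, settings)
  purrr::pwalk(ens, function(stimulus_id, family, seed, signal) {
    stim <- if (model$kind == "identity") signal
            else scale_amplitude(signal, model$max_stimulus)
    resp <- simulate_response(model, stim, settings, y0 = y0)
    tag <- sprintf("%04d_%s", stimulus_id, family)
    write_signal(stim, file.path(config$out_dir,
                                 paste0("stimulus_", tag, ".tsv")))
    write_signal(resp, file.path(config$out_dir,
                                 paste0("response_", tag, ".tsv")))
  })
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(config$out_dir)
}

#' Run the TFA statistics pipeline and write the statistics table
#'
#' @param config A resolved configuration list.
#' @return The `tfa_ensemble` tibble, invisibly.
#' @export
run_tfa <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_model(config)
  ens <- config_ensemble(config)
  res <- run_ensemble(model, ens, config_stft(config),
                      config_settings(config), epsilon = config$epsilon)
  utils::write.table(as.data.frame(res),
                     file.path(config$out_dir, "statistics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(summarize_ensemble(res, by_family = TRUE),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(res)
}

#' TFA statistics for explicit stimulus/response file pairs
#'
#' @param stimulus_paths,response_paths Equal-length vectors of signal
#'   file paths.
#' @param stft An [stft_config()].
#' @param epsilon Smoothing constant.
#' @return A tibble with one statistics row per pair.
#' @export
run_tfa_pairs <- function(stimulus_paths, response_paths,
                          stft = stft_config(), epsilon = 1e-12) {
  if (length(stimulus_paths) != length(response_paths)) {
    rlang::abort("stimulus and response path lists differ in length.",
                 class = "tfanet_io_error")
  }
  rows <- purrr::map2(stimulus_paths, response_paths, function(sp, rp) {
    stats <- analyze_pair(read_signal(sp), read_signal(rp), stft, epsilon)
    stats$stimulus_file <- sp
    stats$response_file <- rp
    stats
  })
  dplyr::bind_rows(rows)
}

#' Run a loop-strength sweep and write its maps
#'
#' @param config A resolved configuration list.
#' @return The `tfa_sweep` tibble, invisibly.
#' @export
run_sweep <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- loop_strength_grid(config$sweep$from, config$sweep$to,
                             config$sweep$n)
  builder <- function(s_pos, s_neg) config_model(config, s_pos, s_neg)
  ens <- config_ensemble(config)
  sw <- sweep_loop_strengths(builder, grid, grid, ens,
                             config_stft(config), config_settings(config),
                             by_family = isTRUE(config$sweep$by_family),
                             epsilon = config$epsilon)
  utils::write.table(as.data.frame(sw),
                     file.path(config$out_dir, "sweep.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(sw)
}

#' Generate a small frozen fixture bundle
#'
#' Writes a reproducible bundle of short stimuli (four per family) and a
#' golden statistics table for the identity system, for regression
#' checks.  Regeneration with the same seed is bit-identical.
#'
#' @param seed Master seed.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = "tfa-fixtures") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- stimulus_config(duration = 600, dt = 1)
  ens <- generate_ensemble(4L, 4L, 4L, base, seed = seed)
  purrr::pwalk(ens, function(stimulus_id, family, seed, signal) {
    write_signal(signal, file.path(dir, sprintf("stimulus_%02d_%s.tsv",
                                                stimulus_id, family)))
  })
  res <- run_ensemble(identity_model(), ens)
  utils::write.table(as.data.frame(res), file.path(dir, "golden_identity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
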