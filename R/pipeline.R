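#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory (created if missing).
#' @param tracks,sightings,mask input file paths (tracks CSV, sightings
#'   CSV, habitat ASCII grid) for [run_fit()].
#' @param model model variant 1-4 (see [model_variant()]).
#' @param M augmented population size.
#' @param scenario a `scenario_config` or path to a scenario YAML, for
#'   [run_simulate()].
#' @param sampler a `sampler_config`.
#' @param seed master seed; all randomness in a run flows from it.
#' @param quiet suppress progress messages.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, tracks = NULL, sightings = NULL,
                       mask = NULL, model = 1, M = 150,
                       scenario = NULL, sampler = sampler_config(),
                       seed = 1, quiet = FALSE) {
  structure(
    list(out_dir = out_dir, tracks = tracks, sightings = sightings,
         mask = mask, model = as.integer(model), M = as.integer(M),
         scenario = scenario, sampler = sampler, seed = as.integer(seed),
         quiet = isTRUE(quiet)),
    class = "run_config")
}

say <- function(config, fmt, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(fmt, ...))
}

resolve_scenario <- function(scenario) {
  if (is.null(scenario)) return(cheetah_scenario())
  if (inherits(scenario, "scenario_config")) return(scenario)
  if (is.character(scenario)) return(read_scenario(scenario))
  stop("scenario must be a scenario_config or a YAML path")
}

#' Simulate a survey and write its files
#'
#' Writes `tracks.csv`, `sightings.csv`, `habitat_mask.asc` (1 = suitable,
#' 0 = unsuitable), `truth.csv` and the scenario used (`scenario.yaml`)
#' into `out_dir`.
#'
#' @param config a `run_config` (uses `scenario`, `seed`, `out_dir`).
#' @return invisibly, the named vector of paths written.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scenario <- resolve_scenario(config$scenario)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_survey(scenario, seed = config$seed)
  paths <- c(
    tracks = file.path(config$out_dir, "tracks.csv"),
    sightings = file.path(config$out_dir, "sightings.csv"),
    mask = file.path(config$out_dir, "habitat_mask.asc"),
    truth = file.path(config$out_dir, "truth.csv"),
    scenario = file.path(config$out_dir, "scenario.yaml"))
  write_tracks(sim$tracks, paths["tracks"])
  write_sightings(sim$sightings, paths["sightings"])
  write_ascii_grid(
    state_space_grid(sim$space, as.numeric(sim$space$suitable)),
    paths["mask"], digits = 1)
  utils::write.csv(sim$population, paths["truth"], row.names = FALSE)
  write_scenario(scenario, paths["scenario"])
  say(config,
      "simulated survey: %.0f km effort, %d occasions, %d individuals, %d detected (%d sightings)",
      sum(sim$effort$effort), ncol(sim$effort$effort), nrow(sim$population),
      length(unique(sim$detections$ind)), nrow(sim$detections))
  invisible(paths)
}

#' Fit a model to survey files and write all artifacts
#'
#' Reads tracks, sightings and the habitat mask, rasterizes effort, builds
#' the encounter array, runs the MCMC sampler for the configured model
#' variant, and writes: one `draws_chain<c>.csv` per chain, `summary.csv`
#' (Table-style posterior summary), `diagnostics.json`,
#' `density_surface.asc` and `effort.csv`, plus `run_metadata.yaml`.
#' Grid/calendar inconsistencies are reported before sampling begins.
#'
#' @param config a `run_config` with `tracks`, `sightings`, `mask` paths
#'   set; `trap_side` and `occasions` are derived from the data (traps
#'   cover the track extent at 1 km).
#' @param trap_side trap pixel side (km).
#' @return invisibly, the fitted `scr_fit`.
#' @export
run_fit <- function(config, trap_side = 1) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("tracks", "sightings", "mask"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file for '", f, "' is missing or does not exist")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  mask <- read_ascii_grid(config$mask)
  space <- state_space_from_grid(mask)
  tracks <- read_tracks(config$tracks)
  sightings <- read_sightings(config$sightings)
  ext <- c(floor(min(tracks$x_km)), ceiling(max(tracks$x_km)),
           floor(min(tracks$y_km)), ceiling(max(tracks$y_km)))
  traps <- build_trap_grid(ext, side = trap_side)
  dates <- sort(unique(c(as.Date(tracks$timestamp), as.Date(sightings$date))))
  occasions <- seq(min(dates), max(dates), by = "day")
  effort <- rasterize_effort(tracks, traps, occasions)
  enc <- build_encounter_array(sightings, effort)
  say(config,
      "inputs: %.0f km effort over %d occasions, %d traps; n = %d (%d F, %d M), %d detection cells; M = %d; suitable area %.1f km^2",
      sum(effort$effort), length(occasions), traps$J, enc$n,
      sum(enc$sex == 0), sum(enc$sex == 1), nrow(enc$det), config$M,
      suitable_area(space))

  variant <- model_variant(config$model)
  sampler <- config$sampler
  sampler$seed <- config$seed
  fit <- run_chains(enc, space, M = config$M, variant = variant,
                    config = sampler)

  for (cc in seq_along(fit$chains)) {
    d <- as.data.frame(fit$chains[[cc]]$draws)
    d <- cbind(iteration = seq_len(nrow(d)), d)
    utils::write.csv(d,
      file.path(config$out_dir, sprintf("draws_chain%d.csv", cc)),
      row.names = FALSE)
  }
  rep <- diagnostics_report(fit, seed = config$seed)
  write_diagnostics(rep, file.path(config$out_dir, "diagnostics.json"))
  write_summary(rep$summary, file.path(config$out_dir, "summary.csv"))
  surf <- density_surface(fit)
  write_ascii_grid(surf$grid, file.path(config$out_dir, "density_surface.asc"))
  write_effort(effort, file.path(config$out_dir, "effort.csv"))
  yaml::write_yaml(
    list(model = config$model, M = config$M, seed = config$seed,
         chains = sampler$chains, iterations = sampler$iterations,
         burnin = sampler$burnin, thin = sampler$thin,
         chain_seeds = fit$chain_seeds,
         kernel = "f(d) = (d/sigma)^(2*theta); cloglog encounter model",
         effort_floor_cells = nrow(enc$floored)),
    file.path(config$out_dir, "run_metadata.yaml"))
  say(config, "max PSRF %.3f; Bayesian p-value %.3f; D = %.3f / 100 km^2",
      rep$max_psrf, rep$p_value,
      rep$summary$table$mean[rep$summary$table$parameter == "D"])
  invisible(fit)
}

#' Write a posterior summary table as CSV
#'
#' @param summ an `scr_summary`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summ, path) {
  stopifnot(inherits(summ, "scr_summary"))
  utils::write.csv(summ$table, path, row.names = FALSE)
  invisible(path)
}

#' Side-by-side report over fitted models
#'
#' Reads `summary.csv` files from one or more fit output directories and
#' renders a model-comparison table (posterior mean and PSD per free
#' parameter, max PSRF, Bayesian p-value).
#'
#' @param dirs character vector of directories written by [run_fit()].
#' @param path optional file to write the rendered text report to.
#' @return the comparison data frame, invisibly; printed if `path` is
#'   `NULL`.
#' @export
run_report <- function(dirs, path = NULL) {
  rows <- list()
  for (d in dirs) {
    sf <- file.path(d, "summary.csv")
    jf <- file.path(d, "diagnostics.json")
    if (!file.exists(sf))
      stop("no summary.csv in ", d, "; run run_fit() first")
    tab <- utils::read.csv(sf, stringsAsFactors = FALSE)
    meta <- if (file.exists(jf)) jsonlite::read_json(jf) else list()
    lab <- sprintf("model_%s", meta$model %||% basename(d))
    rows[[lab]] <- stats::setNames(
      as.vector(rbind(tab$mean, tab$sd)),
      as.vector(rbind(tab$parameter, paste0(tab$parameter, "_psd"))))
    rows[[lab]] <- c(rows[[lab]],
                     max_psrf = meta$max_psrf %||% NA,
                     bayesian_p = meta$bayesian_p_value %||% NA)
  }
  all_names <- unique(unlist(lapply(rows, names)))
  out <- data.frame(quantity = all_names)
  for (lab in names(rows))
    out[[lab]] <- as.numeric(rows[[lab]][all_names])
  txt <- utils::capture.output(print(out, row.names = FALSE))
  if (!is.null(path)) writeLines(txt, path) else cat(txt, sep = "\n")
  invisible(out)
}
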