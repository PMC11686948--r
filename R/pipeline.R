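# Pipeline commands tying the modules together; the Rscript wrapper in
# inst/scripts/metapopclim.R is a thin shell around run_pipeline().

#' Run one pipeline command
#'
#' Commands: `"simulate"` writes a synthetic study to `output_dir`;
#' `"extract"` builds a standardized colony-level climate series from a
#' long-format gridded climate file (`climate_grid.csv`, cell-month values;
#' an optional logical `is_land` column masks land cells) and the colony
#' table, using density surfaces built at every required epoch with the
#' expert capacity as the size proxy;
#' `"fit"` fits one model structure to the inputs in `input_dir`;
#' `"select"` fits and ranks a set of candidate structures; `"forecast"`
#' propagates a fit under both scenarios and writes trajectories;
#' `"sensitivity"` writes the scenario-difference table. Every command
#' writes a `manifest.json` recording config, seed, versions and runtime,
#' and removes partial outputs on failure.
#'
#' @param command One of `"simulate"`, `"fit"`, `"select"`, `"forecast"`,
#'   `"sensitivity"`.
#' @param config A `run_config` (see [read_run_config()]) or a named list
#'   with the same keys.
#' @return Invisibly, the primary result object of the command.
#' @export
run_pipeline <- function(command = c("simulate", "extract", "fit", "select",
                                     "forecast", "sensitivity"),
                         config) {
  command <- match.arg(command)
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(df, f) {
    p <- file.path(out_dir, f)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    switch(command,
      simulate = {
        study <- simulate_study(n_colonies = config$n_colonies,
                                seed = config$seed)
        write_study(study, out_dir)
        study
      },
      extract = {
        colonies <- read_colonies(file.path(config$input_dir, "colonies.csv"))
        grid_df <- read_climate_grid(file.path(config$input_dir,
                                               "climate_grid.csv"))
        cells <- dplyr::distinct(grid_df, .data$cell_id, .data$lon, .data$lat)
        cells$is_land <- if ("is_land" %in% names(grid_df)) {
          dplyr::distinct(grid_df, .data$cell_id, .data$is_land)$is_land
        } else FALSE
        hind_years <- sort(unique(
          grid_df$year[grid_df$scenario == "hindcast"]))
        scen_years <- sort(unique(
          grid_df$year[grid_df$scenario != "hindcast"]))
        # fitting window runs two years past the hindcast horizon, filled
        # with the scenario mean (the standard splice)
        splice <- scen_years[scen_years > max(hind_years) &
                               scen_years <= max(hind_years) + 2]
        fit_years <- c(hind_years, splice)
        fc_years <- setdiff(scen_years, splice)
        col_sized <- dplyr::transmute(colonies, colony_id = .data$colony_id,
                                      lon = .data$lon, lat = .data$lat,
                                      aos = .data$K_expert)
        epochs <- unique(epoch_for_year(c(fit_years, fc_years)))
        surfaces <- dplyr::bind_rows(lapply(epochs, function(e) {
          make_surface(col_sized, cells, epoch = e)
        }))
        series <- assemble_series(surfaces, grid_df,
                                  hindcast_years = fit_years,
                                  forecast_years = fc_years)
        series <- standardize_climate(series, window = fit_years)
        w(series, "climate.csv")
        w(climate_constants(series), "climate_constants.csv")
        w(surfaces, "surfaces.csv")
        series
      },
      fit = {
        data <- read_study(config$input_dir)
        spec <- pipeline_spec(config$model)
        fit <- run_mcmc(data, spec, chains = config$chains,
                        iter = config$iter, burn = config$burn,
                        thin = config$thin, seed = config$seed)
        w(fit$summary, "posterior_summary.csv")
        w(fit$latent, "latent_states.csv")
        w(fit$draws, "draws.csv")
        fit
      },
      select = {
        data <- read_study(config$input_dir)
        ids <- config$model
        suite <- enumerate_models()
        specs <- if (identical(ids, "all")) suite$spec else {
          missing <- setdiff(ids, suite$id)
          if (length(missing)) {
            abort(paste0("unknown model id(s): ",
                         paste(missing, collapse = ", ")))
          }
          suite$spec[match(ids, suite$id)]
        }
        tab <- select_model(data, specs, chains = config$chains,
                            iter = config$iter, burn = config$burn,
                            thin = config$thin, seed = config$seed)
        w(tab, "model_selection.csv")
        tab
      },
      forecast = {
        data <- read_study(config$input_dir)
        spec <- pipeline_spec(config$model)
        fit <- run_mcmc(data, spec, chains = config$chains,
                        iter = config$iter, burn = config$burn,
                        thin = config$thin, seed = config$seed)
        fc <- forecast_scenarios(fit, n_draws = config$n_draws,
                                 seed = config$seed)
        w(fc$trajectories, "forecast_trajectories.csv")
        w(fc$totals, "forecast_totals.csv")
        fc
      },
      sensitivity = {
        fc <- run_pipeline("forecast",
                           within_config(config, output_dir = out_dir))
        w(sensitivity(fc), "sensitivity.csv")
        w(classify_trajectory(fc), "trajectory_patterns.csv")
        fc
      }
    )
  }, error = function(e) {
    unlink(written)
    abort(paste0("pipeline command `", command, "` failed: ",
                 conditionMessage(e)))
  })
  write_manifest(out_dir, command, config, config$seed %||% NA,
                 proc.time()[["elapsed"]] - t0)
  invisible(result)
}

pipeline_spec <- function(id) {
  suite <- enumerate_models()
  i <- match(id, suite$id)
  if (is.na(i)) abort(paste0("unknown model id: ", id))
  suite$spec[[i]]
}

within_config <- function(config, ...) {
  over <- list(...)
  config[names(over)] <- over
  config
}
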