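# Validated file I/O: the CSV schemas shared by the synthetic generator and
# the fitting pipeline, run configuration and run manifests. Validation
# errors name the offending rows.

read_checked <- function(path, required, types, name) {
  if (!file.exists(path)) abort(paste0(name, " file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(name, " file ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in names(types)) {
    if (types[[col]] == "numeric" && !is.numeric(df[[col]])) {
      abort(paste0(name, " column `", col, "` must be numeric"))
    }
  }
  tibble::as_tibble(df)
}

fail_rows <- function(bad, name, path, what) {
  if (any(bad)) {
    rows <- which(bad)
    abort(paste0(name, " file ", path, ": ", what, " at row",
                 if (length(rows) > 1) "s" else "", " ",
                 paste(utils::head(rows, 10), collapse = ", ")))
  }
}

#' Read and validate pipeline input files
#'
#' Readers for the four CSV schemas of the pipeline: census counts
#' (`colony_id, year, aos_count`), fecundity records
#' (`colony_id, year, nests, chicks`), colony metadata
#' (`colony_id, name, lon, lat, K_expert, hpai_status`) and long-format
#' colony climate series (`colony_id, scenario, year, covariate, value`).
#' Schema violations are reported with the offending row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_census <- function(path) {
  df <- read_checked(path, c("colony_id", "year", "aos_count"),
                     list(year = "numeric", aos_count = "numeric"), "census")
  fail_rows(df$aos_count < 0 | df$aos_count != round(df$aos_count),
            "census", path, "aos_count must be a non-negative integer")
  df
}

#' @rdname read_census
#' @export
read_fecundity_obs <- function(path) {
  df <- read_checked(path, c("colony_id", "year", "nests", "chicks"),
                     list(year = "numeric", nests = "numeric",
                          chicks = "numeric"), "fecundity")
  fail_rows(df$nests <= 0, "fecundity", path, "nests must be positive")
  fail_rows(df$chicks < 0 | df$chicks > df$nests, "fecundity", path,
            "chicks must lie in [0, nests]")
  df
}

#' @rdname read_census
#' @export
read_colonies <- function(path) {
  df <- read_checked(path, c("colony_id", "lon", "lat", "K_expert",
                             "hpai_status"),
                     list(lon = "numeric", lat = "numeric",
                          K_expert = "numeric"), "colonies")
  fail_rows(df$K_expert <= 0, "colonies", path, "K_expert must be positive")
  fail_rows(!df$hpai_status %in% c("affected", "unaffected", "unknown"),
            "colonies", path,
            "hpai_status must be affected/unaffected/unknown")
  fail_rows(duplicated(df$colony_id), "colonies", path,
            "duplicated colony_id")
  df
}

#' @rdname read_census
#' @export
read_climate_series <- function(path) {
  df <- read_checked(path, c("colony_id", "scenario", "year", "covariate",
                             "value"),
                     list(year = "numeric", value = "numeric"), "climate")
  fail_rows(!df$covariate %in% mpc_covariates(), "climate", path,
            paste0("covariate must be one of ",
                   paste(mpc_covariates(), collapse = "/")))
  df
}

#' @rdname read_census
#' @export
read_climate_grid <- function(path) {
  read_checked(path, c("cell_id", "lon", "lat", "scenario", "year", "month",
                       "covariate", "value"),
               list(lon = "numeric", lat = "numeric", year = "numeric",
                    month = "numeric", value = "numeric"), "climate grid")
}

#' Write a synthetic study to the pipeline CSV schemas
#'
#' A synthetic study written this way is a drop-in input for the fitting
#' pipeline: `census.csv`, `fecundity.csv`, `colonies.csv`, `climate.csv`
#' (standardized series plus a `climate_constants.csv` with the
#' standardization constants) and `latent.csv` (the true trajectory, for
#' parameter-recovery checks).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  w(study$census, "census.csv")
  w(study$fecundity, "fecundity.csv")
  w(study$colonies, "colonies.csv")
  w(study$climate, "climate.csv")
  w(climate_constants(study$climate), "climate_constants.csv")
  w(study$latent, "latent.csv")
  invisible(dir)
}

#' Load pipeline inputs from a directory of CSVs
#'
#' @param dir Directory holding `census.csv`, `fecundity.csv`,
#'   `colonies.csv` and `climate.csv` (the [write_study()] layout).
#' @return A list (`census`, `fecundity`, `colonies`, `climate`) ready for
#'   [run_mcmc()].
#' @export
read_study <- function(dir) {
  climate <- read_climate_series(file.path(dir, "climate.csv"))
  cst_path <- file.path(dir, "climate_constants.csv")
  if (file.exists(cst_path)) {
    attr(climate, "constants") <- tibble::as_tibble(
      utils::read.csv(cst_path, stringsAsFactors = FALSE))
  }
  list(census = read_census(file.path(dir, "census.csv")),
       fecundity = read_fecundity_obs(file.path(dir, "fecundity.csv")),
       colonies = read_colonies(file.path(dir, "colonies.csv")),
       climate = climate)
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) configuration for the pipeline commands: input paths,
#' model id, MCMC settings, seed and output directory. Unknown keys are
#' rejected; the configuration round-trips through serialization.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("input_dir", "output_dir", "model", "chains", "iter", "burn",
             "thin", "seed", "years", "forecast_years", "n_colonies",
             "n_draws", "scenarios")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(model = "m3.3^251", chains = 4, iter = 100000,
                   burn = 15000, thin = 200, seed = 1, n_colonies = 6,
                   n_draws = 200, scenarios = c("SSP1", "SSP5"))
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  for (k in c("chains", "iter", "burn", "thin", "n_colonies", "n_draws")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      abort(paste0("config `", k, "` must be a positive number"))
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and runtime of a
#' pipeline run next to its artifacts, so every output is reproducible from
#' its manifest.
#'
#' @param dir Output directory.
#' @param command Pipeline command that produced the artifacts.
#' @param config The configuration list used.
#' @param seed Seed used.
#' @param runtime_s Elapsed seconds.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, config, seed, runtime_s) {
  manifest <- list(
    command = command,
    config = unclass(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("metapopclim")),
    r_version = R.version.string,
    runtime_s = round(runtime_s, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
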