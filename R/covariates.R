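# Colony-specific covariate series from gridded monthly climate fields:
# at-sea density surfaces per colony, density-weighted extraction over the
# February-September colony-attendance window, epoch rules and z-scoring.

#' Epochs at which density surfaces are rebuilt
#' @return Integer vector of epoch years.
#' @export
surface_epochs <- function() c(1900L, 1920L, 1940L, 1960L, 1980L, 2000L, 2016L)

#' Surface epoch used for a given year
#'
#' Each year uses the surface of its 20-year interval (1900-1919 use the
#' 1900 surface, and so on); every year from 2016 onwards - including all
#' forecast years - uses the last available (2016) surface.
#'
#' @param year Integer vector of calendar years.
#' @return Integer vector of epoch years.
#' @export
epoch_for_year <- function(year) {
  e <- pmax(1900L, 20L * (as.integer(year) %/% 20L))
  e[year >= 2016L] <- 2016L
  e
}

#' Build colony at-sea density surfaces on a grid
#'
#' A simplified stand-in for a mechanistic space-use model: each colony gets
#' an exponential-decay kernel over sea cells, `w ~ exp(-d / lambda)`, with
#' range `lambda` scaling as the square root of colony size (larger colonies
#' forage further). Cells reachable by several colonies are split between
#' them in proportion to each colony's kernel value (a competitive-exclusion
#' proxy), land cells get zero weight, and each colony's weights are
#' normalized to sum to 1.
#'
#' @param colonies Tibble with columns `colony_id`, `lon`, `lat`, `aos`
#'   (colony size used for the kernel range).
#' @param grid Tibble of cell centroids: `cell_id`, `lon`, `lat` and logical
#'   `is_land`.
#' @param epoch Epoch year stamped on the surface.
#' @param lambda0 Kernel e-folding range (km) of a 1000-AOS colony; the
#'   colony-specific range is `lambda0 * sqrt(aos / 1000)`.
#' @return Tibble (`colony_id`, `epoch`, `cell_id`, `weight`) with weights
#'   summing to 1 within each colony.
#' @export
make_surface <- function(colonies, grid, epoch, lambda0 = 15) {
  colonies <- tibble::as_tibble(colonies)
  grid <- tibble::as_tibble(grid)
  if (any(colonies$aos <= 0)) abort("colony sizes must be > 0")
  sea <- dplyr::filter(grid, !.data$is_land)
  if (!nrow(sea)) abort("grid has no sea cells")
  kern <- purrr::pmap_dfr(colonies, function(colony_id, lon, lat, aos, ...) {
    d_km <- geosphere::distHaversine(cbind(sea$lon, sea$lat), c(lon, lat)) / 1000
    lambda <- lambda0 * sqrt(aos / 1000)
    tibble::tibble(colony_id = colony_id, cell_id = sea$cell_id,
                   k = exp(-d_km / lambda))
  })
  out <- kern |>
    dplyr::mutate(share = .data$k / sum(.data$k), .by = "cell_id") |>
    dplyr::mutate(weight = .data$k * .data$share) |>
    dplyr::mutate(total = sum(.data$weight), .by = "colony_id")
  if (any(out$total <= 0)) {
    bad <- unique(out$colony_id[out$total <= 0])
    abort(paste0("colony has no positive-weight sea cell (landlocked?): ",
                 paste(bad, collapse = ", ")))
  }
  out |>
    dplyr::mutate(weight = .data$weight / .data$total,
                  epoch = as.integer(epoch)) |>
    dplyr::select("colony_id", "epoch", "cell_id", "weight")
}

#' Density-weighted covariate extraction
#'
#' Averages a gridded monthly field over the February-September colony
#' attendance window, then takes the surface-weighted mean over cells
#' (weights renormalized over the cells present in the field), giving one
#' scalar per colony and year.
#'
#' @param surface A surface tibble from [make_surface()] (one epoch).
#' @param field Long tibble of one covariate: `cell_id`, `year`, `month`,
#'   `value` (any number of years).
#' @param months Months averaged per year before the spatial weighting;
#'   default February-September.
#' @return Tibble (`colony_id`, `year`, `value`).
#' @export
extract_covariate <- function(surface, field, months = 2:9) {
  field <- tibble::as_tibble(field)
  missing_cells <- setdiff(surface$cell_id, field$cell_id)
  if (length(missing_cells)) {
    abort(paste0("surface and field grids do not match; missing cell(s): ",
                 paste(utils::head(missing_cells, 5), collapse = ", ")))
  }
  annual <- field |>
    dplyr::filter(.data$month %in% months) |>
    dplyr::summarise(value = mean(.data$value), .by = c("cell_id", "year"))
  dplyr::inner_join(surface, annual, by = "cell_id",
                    relationship = "many-to-many") |>
    dplyr::summarise(value = sum(.data$weight * .data$value) / sum(.data$weight),
                     .by = c("colony_id", "year"))
}

#' Assemble a colony-level climate series from gridded scenarios
#'
#' Applies the epoch rule (each year extracted with its 20-year surface,
#' forecast years with the 2016 surface), splices the fitting series so that
#' 2015-2016 - beyond the hindcast horizon - are the mean of the two
#' scenarios, and returns one long series per scenario.
#'
#' @param surfaces Surface tibble covering all required epochs (rows from
#'   [make_surface()], multiple epochs stacked).
#' @param fields Long tibble: `scenario` (`"hindcast"`, `"SSP1"`, `"SSP5"`),
#'   `covariate`, `cell_id`, `year`, `month`, `value`.
#' @param hindcast_years,forecast_years Years of the fitting and forecast
#'   windows (defaults 1900-2016 and 2017-2100).
#' @param months Passed to [extract_covariate()].
#' @return Long tibble (`colony_id`, `scenario`, `year`, `covariate`,
#'   `value`); the fitting series carries `scenario = "hindcast"`.
#' @export
assemble_series <- function(surfaces, fields,
                            hindcast_years = 1900:2016,
                            forecast_years = 2017:2100,
                            months = 2:9) {
  fields <- tibble::as_tibble(fields)
  need_epochs <- unique(epoch_for_year(c(hindcast_years, forecast_years)))
  have <- unique(surfaces$epoch)
  if (length(setdiff(need_epochs, have))) {
    abort(paste0("missing surface epoch(s): ",
                 paste(setdiff(need_epochs, have), collapse = ", ")))
  }
  extract_years <- function(scen, yrs) {
    sub <- dplyr::filter(fields, .data$scenario == scen, .data$year %in% yrs)
    if (!nrow(sub)) return(tibble::tibble())
    sub |>
      dplyr::mutate(epoch = epoch_for_year(.data$year)) |>
      dplyr::group_by(.data$covariate, .data$epoch) |>
      dplyr::group_modify(function(df, key) {
        surf <- dplyr::filter(surfaces, .data$epoch == key$epoch)
        extract_covariate(surf, df, months = months)
      }) |>
      dplyr::ungroup() |>
      dplyr::select("colony_id", "year", "covariate", "value")
  }
  scen_years <- sort(unique(fields$year[fields$scenario != "hindcast"]))
  splice_years <- intersect(hindcast_years, scen_years)
  hind <- extract_years("hindcast", setdiff(hindcast_years, splice_years))
  splice <- dplyr::bind_rows(extract_years("SSP1", splice_years),
                             extract_years("SSP5", splice_years)) |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("colony_id", "year", "covariate"))
  fit_series <- dplyr::bind_rows(hind, splice) |>
    dplyr::mutate(scenario = "hindcast")
  fc <- dplyr::bind_rows(
    extract_years("SSP1", forecast_years) |> dplyr::mutate(scenario = "SSP1"),
    extract_years("SSP5", forecast_years) |> dplyr::mutate(scenario = "SSP5")
  )
  dplyr::bind_rows(fit_series, fc) |>
    dplyr::arrange(.data$scenario, .data$covariate, .data$colony_id, .data$year) |>
    dplyr::select("colony_id", "scenario", "year", "covariate", "value")
}

#' Standardize a climate series over its fitting window
#'
#' Pools colony-years within the fitting window to compute one mean and SD
#' per covariate (coefficients are shared across colonies, so covariates
#' must live on one common scale), z-scores the whole series with those
#' constants, and records them. Forecast years are standardized with the
#' fitting-window constants, so their z-scores may leave the fitted range.
#'
#' @param series Long tibble (`colony_id`, `scenario`, `year`, `covariate`,
#'   `value`).
#' @param window Years defining the standardization window (default
#'   1900-2016); applied to the `"hindcast"` scenario.
#' @return The z-scored series with a `constants` attribute (tibble
#'   `covariate`, `center`, `scale`), retrievable via [climate_constants()].
#' @export
standardize_climate <- function(series, window = 1900:2016) {
  series <- tibble::as_tibble(series)
  consts <- series |>
    dplyr::filter(.data$scenario == "hindcast", .data$year %in% window) |>
    dplyr::summarise(center = mean(.data$value), scale = sd(.data$value),
                     .by = "covariate")
  if (!nrow(consts)) abort("no hindcast rows inside the standardization window")
  if (any(!is.finite(consts$scale)) || any(consts$scale <= 0)) {
    abort("cannot standardize a covariate with zero variance in the window")
  }
  out <- series |>
    dplyr::left_join(consts, by = "covariate") |>
    dplyr::mutate(value = (.data$value - .data$center) / .data$scale) |>
    dplyr::select(-"center", -"scale")
  attr(out, "constants") <- consts
  out
}

#' @rdname standardize_climate
#' @param x A series returned by [standardize_climate()].
#' @export
climate_constants <- function(x) {
  cst <- attr(x, "constants")
  if (is.null(cst)) abort("no standardization constants attached to this series")
  cst
}

#' @rdname standardize_climate
#' @param constants Constants tibble; defaults to those attached to `x`.
#' @export
unstandardize_climate <- function(x, constants = climate_constants(x)) {
  out <- tibble::as_tibble(x) |>
    dplyr::left_join(constants, by = "covariate") |>
    dplyr::mutate(value = .data$value * .data$scale + .data$center) |>
    dplyr::select(-"center", -"scale")
  attr(out, "constants") <- NULL
  out
}

#' Pivot a long climate series to one row per colony-year
#'
#' @param series Long tibble (`colony_id`, `scenario`, `year`, `covariate`,
#'   `value`).
#' @param scenario Which scenario to keep (default all).
#' @return Wide tibble with one column per covariate.
#' @export
climate_wide <- function(series, scenario = NULL) {
  out <- tibble::as_tibble(series)
  if (!is.null(scenario)) {
    out <- dplyr::filter(out, .data$scenario == !!scenario)
  }
  tidyr::pivot_wider(out, names_from = "covariate", values_from = "value")
}
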