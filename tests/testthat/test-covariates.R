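# Density surfaces, weighted extraction, epoch rules and standardization.

toy_grid <- function(nx = 10, ny = 10, lon0 = -2, lat0 = 55, step = 0.05) {
  tidyr::crossing(ix = seq_len(nx), iy = seq_len(ny)) |>
    dplyr::mutate(cell_id = paste0("c", ix, "_", iy),
                  lon = lon0 + (ix - 1) * step,
                  lat = lat0 + (iy - 1) * step,
                  is_land = FALSE) |>
    dplyr::select(cell_id, lon, lat, is_land)
}

test_that("surface epochs follow the 20-year rule with a 2016 terminal surface", {
  expect_equal(epoch_for_year(1935), 1920L)
  expect_equal(epoch_for_year(1900), 1900L)
  expect_equal(epoch_for_year(1919), 1900L)
  expect_equal(epoch_for_year(2014), 2000L)
  expect_equal(epoch_for_year(c(2016, 2050, 2100)), rep(2016L, 3))
})

test_that("surfaces normalize, decay with distance and split contested cells", {
  grid <- toy_grid()
  one <- tibble::tibble(colony_id = "A", lon = -2, lat = 55, aos = 5000)
  surf <- make_surface(one, grid, epoch = 2016)
  expect_equal(sum(surf$weight), 1, tolerance = 1e-12)
  # maximal weight at the nearest cell (the colony sits on c1_1)
  expect_equal(surf$cell_id[which.max(surf$weight)], "c1_1")

  # two identical colonies equidistant from the mid-line split cells 50/50
  two <- tibble::tibble(colony_id = c("A", "B"), lon = c(-2, -2 + 9 * 0.05),
                        lat = 55, aos = 5000)
  surf2 <- make_surface(two, grid, epoch = 2016)
  wide <- tidyr::pivot_wider(surf2, names_from = colony_id,
                             values_from = weight)
  # symmetry: A's weight on its own side mirrors B's on the other side
  wa <- dplyr::filter(wide, cell_id == "c1_1")$A
  wb <- dplyr::filter(wide, cell_id == "c10_1")$B
  expect_equal(wa, wb, tolerance = 1e-9)

  # a larger colony has a longer-range kernel, hence more tail mass
  sizes <- tibble::tibble(colony_id = c("S", "L"), lon = -2, lat = 55,
                          aos = c(1000, 50000))
  surfs <- make_surface(sizes, grid, epoch = 2016)
  tail_mass <- surfs |>
    dplyr::left_join(grid, by = "cell_id") |>
    dplyr::mutate(far = lon > -1.7) |>
    dplyr::summarise(tail = sum(weight[far]), .by = colony_id)
  expect_gt(tail_mass$tail[tail_mass$colony_id == "L"],
            tail_mass$tail[tail_mass$colony_id == "S"])

  land <- dplyr::mutate(grid, is_land = TRUE)
  expect_error(make_surface(one, land, epoch = 2016), "sea cell")
})

test_that("extraction is a weighted mean over the attendance window", {
  surf <- tibble::tibble(colony_id = "A", epoch = 2016,
                         cell_id = c("c1", "c2", "c3"),
                         weight = c(0.5, 0.3, 0.2))
  field <- tidyr::crossing(cell_id = c("c1", "c2", "c3"), month = 1:12) |>
    dplyr::mutate(year = 2000,
                  value = dplyr::case_when(cell_id == "c1" ~ 10,
                                           cell_id == "c2" ~ 20,
                                           TRUE ~ 30))
  out <- extract_covariate(surf, field)
  expect_equal(out$value, 17) # 0.5*10 + 0.3*20 + 0.2*30
  # spatially uniform field returns the constant
  unif <- dplyr::mutate(field, value = 3.7)
  expect_equal(extract_covariate(surf, unif)$value, 3.7)
  # all weight on one cell returns that cell's Feb-Sep mean
  seasonal <- dplyr::mutate(field, value = ifelse(month %in% 2:9, 12, 99))
  one_cell <- dplyr::mutate(surf, weight = c(1, 0, 0))
  expect_equal(extract_covariate(one_cell, seasonal)$value, 12)
  # linear in the field
  f2 <- dplyr::mutate(field, value = value^2 / 10)
  lin <- extract_covariate(surf,
                           dplyr::mutate(field,
                                         value = 2 * field$value + 3 * f2$value))
  expect_equal(lin$value,
               2 * extract_covariate(surf, field)$value +
                 3 * extract_covariate(surf, f2)$value,
               tolerance = 1e-10)
  # rescaling all weights leaves the weighted mean unchanged
  scaled <- dplyr::mutate(surf, weight = weight * 37)
  expect_equal(extract_covariate(scaled, field)$value, 17)
  expect_error(extract_covariate(dplyr::mutate(surf, cell_id = paste0(cell_id, "x")),
                                 field), "do not match")
})

test_that("series assembly applies the epoch rule and the 2015-2016 splice", {
  grid <- toy_grid(4, 4)
  colonies <- tibble::tibble(colony_id = "A", lon = -2, lat = 55, aos = 4000)
  surfaces <- dplyr::bind_rows(lapply(surface_epochs(), function(e) {
    make_surface(colonies, grid, epoch = e)
  }))
  mk_field <- function(scen, years, level) {
    tidyr::crossing(cell_id = grid$cell_id, year = years, month = 1:12,
                    covariate = "SST") |>
      dplyr::mutate(scenario = scen, value = level + (year - 2000) * 0.01)
  }
  fields <- dplyr::bind_rows(
    mk_field("hindcast", 2010:2014, 10),
    mk_field("SSP1", 2015:2020, 10.2),
    mk_field("SSP5", 2015:2020, 11.0)
  )
  out <- assemble_series(surfaces, fields, hindcast_years = 2010:2016,
                         forecast_years = 2017:2020)
  # 2015 fitting value is the mean of the two scenario values
  v2015 <- dplyr::filter(out, scenario == "hindcast", year == 2015)$value
  s1 <- 10.2 + 15 * 0.01
  s5 <- 11.0 + 15 * 0.01
  expect_equal(v2015, (s1 + s5) / 2, tolerance = 1e-10)
  # forecast years carry scenario labels and use the terminal surface
  expect_setequal(unique(out$scenario), c("hindcast", "SSP1", "SSP5"))
  expect_equal(dplyr::filter(out, scenario == "SSP5", year == 2020)$value,
               11.0 + 20 * 0.01, tolerance = 1e-10)
  expect_error(assemble_series(dplyr::filter(surfaces, epoch != 2016), fields,
                               hindcast_years = 2010:2016,
                               forecast_years = 2017:2020),
               "missing surface epoch")
})

test_that("standardization round-trips and pools to zero mean, unit SD", {
  study_cl <- generate_climate(generate_colonies(3), years = 1990:2030,
                               hindcast_years = 1990:2016, seed = 4)
  z <- standardize_climate(study_cl, window = 1990:2016)
  stats <- z |>
    dplyr::filter(scenario == "hindcast", year <= 2016) |>
    dplyr::summarise(m = mean(value), s = sd(value), .by = covariate)
  expect_true(all(abs(stats$m) < 1e-10))
  expect_true(all(abs(stats$s - 1) < 1e-10))
  back <- unstandardize_climate(z)
  expect_equal(dplyr::arrange(back, scenario, covariate, colony_id, year)$value,
               dplyr::arrange(study_cl, scenario, covariate, colony_id, year)$value,
               tolerance = 1e-10)
  # constant offset shifts z-scores by offset / SD
  cst <- climate_constants(z)
  shifted <- dplyr::mutate(study_cl,
                           value = value + ifelse(covariate == "SST", 2, 0))
  z2 <- standardize_climate(shifted, window = 1990:2016)
  expect_equal(climate_constants(z2)$center[cst$covariate == "SST"],
               cst$center[cst$covariate == "SST"] + 2, tolerance = 1e-10)
  flat <- dplyr::mutate(study_cl, value = 1)
  expect_error(standardize_climate(flat, window = 1990:2016), "zero variance")
})
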