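test_that("identical configurations yield identical datasets", {
  cfg <- city_config(grid_extent = 8, population_total = 10000,
                     n_parks_by_type = c(theme = 2, amusement = 3), seed = 11)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a, b)
  c <- generate_city(city_config(grid_extent = 8, population_total = 10000,
                                 n_parks_by_type = c(theme = 2, amusement = 3),
                                 seed = 12))
  expect_false(identical(a$cells$population, c$cells$population))
})

test_that("generated record counts match the configuration", {
  city <- generate_city(city_config(grid_extent = 10, population_total = 8000,
                                    n_parks_by_type = c(comprehensive = 1,
                                                        theme = 1,
                                                        community = 2),
                                    seed = 7))
  expect_equal(nrow(city$cells), 100)
  expect_equal(nrow(city$parks), 4)
  expect_equal(as.vector(table(city$parks$type)[c("comprehensive", "theme", "community")]),
               c(1, 1, 2))
  expect_true(all(vapply(city$parks$entrances, nrow, integer(1)) >= 1))
})

test_that("population is conserved exactly and degenerate totals give zeros", {
  cfg <- city_config(grid_extent = 9, population_total = 12345,
                     n_parks_by_type = c(community = 1), clustering = 3,
                     seed = 3)
  city <- generate_city(cfg)
  expect_identical(sum(city$cells$population), 12345L)
  expect_true(all(city$cells$population >= 0))

  zero <- generate_city(city_config(grid_extent = 5, population_total = 0,
                                    n_parks_by_type = c(community = 1),
                                    seed = 3))
  expect_true(all(zero$cells$population == 0))
})

test_that("every cell maps to a street and every street to a district", {
  city <- tiny_city()
  expect_true(all(city$cells$street_id %in% city$streets$street_id))
  expect_true(all(!is.na(city$streets$district_id)))
  expect_equal(anyDuplicated(city$streets$street_id), 0L)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(city_config(cell_size = -1), "cell_size")
  expect_error(city_config(detour_factor = 0.5), "detour_factor")
  expect_error(city_config(mode_speeds = c(walking = 0)), "mode_speeds")
  expect_error(city_config(clustering = -2), "clustering")
  expect_error(generate_city(list()), "city_config")
})

test_that("travel times follow distance x detour / speed and scale with speed", {
  cfg <- city_config(grid_extent = 2, cell_size = 1000,
                     n_parks_by_type = c(community = 1),
                     mode_speeds = c(walking = 5, driving = 30),
                     detour_factor = 1, population_total = 100, seed = 1)
  cells <- data.frame(cell_id = "c1", x = 0, y = 0)
  parks <- data.frame(park_id = "p1", stringsAsFactors = FALSE)
  parks$entrances <- I(list(cbind(x = 1000, y = 0)))  # exactly 1 km away
  ttm <- build_travel_time_matrix(cells, parks, "walking", cfg)
  expect_equal(as.vector(ttm), 12)  # 1 km at 5 km/h = 12 min

  # a cell placed on an entrance has zero travel time
  cells0 <- data.frame(cell_id = "c1", x = 1000, y = 0)
  expect_equal(as.vector(build_travel_time_matrix(cells0, parks, "walking", cfg)), 0)

  # driving entries never exceed walking entries when driving is faster
  city <- tiny_city()
  expect_true(all(city$travel_times$driving <= city$travel_times$walking))

  # multiplying all speeds by c divides every entry by c
  cfg2 <- city_config(grid_extent = 2, cell_size = 1000,
                      n_parks_by_type = c(community = 1),
                      mode_speeds = c(walking = 10, driving = 60),
                      detour_factor = 1, population_total = 100, seed = 1)
  ttm2 <- build_travel_time_matrix(cells, parks, "walking", cfg2)
  expect_equal(as.vector(ttm2), as.vector(ttm) / 2)

  expect_error(build_travel_time_matrix(cells, parks, "cycling", cfg),
               "walking, driving")
})

test_that("nearest entrance governs the park travel time", {
  cfg <- city_config(grid_extent = 2, cell_size = 1000,
                     n_parks_by_type = c(community = 1),
                     mode_speeds = c(walking = 5), detour_factor = 1,
                     population_total = 100, seed = 1)
  cells <- data.frame(cell_id = "c1", x = 0, y = 0)
  parks <- data.frame(park_id = "p1", stringsAsFactors = FALSE)
  parks$entrances <- I(list(cbind(x = c(500, 5000), y = c(0, 0))))
  ttm <- build_travel_time_matrix(cells, parks, "walking", cfg)
  expect_equal(as.vector(ttm), 0.5 / 5 * 60)  # nearest entrance at 0.5 km
})

test_that("feature tables reproduce their stored ground truth exactly", {
  city <- tiny_city()
  # all-null effects with zero noise give a constant response
  ft0 <- generate_feature_table(city, effects_spec(noise_sd = 0, intercept = 2),
                                seed = 5)
  expect_true(all(ft0$table$response == 2))

  # single linear effect is reproduced exactly
  ft1 <- generate_feature_table(
    city, effects_spec(list(PD = effect_linear(2)), noise_sd = 0, intercept = 1),
    seed = 5)
  expect_equal(ft1$table$response, 1 + 2 * ft1$table$PD)
  expect_equal(ft1$table$response, ft1$truth(ft1$table))

  # plateau ground truth is flat above its threshold
  sp <- effects_spec(list(PD = effect_plateau(0.07, 10)), noise_sd = 0)
  ft2 <- generate_feature_table(city, sp, seed = 5)
  above <- data.frame(ft2$table[, setdiff(names(ft2$table), "response")])
  above$PD <- 0.1
  higher <- above
  higher$PD <- 5
  expect_equal(ft2$truth(above), ft2$truth(higher))

  # missing predictor in a hand-built spec is named in the error
  broken <- sp
  broken$effects$PD <- NULL
  expect_error(generate_feature_table(city, broken, seed = 5), "PD")
})

test_that("feature table generation is seed-deterministic with all 15 predictors", {
  city <- tiny_city()
  sp <- effects_spec(list(SAD = effect_peak(0.3, 0.1, 5)), noise_sd = 0.2)
  a <- generate_feature_table(city, sp, seed = 9)
  b <- generate_feature_table(city, sp, seed = 9)
  expect_identical(a$table, b$table)
  expect_true(all(pgs_predictors() %in% names(a$table)))
  expect_equal(length(pgs_predictors()), 15L)
})
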