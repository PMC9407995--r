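# Independent oracles and fixture builders, deliberately written as plain
# double loops so they share no code path with the package implementation.

# Brute-force Gaussian 2SFCA over a cells-by-parks travel-time matrix.
oracle_2sfca <- function(population, capacity, tt, t0) {
  g <- function(t) {
    if (t > t0) return(0)
    (exp(-0.5 * (t / t0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  }
  n_c <- length(population)
  n_p <- length(capacity)
  R <- numeric(n_p)
  for (j in seq_len(n_p)) {
    demand <- 0
    for (k in seq_len(n_c)) demand <- demand + g(tt[k, j]) * population[k]
    R[j] <- if (demand > 0) capacity[j] / demand else 0
  }
  A <- numeric(n_c)
  for (i in seq_len(n_c)) {
    for (j in seq_len(n_p)) A[i] <- A[i] + g(tt[i, j]) * R[j]
  }
  list(R = R, A = A)
}

# Population-weighted Gini via the mean-absolute-difference definition:
# G = sum_ij P_i P_j |c_i - c_j| / (2 * P^2 * cbar), c = per-capita service.
oracle_gini <- function(population, service) {
  keep <- population > 0
  p <- population[keep]
  s <- service[keep]
  if (sum(s) == 0) return(0)
  cc <- s / p
  num <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) num <- num + p[i] * p[j] * abs(cc[i] - cc[j])
  }
  num / (2 * sum(p)^2 * (sum(s) / sum(p)))
}

# Random toy 2SFCA instance: cells and parks scattered in a box scaled so
# that some or all pairs fall inside the catchment.
random_instance <- function(n_cells, n_parks, box_km = 2, t0 = 15,
                            speed_kmh = 5, min_pop = 0) {
  xy_c <- matrix(runif(2 * n_cells, 0, box_km), ncol = 2)
  xy_p <- matrix(runif(2 * n_parks, 0, box_km), ncol = 2)
  tt <- matrix(0, n_cells, n_parks)
  for (i in seq_len(n_cells)) {
    for (j in seq_len(n_parks)) {
      d <- sqrt(sum((xy_c[i, ] - xy_p[j, ])^2))
      tt[i, j] <- d / speed_kmh * 60
    }
  }
  list(
    cells = data.frame(cell_id = sprintf("c%02d", seq_len(n_cells)),
                       population = sample(min_pop:100, n_cells, replace = TRUE)),
    parks = data.frame(park_id = sprintf("p%02d", seq_len(n_parks)),
                       capacity = runif(n_parks, 10, 500)),
    tt = tt, t0 = t0)
}

run_2sfca <- function(inst) {
  ttm <- travel_time_matrix(inst$tt, mode = "walking", t0 = inst$t0)
  rownames(ttm) <- inst$cells$cell_id
  colnames(ttm) <- inst$parks$park_id
  ratios <- suppressWarnings(
    supply_demand_ratios(inst$parks, inst$cells, ttm, t0 = inst$t0))
  accessibility_scores(inst$cells, inst$parks, ratios, ttm, t0 = inst$t0)
}

tiny_city <- function(grid_extent = 6, seed = 7, ...) {
  generate_city(city_config(grid_extent = grid_extent,
                            population_total = 5000,
                            n_parks_by_type = c(comprehensive = 1,
                                                community = 3),
                            street_cells = 3, district_streets = 2,
                            seed = seed, ...))
}
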