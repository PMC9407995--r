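#' Configuration for the synthetic city generator
#'
#' Defines a square grid of demand cells, a typed park supply, spatially
#' clustered population, and travel-mode parameters.  Defaults describe a
#' 15 km by 15 km central urban area (30 x 30 cells of 500 m) holding 1.6
#' million residents and 163 parks whose type proportions follow a large
#' central-Chinese city (comprehensive : theme : community : amusement
#' roughly 36 : 31 : 236 : 395).
#'
#' @param grid_extent Cells per side of the square grid.
#' @param cell_size Cell edge length in metres (default 500).
#' @param n_parks_by_type Named integer vector of park counts per type.
#' @param population_total Total residents to apportion over cells.
#' @param clustering Spatial concentration parameter (>= 0): 0 gives a
#'   uniform population surface; larger values pile population onto the
#'   city-core kernels.
#' @param n_kernels Number of Gaussian "city-core" kernels.
#' @param kernel_sd Kernel bandwidth as a fraction of the city side length.
#' @param mode_speeds Named vector of travel speeds in km/h per mode.
#' @param detour_factor Network detour multiplier on straight-line
#'   distance (>= 1).
#' @param park_area_ranges Named list of `c(min, max)` m2 ranges per park
#'   type; areas are drawn log-uniformly.
#' @param street_cells Cells per side of the square street tiles.
#' @param district_streets Street tiles per side of the square districts.
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A validated `city_config` list.
#' @export
#' @examples
#' cfg <- city_config(grid_extent = 10, population_total = 10000,
#'                    n_parks_by_type = c(comprehensive = 1, community = 3))
city_config <- function(grid_extent = 30L,
                        cell_size = 500,
                        n_parks_by_type = c(comprehensive = 8L, theme = 7L,
                                            community = 55L, amusement = 93L),
                        population_total = 1600000,
                        clustering = 1,
                        n_kernels = 3L,
                        kernel_sd = 0.15,
                        mode_speeds = c(walking = 5, driving = 30),
                        detour_factor = 1.2,
                        park_area_ranges = list(comprehensive = c(1e5, 1e6),
                                                theme = c(5e4, 5e5),
                                                community = c(1e4, 1e5),
                                                amusement = c(2e3, 2e4)),
                        street_cells = 5L,
                        district_streets = 3L,
                        seed = 1L) {
  cfg <- list(grid_extent = as.integer(grid_extent), cell_size = cell_size,
              n_parks_by_type = n_parks_by_type,
              population_total = population_total, clustering = clustering,
              n_kernels = as.integer(n_kernels), kernel_sd = kernel_sd,
              mode_speeds = mode_speeds, detour_factor = detour_factor,
              park_area_ranges = park_area_ranges,
              street_cells = as.integer(street_cells),
              district_streets = as.integer(district_streets),
              seed = as.integer(seed))
  bad <- function(field, why) {
    stop("invalid city_config: field '", field, "' ", why, call. = FALSE)
  }
  if (cfg$grid_extent < 1) bad("grid_extent", "must be a positive count")
  if (!is.finite(cfg$cell_size) || cfg$cell_size <= 0) bad("cell_size", "must be > 0")
  if (is.null(names(cfg$n_parks_by_type)) || any(names(cfg$n_parks_by_type) == "")) {
    bad("n_parks_by_type", "must be a named vector of counts")
  }
  if (any(cfg$n_parks_by_type < 0)) bad("n_parks_by_type", "counts must be >= 0")
  if (sum(cfg$n_parks_by_type) < 1) bad("n_parks_by_type", "must request at least one park")
  if (!is.finite(cfg$population_total) || cfg$population_total < 0) {
    bad("population_total", "must be >= 0")
  }
  if (!is.finite(cfg$clustering) || cfg$clustering < 0) bad("clustering", "must be >= 0")
  if (cfg$n_kernels < 1) bad("n_kernels", "must be >= 1")
  if (!is.finite(cfg$kernel_sd) || cfg$kernel_sd <= 0) bad("kernel_sd", "must be > 0")
  if (is.null(names(cfg$mode_speeds)) || any(cfg$mode_speeds <= 0)) {
    bad("mode_speeds", "must be named speeds > 0 km/h")
  }
  if (!is.finite(cfg$detour_factor) || cfg$detour_factor < 1) {
    bad("detour_factor", "must be >= 1")
  }
  miss <- setdiff(names(cfg$n_parks_by_type), names(cfg$park_area_ranges))
  if (length(miss)) bad("park_area_ranges", paste("missing type(s):", paste(miss, collapse = ", ")))
  for (rg in cfg$park_area_ranges) {
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2]) {
      bad("park_area_ranges", "entries must be positive c(min, max) ranges")
    }
  }
  if (cfg$street_cells < 1) bad("street_cells", "must be >= 1")
  if (cfg$district_streets < 1) bad("district_streets", "must be >= 1")
  structure(cfg, class = "city_config")
}

# Largest-remainder apportionment: integer populations summing exactly to
# `total`, proportional to weights `w`.
apportion_population <- function(total, w) {
  n <- length(w)
  if (total == 0 || sum(w) == 0) return(integer(n))
  q <- total * w / sum(w)
  fl <- floor(q)
  rem <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0) {
    ord <- order(q - fl, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  out
}

#' Generate a synthetic city dataset
#'
#' Builds the full demand/supply substrate for the pipeline: a square
#' grid of demand cells with population concentrated around Gaussian
#' city-core kernels, typed parks with log-uniform areas and 1--4 boundary
#' entrances, a regular street/district tiling, and per-mode travel-time
#' matrices.  The result is a deterministic function of the configuration
#' (including its seed).
#'
#' @param config A [city_config()].
#' @return A `city_dataset`: list with `cells`, `parks` (including an
#'   `entrances` list column of coordinate matrices), `streets`
#'   (street-to-district table), `travel_times` (one
#'   [travel_time_matrix()] per mode) and the `config`.
#' @export
#' @examples
#' city <- generate_city(city_config(grid_extent = 6, population_total = 5000,
#'   n_parks_by_type = c(community = 2), street_cells = 3, seed = 7))
generate_city <- function(config) {
  if (!inherits(config, "city_config")) {
    stop("config must be built with city_config()", call. = FALSE)
  }
  set.seed(config$seed)
  ext <- config$grid_extent
  cs <- config$cell_size
  side <- ext * cs

  idx <- expand.grid(col = seq_len(ext), row = seq_len(ext))
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(nrow(idx))),
                      x = (idx$col - 0.5) * cs,
                      y = (idx$row - 0.5) * cs,
                      stringsAsFactors = FALSE)

  s_row <- (idx$row - 1L) %/% config$street_cells
  s_col <- (idx$col - 1L) %/% config$street_cells
  ns_col <- ceiling(ext / config$street_cells)
  cells$street_id <- sprintf("s%03d", s_row * ns_col + s_col + 1L)
  d_row <- s_row %/% config$district_streets
  d_col <- s_col %/% config$district_streets
  nd_col <- ceiling(ns_col / config$district_streets)
  district_id <- sprintf("d%02d", d_row * nd_col + d_col + 1L)
  streets <- unique(data.frame(street_id = cells$street_id,
                               district_id = district_id,
                               stringsAsFactors = FALSE))
  streets <- streets[order(streets$street_id), , drop = FALSE]
  rownames(streets) <- NULL

  # population: uniform floor plus Gaussian city-core kernels
  kx <- stats::runif(config$n_kernels, 0, side)
  ky <- stats::runif(config$n_kernels, 0, side)
  bw <- config$kernel_sd * side
  kern <- rep(0, nrow(cells))
  for (k in seq_len(config$n_kernels)) {
    kern <- kern + exp(-((cells$x - kx[k])^2 + (cells$y - ky[k])^2) / (2 * bw^2))
  }
  w <- 1 + config$clustering * kern
  cells$population <- apportion_population(config$population_total, w)

  # parks
  types <- rep(names(config$n_parks_by_type), config$n_parks_by_type)
  n_p <- length(types)
  px <- stats::runif(n_p, 0, side)
  py <- stats::runif(n_p, 0, side)
  area <- numeric(n_p)
  for (i in seq_len(n_p)) {
    rg <- config$park_area_ranges[[types[i]]]
    area[i] <- exp(stats::runif(1, log(rg[1]), log(rg[2])))
  }
  entrances <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    n_e <- sample(1:4, 1)
    r <- sqrt(area[i] / pi)
    ang <- stats::runif(n_e, 0, 2 * pi)
    entrances[[i]] <- cbind(x = px[i] + r * cos(ang), y = py[i] + r * sin(ang))
  }
  parks <- data.frame(park_id = sprintf("p%04d", seq_len(n_p)),
                      type = types, x = px, y = py, area_m2 = area,
                      capacity = park_capacity(area, types),
                      stringsAsFactors = FALSE)
  parks$entrances <- I(entrances)

  travel_times <- lapply(names(config$mode_speeds), function(mode) {
    build_travel_time_matrix(cells, parks, mode, config)
  })
  names(travel_times) <- names(config$mode_speeds)

  structure(list(cells = cells, parks = parks, streets = streets,
                 travel_times = travel_times, config = config),
            class = "city_dataset")
}

#' @export
print.city_dataset <- function(x, ...) {
  cat(sprintf("city_dataset: %d cells (%d x %d of %g m), %d parks, %d streets, %s residents\n",
              nrow(x$cells), x$config$grid_extent, x$config$grid_extent,
              x$config$cell_size, nrow(x$parks), nrow(x$streets),
              format(sum(x$cells$population), big.mark = ",")))
  invisible(x)
}

#' Travel-time matrix from cell centroids to park entrances
#'
#' Travel time in minutes from every cell centroid to every park, using
#' the Euclidean distance to the park's nearest entrance, inflated by the
#' network detour factor and divided by the mode speed:
#' `t = distance_km * detour / speed_kmh * 60`.  Halving the speed doubles
#' every entry.
#'
#' @param cells Cell table with `cell_id`, `x`, `y`.
#' @param parks Park table with `park_id` and an `entrances` list column.
#' @param mode One of `names(config$mode_speeds)`.
#' @param config A [city_config()] supplying speeds and detour factor.
#' @return A [travel_time_matrix()] (cells x parks, minutes).
#' @export
build_travel_time_matrix <- function(cells, parks, mode, config) {
  if (nrow(cells) == 0 || nrow(parks) == 0) {
    stop("cells and parks must be nonempty", call. = FALSE)
  }
  if (!mode %in% names(config$mode_speeds)) {
    stop("unknown travel mode '", mode, "'; configured modes: ",
         paste(names(config$mode_speeds), collapse = ", "), call. = FALSE)
  }
  speed <- config$mode_speeds[[mode]]
  tt <- matrix(NA_real_, nrow(cells), ncol = nrow(parks),
               dimnames = list(cells$cell_id, parks$park_id))
  for (j in seq_len(nrow(parks))) {
    e <- parks$entrances[[j]]
    dmin <- rep(Inf, nrow(cells))
    for (r in seq_len(nrow(e))) {
      dmin <- pmin(dmin, sqrt((cells$x - e[r, 1])^2 + (cells$y - e[r, 2])^2))
    }
    tt[, j] <- dmin * config$detour_factor / 1000 / speed * 60
  }
  travel_time_matrix(tt, mode = mode, t0 = 15)
}
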