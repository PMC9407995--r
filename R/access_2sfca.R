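#' Per-capita park area standards by park type
#'
#' National code-based per-capita area standards used to convert a park's
#' area into the population it can serve (its supply capacity).  Parks are
#' typed I--IV: comprehensive (60 m2/person), theme (50), community (40)
#' and amusement (30).
#'
#' @return Named numeric vector of m2-per-person standards.
#' @export
#' @examples
#' pgs_standards()
pgs_standards <- function() {
  c(comprehensive = 60, theme = 50, community = 40, amusement = 30)
}

#' Park supply capacity
#'
#' Converts park area into the number of persons the park can serve,
#' `S_j = area / standard(type)`, where the per-capita standard depends on
#' the park type.
#'
#' @param area Park area in m2 (vectorised). Must be > 0.
#' @param type Park type, one of `names(standards)` (recycled against
#'   `area`).
#' @param standards Named vector of per-capita area standards
#'   (m2/person); defaults to [pgs_standards()].
#' @return Numeric vector of capacities in persons.
#' @export
#' @examples
#' park_capacity(60, "comprehensive")   # 1 person
#' park_capacity(5000, "theme")         # 100 persons
park_capacity <- function(area, type, standards = pgs_standards()) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("park area must be a positive, finite number of m2", call. = FALSE)
  }
  unknown <- setdiff(unique(type), names(standards))
  if (length(unknown)) {
    stop("unknown park type(s) ", paste(unknown, collapse = ", "),
         "; valid types: ", paste(names(standards), collapse = ", "),
         call. = FALSE)
  }
  if (any(standards <= 0)) stop("standards must be positive", call. = FALSE)
  unname(area / standards[type])
}

#' Gaussian travel-impedance weight
#'
#' Normalised Gaussian distance decay on travel time `t` with catchment
#' threshold `t0`:
#' `G(t, t0) = (exp(-(1/2)(t/t0)^2) - exp(-1/2)) / (1 - exp(-1/2))`
#' for `t <= t0`, and 0 beyond the threshold.  The weight is 1 at `t = 0`,
#' falls strictly monotonically, and reaches 0 continuously at `t = t0`.
#'
#' @param t Travel time(s), minutes, >= 0.
#' @param t0 Catchment time threshold, minutes, > 0 (default 15).
#' @return Weights in \[0, 1\], same length as `t`.
#' @export
#' @examples
#' gaussian_decay(c(0, 7.5, 15), t0 = 15)
gaussian_decay <- function(t, t0 = 15) {
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 <= 0) {
    stop("t0 must be a single positive number of minutes", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("travel times must be finite and >= 0", call. = FALSE)
  }
  half <- exp(-0.5)
  w <- (exp(-0.5 * (t / t0)^2) - half) / (1 - half)
  w[t > t0] <- 0
  w
}

#' Construct a travel-time matrix object
#'
#' Wraps a complete cells-by-parks matrix of travel times (minutes) with
#' its travel mode label and catchment threshold.
#'
#' @param entries Numeric matrix, rows = demand cells, columns = parks,
#'   all entries finite and >= 0.  Dimnames should carry cell and park ids.
#' @param mode Travel-mode label (e.g. `"walking"`).
#' @param t0 Catchment threshold in minutes attached to the matrix.
#' @return A `travel_time_matrix` (a classed numeric matrix).
#' @export
travel_time_matrix <- function(entries, mode, t0 = 15) {
  entries <- as.matrix(entries)
  if (any(!is.finite(entries)) || any(entries < 0)) {
    stop("travel-time entries must be finite and >= 0", call. = FALSE)
  }
  structure(entries, mode = mode, t0 = t0,
            class = c("travel_time_matrix", "matrix", "array"))
}

#' @export
print.travel_time_matrix <- function(x, ...) {
  cat(sprintf("travel_time_matrix: %d cells x %d parks, mode = %s, t0 = %g min\n",
              nrow(x), ncol(x), attr(x, "mode"), attr(x, "t0")))
  invisible(x)
}

resolve_t0 <- function(ttm, t0) {
  if (!is.null(t0)) return(t0)
  t0 <- attr(ttm, "t0")
  if (is.null(t0)) 15 else t0
}

#' Step 1 of 2SFCA: park supply--demand ratios
#'
#' For every park `j`, computes the ratio of its supply capacity to the
#' Gaussian-weighted population inside its catchment:
#' `R_j = S_j / sum_k G(t_kj, t0) * P_k` over cells with `t_kj <= t0`.
#' A park whose catchment holds no population gets `R_j = 0` and is
#' flagged `unreached` (with a warning): such a park's capacity cannot be
#' distributed, so it is excluded from mass-conservation accounting.
#'
#' @param parks Data frame with columns `park_id` and `capacity`
#'   (persons), as produced by [generate_city()] or [read_parks_csv()].
#' @param cells Data frame with columns `cell_id` and `population`.
#' @param ttm A [travel_time_matrix()] over exactly these cells and parks.
#' @param t0 Catchment threshold (minutes); defaults to the matrix's own.
#' @return Data frame: `park_id`, `capacity`, `weighted_demand`, `ratio`,
#'   `unreached`.
#' @export
supply_demand_ratios <- function(parks, cells, ttm, t0 = NULL) {
  t0 <- resolve_t0(ttm, t0)
  check_ttm_alignment(ttm, cells, parks)
  W <- gaussian_decay(as.vector(ttm), t0)
  W <- matrix(W, nrow(ttm), ncol(ttm))
  demand <- as.vector(crossprod(W, cells$population))
  ratio <- ifelse(demand > 0, parks$capacity / demand, 0)
  unreached <- demand <= 0
  if (any(unreached)) {
    warning(sum(unreached), " park(s) have no population within t0; ",
            "their supply-demand ratio is set to 0", call. = FALSE)
  }
  data.frame(park_id = parks$park_id, capacity = parks$capacity,
             weighted_demand = demand, ratio = ratio,
             unreached = unreached, stringsAsFactors = FALSE)
}

check_ttm_alignment <- function(ttm, cells, parks) {
  if (nrow(ttm) != nrow(cells) || ncol(ttm) != nrow(parks)) {
    stop("travel-time matrix dimensions (", nrow(ttm), " x ", ncol(ttm),
         ") do not match cells (", nrow(cells), ") and parks (",
         nrow(parks), ")", call. = FALSE)
  }
  if (!is.null(rownames(ttm)) && !identical(rownames(ttm), as.character(cells$cell_id))) {
    stop("travel-time matrix rows are not aligned with the cell table", call. = FALSE)
  }
  if (!is.null(colnames(ttm)) && !identical(colnames(ttm), as.character(parks$park_id))) {
    stop("travel-time matrix columns are not aligned with the park table", call. = FALSE)
  }
  invisible(TRUE)
}

#' Step 2 of 2SFCA: per-cell accessibility scores
#'
#' Sums Gaussian-weighted supply--demand ratios reachable from each cell:
#' `A_i = sum_j G(t_ij, t0) * R_j` over parks with `t_ij <= t0`.  `A_i` is
#' dimensionless service capacity per person; cells with no park within
#' `t0` score 0.  When every park's catchment holds population, the
#' population-weighted total `sum_i P_i A_i` equals the total park
#' capacity `sum_j S_j`.
#'
#' @param cells Cell table (`cell_id`, `population`, optionally
#'   `street_id`).
#' @param parks Park table (`park_id`, `capacity`).
#' @param ratios Result of [supply_demand_ratios()] computed with the same
#'   matrix and threshold.
#' @param ttm The same [travel_time_matrix()].
#' @param t0 Catchment threshold (minutes); defaults to the matrix's own.
#' @return An `accessibility_field`: list with `mode`, `t0`, `cells`
#'   (cell table plus `accessibility`), and `ratios`.
#' @export
accessibility_scores <- function(cells, parks, ratios, ttm, t0 = NULL) {
  t0 <- resolve_t0(ttm, t0)
  check_ttm_alignment(ttm, cells, parks)
  if (!identical(as.character(ratios$park_id), as.character(parks$park_id))) {
    stop("supply-demand ratios were computed for a different park set",
         call. = FALSE)
  }
  W <- gaussian_decay(as.vector(ttm), t0)
  W <- matrix(W, nrow(ttm), ncol(ttm))
  a <- as.vector(W %*% ratios$ratio)
  out <- cells
  out$accessibility <- a
  structure(list(mode = attr(ttm, "mode"), t0 = t0,
                 cells = out, ratios = ratios),
            class = "accessibility_field")
}

#' @export
print.accessibility_field <- function(x, ...) {
  cat(sprintf("accessibility_field (%s, t0 = %g min): %d cells, %d parks\n",
              x$mode, x$t0, nrow(x$cells), nrow(x$ratios)))
  cat(sprintf("  A_i: min %.4g, mean %.4g, max %.4g; %d unreached park(s)\n",
              min(x$cells$accessibility), mean(x$cells$accessibility),
              max(x$cells$accessibility), sum(x$ratios$unreached)))
  invisible(x)
}

as_zone_map <- function(zones) {
  if (is.data.frame(zones)) {
    if (!all(c("cell_id", "zone") %in% names(zones))) {
      stop("zone mapping data frame needs columns cell_id and zone", call. = FALSE)
    }
    stats::setNames(as.character(zones$zone), as.character(zones$cell_id))
  } else if (!is.null(names(zones))) {
    stats::setNames(as.character(zones), names(zones))
  } else {
    stop("zones must be a data frame (cell_id, zone) or a named vector",
         call. = FALSE)
  }
}

#' Aggregate cell accessibility to zone means
#'
#' Averages per-cell accessibility within zones (streets or districts),
#' either as a simple arithmetic mean over member cells (default) or as a
#' population-weighted mean.
#'
#' @param field An `accessibility_field` from [accessibility_scores()].
#' @param zones Mapping from cells to zones: a data frame with columns
#'   `cell_id` and `zone`, or a named character vector `cell_id -> zone`.
#'   Every cell in the field must be mapped.
#' @param scheme `"simple-mean"` or `"population-weighted-mean"`.
#' @return Data frame: `zone`, `mean_accessibility`, `n_cells`,
#'   `population`, sorted by zone.
#' @export
aggregate_by_zone <- function(field, zones,
                              scheme = c("simple-mean", "population-weighted-mean")) {
  scheme <- match.arg(scheme)
  map <- as_zone_map(zones)
  cells <- field$cells
  ids <- as.character(cells$cell_id)
  missing <- setdiff(ids, names(map))
  if (length(missing)) {
    stop("cell(s) not mapped to any zone: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  z <- map[ids]
  a <- cells$accessibility
  p <- cells$population
  zs <- sort(unique(z))
  mean_a <- vapply(zs, function(zz) {
    at <- z == zz
    if (scheme == "simple-mean") {
      mean(a[at])
    } else {
      if (sum(p[at]) == 0) {
        warning("zone ", zz, " has zero population; weighted mean is NA",
                call. = FALSE)
        NA_real_
      } else {
        sum(a[at] * p[at]) / sum(p[at])
      }
    }
  }, numeric(1))
  data.frame(zone = zs,
             mean_accessibility = unname(mean_a),
             n_cells = as.vector(table(z)[zs]),
             population = unname(vapply(zs, function(zz) sum(p[z == zz]), numeric(1))),
             row.names = NULL, stringsAsFactors = FALSE)
}
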