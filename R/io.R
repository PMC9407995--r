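#' Write city tables to CSV
#'
#' Writes `cells.csv` (cell_id, x, y, population, street_id), `parks.csv`
#' (park_id, type, x, y, area_m2, capacity, entrances as a JSON list
#' column) and `streets.csv` (street_id, district_id) into a directory.
#'
#' @param city A `city_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_city_csv <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- city$cells[, c("cell_id", "x", "y", "population", "street_id")]
  parks <- city$parks
  parks$entrances <- vapply(parks$entrances, function(e) {
    as.character(jsonlite::toJSON(unname(apply(e, 1, as.numeric,
                                               simplify = FALSE)),
                                  digits = NA))
  }, character(1))
  paths <- c(cells = file.path(dir, "cells.csv"),
             parks = file.path(dir, "parks.csv"),
             streets = file.path(dir, "streets.csv"))
  utils::write.csv(cells, paths["cells"], row.names = FALSE)
  utils::write.csv(parks, paths["parks"], row.names = FALSE)
  utils::write.csv(city$streets, paths["streets"], row.names = FALSE)
  invisible(paths)
}

#' Read a demand-cell table
#'
#' Expects columns `cell_id`, `x`, `y`, `population`, `street_id`.
#'
#' @param path CSV path.
#' @return Cell data frame.
#' @export
read_cells_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "population", "street_id")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop("cells file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(cells$population < 0)) {
    stop("cell populations must be >= 0", call. = FALSE)
  }
  cells
}

#' Read a park table
#'
#' Expects columns `park_id`, `type`, `area_m2` and either an `entrances`
#' JSON list column (`[[x, y], ...]`) or `x`/`y` park coordinates used as
#' a single entrance.  Capacity is derived from area and type.
#'
#' @param path CSV path.
#' @param standards Per-capita area standards, see [pgs_standards()].
#' @return Park data frame with `capacity` and an `entrances` list column.
#' @export
read_parks_csv <- function(path, standards = pgs_standards()) {
  parks <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("park_id", "type", "area_m2")
  missing <- setdiff(need, names(parks))
  if (length(missing)) {
    stop("parks file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("entrances" %in% names(parks)) {
    ent <- lapply(parks$entrances, function(s) {
      m <- jsonlite::fromJSON(s)
      matrix(as.numeric(m), ncol = 2, dimnames = list(NULL, c("x", "y")))
    })
  } else if (all(c("x", "y") %in% names(parks))) {
    ent <- lapply(seq_len(nrow(parks)), function(i) {
      cbind(x = parks$x[i], y = parks$y[i])
    })
  } else {
    stop("parks file needs either an 'entrances' JSON column or x/y ",
         "coordinates", call. = FALSE)
  }
  parks$capacity <- park_capacity(parks$area_m2, parks$type, standards)
  parks$entrances <- I(ent)
  parks
}

#' Write / read a travel-time matrix as long-format CSV
#'
#' Long format: `cell_id`, `park_id`, `mode`, `minutes`, one row per
#' cell-park pair.
#'
#' @param ttm A [travel_time_matrix()].
#' @param path CSV path.
#' @return `write_travel_times_csv()` returns `path` invisibly.
#' @export
write_travel_times_csv <- function(ttm, path) {
  long <- data.frame(cell_id = rep(rownames(ttm), ncol(ttm)),
                     park_id = rep(colnames(ttm), each = nrow(ttm)),
                     mode = attr(ttm, "mode"),
                     minutes = as.vector(ttm),
                     stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_travel_times_csv
#' @param mode Mode to extract when the file holds several.
#' @param t0 Catchment threshold attached to the matrix.
#' @export
read_travel_times_csv <- function(path, mode, t0 = 15) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "park_id", "mode", "minutes")
  missing <- setdiff(need, names(long))
  if (length(missing)) {
    stop("travel-time file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long <- long[long$mode == mode, , drop = FALSE]
  if (!nrow(long)) {
    stop("no travel times for mode '", mode, "' in ", path, call. = FALSE)
  }
  cells <- unique(long$cell_id)
  parks <- unique(long$park_id)
  m <- matrix(NA_real_, length(cells), length(parks),
              dimnames = list(cells, parks))
  m[cbind(match(long$cell_id, cells), match(long$park_id, parks))] <- long$minutes
  if (any(is.na(m))) {
    stop("travel-time table is incomplete over the cell x park grid",
         call. = FALSE)
  }
  travel_time_matrix(m, mode = mode, t0 = t0)
}

#' Write point features as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection export of point records (demand
#' cells with accessibility attributes, park entrances, ...) for use in
#' desktop GIS.  Coordinates are emitted as given (planar metres here;
#' no CRS transformation is attempted).
#'
#' @param df Data frame with coordinate columns and attribute columns.
#' @param path Output path.
#' @param x,y Names of the coordinate columns.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path, x = "x", y = "y") {
  props <- setdiff(names(df), c(x, y))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df[[x]][i], df[[y]][i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
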