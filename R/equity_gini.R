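#' Lorenz curve of service against population
#'
#' Orders units ascending by per-capita service, then accumulates
#' population share (`X_k`) and service share (`Y_k`).  The resulting
#' polyline runs from (0, 0) to (1, 1) and never rises above the equality
#' diagonal.  Units with zero population carry no per-capita service and
#' are dropped.  If the total service is zero, every unit's per-capita
#' service is identically zero and the curve is the equality diagonal.
#'
#' @param populations Persons per unit, >= 0, at least one > 0.
#' @param services Service mass per unit (e.g. accessibility mass
#'   `A_i * P_i`), >= 0.
#' @return A `lorenz_curve` data frame with columns `x` (cumulative
#'   population share) and `y` (cumulative service share), including the
#'   origin.
#' @export
#' @examples
#' lorenz_points(c(1, 1), c(0, 4))
lorenz_points <- function(populations, services) {
  if (length(populations) != length(services)) {
    stop("populations and services must have the same length", call. = FALSE)
  }
  if (any(!is.finite(populations)) || any(populations < 0)) {
    stop("populations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(services)) || any(services < 0)) {
    stop("services must be finite and >= 0", call. = FALSE)
  }
  keep <- populations > 0
  if (!any(keep)) {
    stop("all unit populations are zero; the Lorenz curve is undefined",
         call. = FALSE)
  }
  p <- populations[keep]
  s <- services[keep]
  if (sum(s) == 0) {
    # identical (zero) per-capita service everywhere: equality diagonal
    ord <- seq_along(p)
    y <- cumsum(p) / sum(p)
  } else {
    ord <- order(s / p)
    y <- cumsum(s[ord]) / sum(s)
  }
  x <- cumsum(p[ord]) / sum(p)
  structure(data.frame(x = c(0, x), y = c(0, y)),
            class = c("lorenz_curve", "data.frame"))
}

#' @export
plot.lorenz_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", xlab = "cumulative population share",
                 ylab = "cumulative service share", asp = 1, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Gini coefficient by the trapezoidal Lorenz formula
#'
#' Computes `G1 = 1 - sum_k (X_k - X_{k-1}) (Y_k + Y_{k-1})` over the
#' sorted Lorenz curve of [lorenz_points()].  G1 is 0 exactly when every
#' unit has identical per-capita service (perfect equality) and approaches
#' 1 as all service concentrates in a vanishing population share.
#'
#' @inheritParams lorenz_points
#' @param zone Optional zone label stored on the result.
#' @return A `gini_result`: list with `value`, `zone`, `n_units` (units
#'   with population), `total_population`, `total_service`.
#' @export
#' @examples
#' gini(c(1, 1), c(0, 4))$value   # 0.5
gini <- function(populations, services, zone = NA_character_) {
  lc <- lorenz_points(populations, services)
  dx <- diff(lc$x)
  ys <- lc$y[-1] + lc$y[-nrow(lc)]
  keep <- populations > 0
  structure(list(value = 1 - sum(dx * ys),
                 zone = zone,
                 n_units = sum(keep),
                 total_population = sum(populations[keep]),
                 total_service = sum(services[keep])),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("Gini %.4f over %d units (zone: %s)\n", x$value, x$n_units,
              if (is.na(x$zone)) "overall" else x$zone))
  invisible(x)
}

#' Per-zone and overall Gini of accessibility
#'
#' Treats every demand cell as a Lorenz unit with population `P_i` and
#' service mass `A_i * P_i` (default, so equality means equal per-capita
#' accessibility) or `A_i`, and computes the Gini coefficient within each
#' zone plus one overall coefficient across all cells.  Zones with no
#' populated cell are omitted with a warning.
#'
#' @param field An `accessibility_field` from [accessibility_scores()].
#' @param zones Cell-to-zone mapping as in [aggregate_by_zone()].
#' @param service Service-mass convention: `"mass"` (`A_i * P_i`) or
#'   `"accessibility"` (`A_i`).
#' @return Data frame: `zone` (including `"overall"`), `mode`, `gini`,
#'   `n_units`, `population`.
#' @export
zone_gini <- function(field, zones, service = c("mass", "accessibility")) {
  service <- match.arg(service)
  map <- as_zone_map(zones)
  cells <- field$cells
  ids <- as.character(cells$cell_id)
  missing <- setdiff(ids, names(map))
  if (length(missing)) {
    stop("cell(s) not mapped to any zone: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  z <- map[ids]
  p <- cells$population
  s <- if (service == "mass") cells$accessibility * p else cells$accessibility
  one <- function(sel, label) {
    if (!any(p[sel] > 0)) return(NULL)
    g <- gini(p[sel], s[sel], zone = label)
    data.frame(zone = label, mode = field$mode, gini = g$value,
               n_units = g$n_units, population = g$total_population,
               stringsAsFactors = FALSE)
  }
  zs <- sort(unique(z))
  rows <- lapply(zs, function(zz) one(z == zz, zz))
  empty <- zs[vapply(rows, is.null, logical(1))]
  if (length(empty)) {
    warning("zone(s) with no populated cell omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  rows <- c(rows, list(one(rep(TRUE, length(z)), "overall")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
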