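#' Cutoffs for the accessibility-by-equity street scenarios
#'
#' A street counts as high accessibility (HA) when its mean accessibility
#' strictly exceeds the mode's cutoff (walking 10, driving 1 by default),
#' and as low equity (LE) when its Gini coefficient strictly exceeds the
#' Gini cutoff (0.5 by default).  Values exactly at a cutoff are low
#' accessibility / high equity.
#'
#' @param access Named vector of per-mode accessibility cutoffs.
#' @param gini Gini cutoff in (0, 1).
#' @return A `scenario_thresholds` list.
#' @export
scenario_thresholds <- function(access = c(walking = 10, driving = 1),
                                gini = 0.5) {
  if (is.null(names(access)) || any(!is.finite(access))) {
    stop("access cutoffs must be a named vector of finite numbers",
         call. = FALSE)
  }
  if (!is.finite(gini) || gini <= 0 || gini >= 1) {
    stop("gini cutoff must lie in (0, 1)", call. = FALSE)
  }
  structure(list(access = access, gini = gini), class = "scenario_thresholds")
}

#' Classify one street (or a vector of streets) for a mode
#'
#' Crosses high/low accessibility with high/low equity into one of
#' HA-HE, HA-LE, LA-HE, LA-LE.
#'
#' @param mean_accessibility Street mean accessibility score(s).
#' @param gini Street Gini coefficient(s).
#' @param mode Travel mode; must have a cutoff in `thresholds`.
#' @param thresholds A [scenario_thresholds()].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_street(12, 0.6, "walking")   # "HA-LE"
classify_street <- function(mean_accessibility, gini, mode,
                            thresholds = scenario_thresholds()) {
  if (length(mode) != 1 || !mode %in% names(thresholds$access)) {
    stop("unknown mode '", mode, "'; thresholds defined for: ",
         paste(names(thresholds$access), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(mean_accessibility)) || any(!is.finite(gini))) {
    stop("mean accessibility and gini must be finite", call. = FALSE)
  }
  ha <- mean_accessibility > thresholds$access[[mode]]
  le <- gini > thresholds$gini
  paste0(ifelse(ha, "HA", "LA"), "-", ifelse(le, "LE", "HE"))
}

#' Classify every street in a table
#'
#' Labels each (street, mode) row of a street summary table and tallies
#' the labels per mode.  Labels partition the streets: per-label counts
#' sum to the number of streets in each mode.
#'
#' @param streets Data frame with columns `street_id`, `mode`,
#'   `mean_accessibility`, `gini`.
#' @param thresholds A [scenario_thresholds()].
#' @return A `scenario_classification`: `table` (input plus `label`) and
#'   `counts` (`mode`, `label`, `n`).
#' @export
classify_all <- function(streets, thresholds = scenario_thresholds()) {
  need <- c("street_id", "mode", "mean_accessibility", "gini")
  missing <- setdiff(need, names(streets))
  if (length(missing)) {
    stop("street table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- streets
  out$label <- NA_character_
  for (mode in unique(out$mode)) {
    at <- out$mode == mode
    out$label[at] <- classify_street(out$mean_accessibility[at],
                                     out$gini[at], mode, thresholds)
  }
  counts <- as.data.frame(table(mode = out$mode, label = out$label),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  counts <- counts[order(counts$mode, counts$label), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(table = out, counts = counts),
            class = "scenario_classification")
}

#' @export
print.scenario_classification <- function(x, ...) {
  cat("street scenario classification:\n")
  print(stats::xtabs(n ~ mode + label, data = x$counts))
  invisible(x)
}
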