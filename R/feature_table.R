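#' Names of the fifteen street-level predictors
#'
#' Three park-characteristic factors (PCAR per-capita park area, PTN park
#' type count, SAD shortest average distance to the nearest park), seven
#' built-environment factors (P_NDVI per-capita vegetation index, RD road
#' network density, RI road intersections, PC / PR / PI proportions of
#' commercial / residential / industrial land, LUM land-use mix) and five
#' socioeconomic factors (PD population density, GDP, RCG retail sales of
#' consumer goods, PFBR public-finance budget revenue, IFA fixed-asset
#' investment).
#'
#' @return Character vector of the 15 predictor names.
#' @export
pgs_predictors <- function() {
  c("PCAR", "PTN", "SAD", "P_NDVI", "RD", "RI", "PC", "PR", "PI", "LUM",
    "PD", "GDP", "RCG", "PFBR", "IFA")
}

#' Generative effect shapes for synthetic responses
#'
#' Building blocks of an [effects_spec()]: each predictor contributes an
#' additive term to the noiseless response.
#'
#' * `effect_linear(slope)`: `slope * x`.
#' * `effect_plateau(threshold, level)`: rises linearly to `level` at
#'   `x = threshold`, flat beyond it (a saturating threshold effect).
#' * `effect_peak(location, width, height)`: Gaussian bump
#'   `height * exp(-(x - location)^2 / (2 width^2))`.
#' * `effect_null()`: no contribution.
#'
#' @param slope,threshold,level,location,width,height Shape parameters on
#'   the predictor / response scale.
#' @return A `pgs_effect` object.
#' @name effects
#' @export
effect_linear <- function(slope) {
  structure(list(kind = "linear", slope = slope), class = "pgs_effect")
}

#' @rdname effects
#' @export
effect_plateau <- function(threshold, level) {
  stopifnot(threshold > 0)
  structure(list(kind = "plateau", threshold = threshold, level = level),
            class = "pgs_effect")
}

#' @rdname effects
#' @export
effect_peak <- function(location, width, height = 1) {
  stopifnot(width > 0)
  structure(list(kind = "peak", location = location, width = width,
                 height = height), class = "pgs_effect")
}

#' @rdname effects
#' @export
effect_null <- function() {
  structure(list(kind = "null"), class = "pgs_effect")
}

eval_effect <- function(e, x) {
  switch(e$kind,
         linear = e$slope * x,
         plateau = e$level * pmin(x, e$threshold) / e$threshold,
         peak = e$height * exp(-(x - e$location)^2 / (2 * e$width^2)),
         null = rep(0, length(x)),
         stop("unknown effect kind: ", e$kind, call. = FALSE))
}

#' Specify the generative response structure of a feature table
#'
#' Assigns one generative effect to each of the 15 predictors (predictors
#' not listed get [effect_null()]); the synthetic response is the sum of
#' the effects plus an intercept and Gaussian noise.  The spec is the
#' ground truth that effect-recovery tests compare against.
#'
#' @param effects Named list of `pgs_effect` objects, keyed by predictor
#'   name (see [pgs_predictors()]).
#' @param noise_sd Response-scale noise standard deviation, >= 0.
#' @param intercept Response intercept.
#' @return An `effects_spec` list.
#' @export
#' @examples
#' spec <- effects_spec(list(PD = effect_plateau(0.07, 10)), noise_sd = 0.5)
effects_spec <- function(effects = list(), noise_sd = 1, intercept = 0) {
  preds <- pgs_predictors()
  unknown <- setdiff(names(effects), preds)
  if (length(unknown)) {
    stop("effects given for unknown predictor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(effects)) {
    if (!inherits(effects[[nm]], "pgs_effect")) {
      stop("effect for ", nm, " must be built with effect_*()", call. = FALSE)
    }
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  full <- stats::setNames(lapply(preds, function(p) {
    if (p %in% names(effects)) effects[[p]] else effect_null()
  }), preds)
  structure(list(effects = full, noise_sd = noise_sd, intercept = intercept),
            class = "effects_spec")
}

# Moment-matched lognormal draw (mean m, sd s on the natural scale).
rlnorm_ms <- function(n, m, s) {
  sdl <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, log(m) - sdl^2 / 2, sdl)
}

# Street-level predictor table whose marginals emulate the descriptive
# statistics of a dense central urban area (means/sds per predictor).
generate_street_predictors <- function(street_ids, seed) {
  set.seed(seed)
  n <- length(street_ids)
  data.frame(
    street_id = street_ids,
    PCAR = rlnorm_ms(n, 0.994, 2.596),
    PTN = sample(0:4, n, replace = TRUE, prob = c(0.08, 0.27, 0.35, 0.22, 0.08)),
    SAD = rlnorm_ms(n, 0.318, 0.365),
    P_NDVI = rlnorm_ms(n, 0.091, 0.264),
    RD = rlnorm_ms(n, 0.005, 0.003),
    RI = rlnorm_ms(n, 116, 176),
    PC = rlnorm_ms(n, 0.108, 0.182),
    PR = rlnorm_ms(n, 0.398, 0.956),
    PI = rlnorm_ms(n, 0.904, 1.744),
    LUM = pmin(pmax(stats::rnorm(n, 0.587, 0.158), 0), 1),
    PD = rlnorm_ms(n, 0.026, 0.024),
    GDP = rlnorm_ms(n, 11.578, 18.257),
    RCG = rlnorm_ms(n, 9.210, 14.263),
    PFBR = rlnorm_ms(n, 0.790, 1.222),
    IFA = rlnorm_ms(n, 20.565, 45.772),
    stringsAsFactors = FALSE)
}

#' Generate a street feature table with known ground truth
#'
#' Draws the 15 street-level predictors for every street of a synthetic
#' city and constructs a response as the additive generative function of
#' an [effects_spec()] plus Gaussian noise.  The noiseless ground-truth
#' function is returned alongside so that effect-recovery (importance
#' ranking, partial-dependence shape) is testable against a known answer.
#'
#' @param city A `city_dataset` from [generate_city()].
#' @param spec An [effects_spec()] covering all 15 predictors.
#' @param seed Integer RNG seed for predictor draws and noise.
#' @return A `feature_table`: list with `table` (street_id, 15 predictors,
#'   `response`), `truth` (function mapping a predictor data frame to the
#'   noiseless response) and `spec`.
#' @export
generate_feature_table <- function(city, spec, seed = 1L) {
  if (!inherits(spec, "effects_spec")) {
    # allow hand-built lists but insist on full predictor coverage
    if (!is.list(spec) || is.null(spec$effects)) {
      stop("spec must be built with effects_spec()", call. = FALSE)
    }
  }
  missing <- setdiff(pgs_predictors(), names(spec$effects))
  if (length(missing)) {
    stop("effects spec is missing predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- generate_street_predictors(city$streets$street_id, seed = seed)
  truth <- function(data) {
    out <- rep(spec$intercept, nrow(data))
    for (p in pgs_predictors()) {
      out <- out + eval_effect(spec$effects[[p]], data[[p]])
    }
    out
  }
  tab$response <- truth(tab) + stats::rnorm(nrow(tab), 0, spec$noise_sd)
  structure(list(table = tab, truth = truth, spec = spec),
            class = "feature_table")
}
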