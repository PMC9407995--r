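#' Default pipeline configuration
#'
#' Collects every knob of the end-to-end run: city generation, catchment
#' thresholds per mode (15 min), per-capita capacity standards
#' (60/50/40/30 m2 for types I--IV), zone aggregation scheme, Gini
#' service-mass convention, boosting hyperparameters (5000 trees,
#' learning rate 0.001, 5 folds), partial-dependence and smoothing
#' settings, scenario cutoffs (walking 10, driving 1, Gini 0.5), and a
#' single seed that governs the whole run.
#'
#' @return A `pipeline_config` nested list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    city = unclass(city_config())[setdiff(names(unclass(city_config())), "seed")],
    standards = as.list(pgs_standards()),
    access = list(t0 = list(walking = 15, driving = 15),
                  scheme = "simple-mean"),
    equity = list(service = "mass"),
    gbdt = list(n_trees = 5000L, learning_rate = 0.001, max_depth = 3L,
                min_leaf = 5L, n_folds = 5L),
    effects = list(n_grid = 50L, quantile_low = 0.01, quantile_high = 0.99,
                   span = 0.5, key_threshold_pct = 7),
    scenarios = list(walking = 10, driving = 1, gini = 0.5),
    feature_noise_sd = 0,
    data = list(cells = NULL, parks = NULL, travel_times = NULL)
  ), class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      stop("unknown config key: ", path, k, call. = FALSE)
    }
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "/"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

config_city <- function(config, seed) {
  cc <- config$city
  do.call(city_config, c(
    list(grid_extent = cc$grid_extent, cell_size = cc$cell_size,
         n_parks_by_type = unlist(cc$n_parks_by_type),
         population_total = cc$population_total,
         clustering = cc$clustering, n_kernels = cc$n_kernels,
         kernel_sd = cc$kernel_sd,
         mode_speeds = unlist(cc$mode_speeds),
         detour_factor = cc$detour_factor,
         park_area_ranges = lapply(cc$park_area_ranges, unlist),
         street_cells = cc$street_cells,
         district_streets = cc$district_streets,
         seed = seed)))
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  # city block validates through its own constructor
  invisible(config_city(config, seed = 1L))
  for (mode in names(config$access$t0)) {
    t0 <- config$access$t0[[mode]]
    if (!is.finite(t0) || t0 <= 0) {
      stop("config key access/t0/", mode, " must be > 0 minutes",
           call. = FALSE)
    }
  }
  if (!config$access$scheme %in% c("simple-mean", "population-weighted-mean")) {
    stop("config key access/scheme must be 'simple-mean' or ",
         "'population-weighted-mean'", call. = FALSE)
  }
  if (!config$equity$service %in% c("mass", "accessibility")) {
    stop("config key equity/service must be 'mass' or 'accessibility'",
         call. = FALSE)
  }
  if (any(unlist(config$standards) <= 0)) {
    stop("config key standards: all per-capita standards must be > 0",
         call. = FALSE)
  }
  do.call(gbdt_control, c(config$gbdt, list(seed = 1L)))
  ef <- config$effects
  if (ef$span <= 0 || ef$span > 1) {
    stop("config key effects/span must be in (0, 1]", call. = FALSE)
  }
  if (ef$quantile_low < 0 || ef$quantile_high > 1 ||
      ef$quantile_low >= ef$quantile_high) {
    stop("config key effects/quantile_low|quantile_high must satisfy ",
         "0 <= low < high <= 1", call. = FALSE)
  }
  sc <- config$scenarios
  scenario_thresholds(access = c(walking = sc$walking, driving = sc$driving),
                      gini = sc$gini)
  if (!is.finite(config$feature_noise_sd) || config$feature_noise_sd < 0) {
    stop("config key feature_noise_sd must be >= 0", call. = FALSE)
  }
  # canonical YAML-stable form: named vectors as named lists, and the
  # real-data block always carrying its three path slots (NULL = unset)
  config$city$n_parks_by_type <- as.list(unlist(config$city$n_parks_by_type))
  config$city$mode_speeds <- as.list(unlist(config$city$mode_speeds))
  config$standards <- as.list(unlist(config$standards))
  for (k in c("cells", "parks", "travel_times")) {
    if (is.null(config$data[[k]])) config$data[k] <- list(NULL)
  }
  structure(config, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file, overlays it on [default_config()] (an empty file
#' yields the pure defaults), rejects unknown keys, and validates every
#' block against its module's constraints.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(unclass(default_config()), user))
}

#' Save a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run the full accessibility-equity-effects pipeline
#'
#' Executes the end-to-end analysis and writes every artifact to
#' `outdir`: city generation (or real-data loading), per-mode travel
#' times, Gaussian 2SFCA accessibility, street means, street/overall Gini
#' coefficients, feature-table assembly, one boosted model per response
#' (mean accessibility and Gini for each mode) with cross-validation,
#' relative importance, key variables, smoothed partial-dependence curves
#' and an OLS comparison, and finally the four-way street scenario
#' classification.  A manifest (config hash, seed, versions, file list)
#' and a plain-text summary are written alongside.  The run is a
#' deterministic function of the configuration.
#'
#' Real-data mode activates when `config$data$cells` is set: cells and
#' parks are then read from the documented CSV schemas ([read_cells_csv()],
#' [read_parks_csv()]), and travel times are either read from
#' `config$data$travel_times` or computed from entrances.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with the in-memory stage results and
#'   `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  config <- validate_config(unclass(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_stage <- function(...) message(sprintf(...))

  # one master seed, split into independent per-stage streams
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  modes <- names(unlist(config$city$mode_speeds))
  synthetic <- is.null(config$data$cells)

  city <- NULL
  dat <- stage("inputs", {
    if (synthetic) {
      city <- generate_city(config_city(config, seed = stage_seeds[1]))
      list(cells = city$cells, parks = city$parks, streets = city$streets,
           travel_times = city$travel_times)
    } else {
      cells <- read_cells_csv(config$data$cells)
      streets <- unique(cells[, "street_id", drop = FALSE])
      list(cells = cells, parks = NULL, streets = streets,
           travel_times = NULL)
    }
  })
  log_stage("inputs: %d cells, %d streets%s", nrow(dat$cells),
            nrow(dat$streets), if (synthetic) " (synthetic)" else "")

  access_fields <- stage("access", {
    if (!synthetic) {
      if (is.null(config$data$parks)) {
        stop("real-data mode needs config$data$parks (parks CSV path)")
      }
      dat$parks <- read_parks_csv(config$data$parks,
                                  standards = unlist(config$standards))
      cc <- config_city(config, seed = 1L)
      dat$travel_times <- lapply(modes, function(mode) {
        if (!is.null(config$data$travel_times)) {
          read_travel_times_csv(config$data$travel_times, mode,
                                t0 = config$access$t0[[mode]])
        } else {
          build_travel_time_matrix(dat$cells, dat$parks, mode, cc)
        }
      })
      names(dat$travel_times) <- modes
    } else {
      # synthetic parks carry capacities from the default standards table;
      # recompute under the configured standards
      dat$parks$capacity <- park_capacity(dat$parks$area_m2, dat$parks$type,
                                          unlist(config$standards))
    }
    fields <- lapply(modes, function(mode) {
      ttm <- dat$travel_times[[mode]]
      t0 <- config$access$t0[[mode]]
      ratios <- supply_demand_ratios(dat$parks, dat$cells, ttm, t0 = t0)
      accessibility_scores(dat$cells, dat$parks, ratios, ttm, t0 = t0)
    })
    names(fields) <- modes
    fields
  })
  log_stage("access: %d parks, modes %s", nrow(dat$parks),
            paste(modes, collapse = "/"))

  zone_map <- dat$cells[, c("cell_id", "street_id")]
  names(zone_map)[2] <- "zone"

  street_access <- stage("aggregate", {
    do.call(rbind, lapply(modes, function(mode) {
      agg <- aggregate_by_zone(access_fields[[mode]], zone_map,
                               scheme = config$access$scheme)
      data.frame(street_id = agg$zone, mode = mode,
                 mean_accessibility = agg$mean_accessibility,
                 n_cells = agg$n_cells, population = agg$population,
                 stringsAsFactors = FALSE)
    }))
  })

  ginis <- stage("equity", {
    do.call(rbind, lapply(modes, function(mode) {
      zone_gini(access_fields[[mode]], zone_map,
                service = config$equity$service)
    }))
  })
  log_stage("equity: %d street-mode Gini values", nrow(ginis))

  features <- stage("features", {
    assemble_feature_table(dat$streets, street_access, ginis,
                           seed = stage_seeds[2],
                           noise_sd = config$feature_noise_sd)
  })

  responses <- intersect(c(paste0("ai_", modes), paste0("gini_", modes)),
                         names(features))

  models <- stage("gbdt", {
    ctl <- gbdt_control(n_trees = config$gbdt$n_trees,
                        learning_rate = config$gbdt$learning_rate,
                        max_depth = config$gbdt$max_depth,
                        min_leaf = config$gbdt$min_leaf,
                        n_folds = config$gbdt$n_folds,
                        seed = stage_seeds[3])
    X <- features[, pgs_predictors()]
    lapply(stats::setNames(responses, responses), function(resp) {
      y <- features[[resp]]
      model <- fit_gbdt(X, y, ctl)
      cv <- cross_validate_gbdt(X, y, ctl)
      imp <- feature_importance(model)
      keys <- select_key_variables(imp, config$effects$key_threshold_pct)
      pd <- lapply(stats::setNames(keys$feature, keys$feature), function(f) {
        partial_dependence(model, X, f, n_grid = config$effects$n_grid,
                           quantile_range = c(config$effects$quantile_low,
                                              config$effects$quantile_high),
                           span = config$effects$span)
      })
      ols <- ols_fit(X, y)
      list(response = resp, model = model, cv = cv, importance = imp,
           key_variables = keys, pd = pd,
           comparison = compare_models(ols, cv))
    })
  })
  log_stage("gbdt: fitted %d response models", length(models))

  scen <- stage("scenarios", {
    st <- merge(street_access[, c("street_id", "mode", "mean_accessibility")],
                ginis[ginis$zone != "overall", c("zone", "mode", "gini")],
                by.x = c("street_id", "mode"), by.y = c("zone", "mode"))
    st <- st[order(st$mode, st$street_id), , drop = FALSE]
    sc <- config$scenarios
    classify_all(st, scenario_thresholds(
      access = c(walking = sc$walking, driving = sc$driving)[modes],
      gini = sc$gini))
  })

  stage("outputs", {
    write_city_csv(list(cells = dat$cells, parks = dat$parks,
                        streets = dat$streets), outdir)
    for (mode in modes) {
      write_travel_times_csv(dat$travel_times[[mode]],
                             file.path(outdir, paste0("travel_times_", mode, ".csv")))
      f <- access_fields[[mode]]
      utils::write.csv(f$cells, file.path(outdir, paste0("accessibility_", mode, ".csv")),
                       row.names = FALSE)
      utils::write.csv(f$ratios, file.path(outdir, paste0("park_ratios_", mode, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(street_access, file.path(outdir, "street_accessibility.csv"),
                     row.names = FALSE)
    utils::write.csv(ginis, file.path(outdir, "gini.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(outdir, "feature_table.csv"),
                     row.names = FALSE)
    for (resp in responses) {
      m <- models[[resp]]
      write_gbdt_json(m$model, file.path(outdir, paste0("gbdt_", resp, ".json")))
      utils::write.csv(m$importance,
                       file.path(outdir, paste0("importance_", resp, ".csv")),
                       row.names = FALSE)
      utils::write.csv(m$key_variables,
                       file.path(outdir, paste0("key_variables_", resp, ".csv")),
                       row.names = FALSE)
      if (length(m$pd)) {
        pd_all <- do.call(rbind, lapply(names(m$pd), function(f) {
          cbind(feature = f, as.data.frame(m$pd[[f]]))
        }))
        utils::write.csv(pd_all, file.path(outdir, paste0("pd_", resp, ".csv")),
                         row.names = FALSE)
      }
      write_json_out(list(response = resp,
                          ols_r2 = m$comparison$ols_r2,
                          gbdt_cv_r2 = m$comparison$gbdt_cv_r2,
                          difference = m$comparison$difference,
                          fold_r2 = m$cv$fold_r2),
                     file.path(outdir, paste0("comparison_", resp, ".json")))
    }
    utils::write.csv(scen$table, file.path(outdir, "scenarios.csv"),
                     row.names = FALSE)
    write_json_out(scen$counts, file.path(outdir, "scenario_counts.json"))

    cfg_path <- file.path(outdir, "config.yaml")
    save_config(config, cfg_path)

    summ <- c(
      sprintf("greenaccess pipeline run (seed %d)", config$seed),
      sprintf("cells: %d, parks: %d, streets: %d, population: %d",
              nrow(dat$cells), nrow(dat$parks), nrow(dat$streets),
              sum(dat$cells$population)),
      vapply(modes, function(mode) {
        ov <- ginis[ginis$zone == "overall" & ginis$mode == mode, "gini"]
        sprintf("%s: mean A_i = %.4f, overall Gini = %.4f", mode,
                mean(access_fields[[mode]]$cells$accessibility), ov)
      }, character(1)),
      vapply(responses, function(resp) {
        m <- models[[resp]]
        sprintf("%s: GBDT CV R2 = %.3f, OLS R2 = %.3f, key variables: %s",
                resp, m$cv$mean_r2, m$comparison$ols_r2,
                paste(m$key_variables$feature, collapse = ", "))
      }, character(1)),
      "scenario counts:",
      utils::capture.output(print(stats::xtabs(n ~ mode + label,
                                               data = scen$counts))))
    writeLines(summ, file.path(outdir, "summary.txt"))

    files <- sort(setdiff(list.files(outdir), "manifest.json"))
    write_json_out(list(seed = config$seed,
                        config_md5 = unname(tools::md5sum(cfg_path)),
                        package_version = as.character(utils::packageVersion("greenaccess")),
                        r_version = R.version.string,
                        synthetic = synthetic,
                        files = files),
                   file.path(outdir, "manifest.json"))
  })
  log_stage("outputs written to %s", outdir)

  invisible(list(city = city, cells = dat$cells, parks = dat$parks,
                 streets = dat$streets, access = access_fields,
                 street_access = street_access, gini = ginis,
                 features = features, models = models, scenarios = scen,
                 outdir = outdir))
}

#' Assemble the street feature table of the pipeline
#'
#' Joins the 15 synthetic street-level predictors with the four computed
#' responses: street mean accessibility and street Gini coefficient per
#' travel mode.
#'
#' @param streets Street table (`street_id`, ...).
#' @param street_access Output of the aggregation stage (`street_id`,
#'   `mode`, `mean_accessibility`).
#' @param ginis Output of [zone_gini()] over streets (`zone`, `mode`,
#'   `gini`).
#' @param seed Seed for the predictor draws.
#' @param noise_sd Optional extra Gaussian noise added to the responses.
#' @return Data frame: `street_id`, the 15 predictors, `ai_<mode>` and
#'   `gini_<mode>` response columns.
#' @export
assemble_feature_table <- function(streets, street_access, ginis, seed = 1L,
                                   noise_sd = 0) {
  tab <- generate_street_predictors(streets$street_id, seed = seed)
  for (mode in unique(street_access$mode)) {
    sa <- street_access[street_access$mode == mode, ]
    tab[[paste0("ai_", mode)]] <-
      sa$mean_accessibility[match(tab$street_id, sa$street_id)]
    gi <- ginis[ginis$mode == mode & ginis$zone != "overall", ]
    tab[[paste0("gini_", mode)]] <- gi$gini[match(tab$street_id, gi$zone)]
  }
  resp <- setdiff(names(tab), c("street_id", pgs_predictors()))
  keep <- stats::complete.cases(tab[, resp, drop = FALSE])
  tab <- tab[keep, , drop = FALSE]
  if (noise_sd > 0) {
    for (r in resp) {
      tab[[r]] <- tab[[r]] + stats::rnorm(nrow(tab), 0, noise_sd)
    }
  }
  rownames(tab) <- NULL
  tab
}
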