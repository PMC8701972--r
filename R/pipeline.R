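#' Pipeline run configuration
#'
#' Bundles the thresholds and settings of a full model-development run.
#' Defaults are the reference workflow's constants: 75% completeness at
#' day and year level, 75% screening rule, >1% adjusted-R2 gain, VIF > 3,
#' Cook's distance > 4/n, |DFBETAS| > 2/sqrt(n), 5-fold cross-validation.
#'
#' @param seed Run seed.
#' @param world A [world_config()] for synthetic mode, or `NULL` when
#'   `input_dir` points at a world written by [write_world()].
#' @param input_dir Optional directory of on-disk inputs.
#' @param specs Candidate predictor table.
#' @param completeness Day/year completeness threshold.
#' @param screen_threshold Screening fraction.
#' @param gain_threshold Forward-selection adjusted-R2 gain rule.
#' @param vif_threshold Collinearity flag level.
#' @param cv_k,cv_repeats Cross-validation shape.
#' @param max_removals Cap for [sequential_removal()].
#' @param map_extent Extent mapped by the prediction stage (defaults to
#'   the central 20 km of the world).
#' @param map_cell_size Prediction grid cell size (metres).
#' @param radii Buffer radius whitelist (ascending, unique).
#' @return A `lur_run_config` list.
#' @export
run_config <- function(seed = 1L, world = world_config(seed), input_dir = NULL,
                       specs = default_predictor_specs(),
                       completeness = 0.75, screen_threshold = 0.75,
                       gain_threshold = 0.01, vif_threshold = 3,
                       cv_k = 5L, cv_repeats = 50L, max_removals = 10L,
                       map_extent = NULL, map_cell_size = 100,
                       radii = lur_buffer_radii()) {
  stopifnot(completeness > 0, screen_threshold > 0, gain_threshold > 0,
            vif_threshold > 0, cv_k >= 2, cv_repeats >= 1,
            !is.unsorted(radii, strictly = TRUE))
  if (nrow(specs) == 0) abort("run_config(): no candidates (empty predictor table)")
  structure(
    list(seed = as.integer(seed), world = world, input_dir = input_dir,
         specs = specs, completeness = completeness,
         screen_threshold = screen_threshold,
         gain_threshold = gain_threshold, vif_threshold = vif_threshold,
         cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
         max_removals = as.integer(max_removals),
         map_extent = map_extent, map_cell_size = map_cell_size,
         radii = radii),
    class = "lur_run_config"
  )
}

#' Read a synthetic world written by [write_world()]
#'
#' @param dir Directory of `.asc` rasters, GeoJSON vectors, and CSV/YAML
#'   site and truth tables.
#' @return A list with `layers`, `sites`, `annual`, and `truth`.
#' @export
read_world <- function(dir) {
  ascs <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  layers <- setNames(lapply(ascs, read_ascii_grid),
                     sub("\\.asc$", "", basename(ascs)))
  for (nm in names(layers)) layers[[nm]]$name <- nm
  roads_path <- file.path(dir, "roads.geojson")
  if (file.exists(roads_path)) layers$roads <- read_roads_geojson(roads_path)
  ps_path <- file.path(dir, "power_stations.geojson")
  if (file.exists(ps_path)) layers$power_stations <- read_points_geojson(ps_path)
  sites <- readr::read_csv(file.path(dir, "sites.csv"),
                           show_col_types = FALSE)
  annual <- readr::read_csv(file.path(dir, "annual_truth.csv"),
                            show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path)
  list(layers = layers, sites = sites, annual = annual, truth = truth)
}

#' Run the full LUR pipeline
#'
#' Executes the stages in order — measurements QC, predictor extraction +
#' screening + standardization, forward selection, diagnostics with
#' sequential influential-site removal and refit, Moran's I on residuals,
#' repeated cross-validation, gridded prediction with population-weighted
#' township aggregation — and writes every artefact to `out_dir`, each
#' stamped with the configuration hash and seed. A failing stage halts the
#' run with the stage name; artefacts already written are retained.
#' Deterministic stages are bit-identical across reruns of the same
#' config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results: `annual`,
#'   `model`, `model_refit`, `diagnostics`, `moran`, `cv`, `grid`,
#'   `townships`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "input_dir")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  world <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      w <- read_world(config$input_dir)
      w$config <- config$world %||% world_config(config$seed)
      w
    } else {
      generate_world(config$world, specs = config$specs)
    }
  })

  annual <- stage("qc", {
    series <- generate_hourly_series(
      rename(world$annual, mean_ppb = "no2_ppb"), world$config)
    qc <- qc_annual_means(series, world$config$year,
                          min_day_fraction = config$completeness)
    readr::write_csv(qc, file.path(out_dir, "annual_means.csv"))
    filter(qc, .data$retained)
  })

  zdata <- stage("extract", {
    pm <- if (!is.null(world$predictors)) world$predictors else
      build_predictor_matrix(world$sites, world$layers, config$specs)
    pm <- pm[pm$site_id %in% annual$site_id, , drop = FALSE]
    attr(pm, "predictor_info") <- config$specs
    z <- standardize_predictors(
      screen_predictors(pm, config$screen_threshold))
    readr::write_csv(z, file.path(out_dir, "design_matrix.csv"))
    yaml::write_yaml(
      list(config_hash = cfg_hash, seed = config$seed,
           columns = purrr::transpose(as.list(standardization_stats(z)))),
      file.path(out_dir, "design_matrix_stats.yaml"))
    z
  })

  data <- dplyr::inner_join(zdata, select(annual, "site_id", "mean_ppb"),
                            by = "site_id")
  attributes(data)$predictor_info <- predictor_info(zdata)
  attributes(data)$standardization <- standardization_stats(zdata)

  model <- stage("build", {
    m <- forward_select(data, "mean_ppb",
                        gain_threshold = config$gain_threshold)
    if (nrow(m$terms) == 0) abort("no candidates passed the selection rules")
    write_lur_model(m, file.path(out_dir, "model.yaml"))
    readr::write_csv(m$trace, file.path(out_dir, "selection_trace.csv"))
    m
  })

  diag_out <- stage("diagnose", {
    sel <- model$terms$column
    sites_xy <- world$sites[match(data$site_id, world$sites$site_id), ]
    cleaned <- sequential_removal(data, "mean_ppb", sel,
                                  max_removals = config$max_removals)
    refit <- fit_ols(cleaned, "mean_ppb", sel)
    vt <- if (length(sel) >= 2) {
      vif_table(cleaned, sel, threshold = config$vif_threshold)
    }
    infl <- influence_table(refit, site_id = cleaned$site_id)
    kept_xy <- sites_xy[match(cleaned$site_id, sites_xy$site_id), ]
    moran <- morans_i(resid(refit$fit), kept_xy$x, kept_xy$y,
                      seed = config$seed)
    readr::write_csv(infl, file.path(out_dir, "influence.csv"))
    rl <- removal_log(cleaned)
    readr::write_csv(select(rl, -"coef_before", -"coef_after"),
                     file.path(out_dir, "removals.csv"))
    yaml::write_yaml(list(config_hash = cfg_hash,
                          vif = if (!is.null(vt)) purrr::transpose(as.list(vt)),
                          moran = as.list(select(moran, -"scheme"))),
                     file.path(out_dir, "diagnostics.yaml"))
    list(cleaned = cleaned, refit = refit, vif = vt, influence = infl,
         moran = moran, removal_log = rl)
  })

  cv <- stage("validate", {
    cvr <- kfold_cv(diag_out$cleaned, "mean_ppb", model$terms$column,
                    k = config$cv_k, n_repeats = config$cv_repeats,
                    seed = config$seed)
    readr::write_csv(tidy(cvr), file.path(out_dir, "cv_repeats.csv"))
    yaml::write_yaml(c(list(config_hash = cfg_hash),
                       as.list(glance(cvr))),
                     file.path(out_dir, "cv_summary.yaml"))
    cvr
  })

  maps <- stage("predict", {
    e <- world$config$extent
    map_extent <- config$map_extent %||% {
      cx <- mean(e[c("xmin", "xmax")]); cy <- mean(e[c("ymin", "ymax")])
      c(xmin = cx - 10000, xmax = cx + 10000,
        ymin = cy - 10000, ymax = cy + 10000)
    }
    refit_model <- new_lur_model(
      intercept = unname(coef(diag_out$refit$fit)[1]),
      terms = mutate(model$terms,
                     beta = unname(coef(diag_out$refit$fit)[-1])),
      fit = diag_out$refit, stats = model$stats,
      gain_threshold = model$gain_threshold)
    grid <- predict_grid(refit_model, world$layers, config$specs,
                         map_extent, cell_size = config$map_cell_size)
    write_ascii_grid(grid, file.path(out_dir, "prediction.asc"))
    pop <- generate_population(world$config,
                               cell_size = config$map_cell_size,
                               extent = map_extent)
    townships <- generate_townships(map_extent, 4L, 4L)
    agg <- pop_weighted_aggregate(grid, pop, townships)
    readr::write_csv(agg, file.path(out_dir, "townships.csv"))
    readr::write_csv(aggregate_percentiles(agg),
                     file.path(out_dir, "township_percentiles.csv"))
    list(grid = grid, townships = agg, model = refit_model)
  })

  yaml::write_yaml(list(config_hash = cfg_hash, seed = config$seed,
                        n_sites_qc = nrow(annual),
                        n_sites_final = nrow(diag_out$cleaned),
                        terms = model$terms$column,
                        adj_r2 = diag_out$refit$adj_r2),
                   file.path(out_dir, "run_manifest.yaml"))
  invisible(list(annual = annual, model = model,
                 model_refit = maps$model, diagnostics = diag_out,
                 moran = diag_out$moran, cv = cv, grid = maps$grid,
                 townships = maps$townships, config_hash = cfg_hash))
}
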