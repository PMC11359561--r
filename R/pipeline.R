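# End-to-end orchestration: simulate (optional) -> cluster -> screen ->
# preprocess -> train -> predict -> intervals -> evaluate, persisting every
# intermediate artefact as plain text under the output directory. All
# randomness derives from one root seed.

#' Assemble and validate a pipeline run configuration
#'
#' Either supply `stations`, `pois`, and `panel` file paths, or set
#' `synthetic = TRUE` to generate data with [synth_config()] (extra
#' generator arguments go in `generator`).
#'
#' @param synthetic generate the input data instead of reading files.
#' @param stations,pois,panel input file paths (ignored when synthetic).
#' @param generator named list of [synth_config()] overrides.
#' @param target_station target station id; defaults to the first station.
#' @param k cluster count for the POI clustering cut; defaults to the
#'   generator's planted cluster count when synthetic, else 4.
#' @param radius_km POI assignment radius.
#' @param station_r_min Pearson threshold for correlated-station screening.
#' @param feature_r_min absolute-correlation threshold for feature
#'   screening.
#' @param window_d input window length.
#' @param horizons integer vector of forecast horizons (a model is trained
#'   per horizon).
#' @param model named list of [convformer_config()] overrides.
#' @param alphas interval confidence levels.
#' @param error_split split whose residuals feed the KDE
#'   (`"train"` default; `"val"` supported).
#' @param max_test_windows optional evenly spaced cap on the test windows
#'   evaluated (a desk-scale runtime control; `NULL` evaluates all).
#' @param seed root seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, stations = NULL, pois = NULL,
                       panel = NULL, generator = list(),
                       target_station = NULL, k = NULL, radius_km = 1.0,
                       station_r_min = 0.5, feature_r_min = 0.1,
                       window_d = 48L, horizons = 24L, model = list(),
                       alphas = c(0.85, 0.90, 0.95),
                       error_split = c("train", "val"),
                       max_test_windows = NULL, seed = 1L) {
  error_split <- match.arg(error_split)
  if (!synthetic &&
      (is.null(stations) || is.null(pois) || is.null(panel))) {
    stop_config("non-synthetic runs need stations, pois and panel paths")
  }
  structure(list(synthetic = isTRUE(synthetic), stations = stations,
                 pois = pois, panel = panel, generator = generator,
                 target_station = target_station, k = k,
                 radius_km = radius_km, station_r_min = station_r_min,
                 feature_r_min = feature_r_min,
                 window_d = as.integer(window_d),
                 horizons = as.integer(horizons), model = model,
                 alphas = alphas, error_split = error_split,
                 max_test_windows = max_test_windows,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file; top-level keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("the 'yaml' package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) stop_config("unknown config key(s): %s",
                                   paste(unknown, collapse = ", "))
  do.call(run_config, obj)
}

#' Desk-scale reference run configuration
#'
#' The packaged end-to-end reference world: a synthetic panel of about
#' 20,000 hours over 20 stations, a 48 h input window, a 24 h horizon, and
#' a deliberately small ConvFormer (16 conv channels, width 32, 2 encoder
#' layers) trained for up to 3 epochs on an evenly spaced subsample of
#' 1,200 training windows. These sizes are chosen so one full pipeline run
#' finishes in roughly two minutes on a single CPU; they are desk-scale
#' stand-ins, not tuned values (see the methods vignette).
#'
#' @param seed root seed for the run.
#' @param n_hours panel length in hours.
#' @return a `run_config`.
#' @export
reference_run_config <- function(seed = 1L, n_hours = 20000L) {
  run_config(
    synthetic = TRUE,
    generator = list(n_hours = n_hours, n_stations = 20L),
    window_d = 48L, horizons = 24L,
    model = list(conv_kernel = c(3L, 3L), conv_channels = 16L,
                 d_model = 32L, n_heads = 4L, n_layers = 2L, d_ff = 64L,
                 batch_size = 64L, max_epochs = 3L, patience = 2L,
                 max_train_windows = 1200L, max_val_windows = 300L),
    alphas = c(0.85, 0.90, 0.95), error_split = "train",
    max_test_windows = 1200L, seed = seed)
}

#' Run the full forecasting pipeline
#'
#' Executes simulate (when synthetic), POI clustering, correlated-station
#' and feature screening, gap handling, windowing, model training, point
#' prediction, KDE interval construction, and evaluation; artefacts are
#' written under `out_dir`. Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config a `run_config` (or a path readable by
#'   [read_run_config()]).
#' @param out_dir output directory.
#' @return invisibly, a list with the per-horizon `forecast`, `intervals`,
#'   and `metrics`, plus the screening results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("convformer_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  root <- config$seed

  # -- data ----------------------------------------------------------------
  if (config$synthetic) {
    gen_args <- config$generator
    gen_args$seed <- derive_seed(root, 1L)
    cfg <- do.call(synth_config, gen_args)
    stations <- generate_stations(cfg)
    panel <- generate_panel(cfg, stations)
    write_synth(stations, panel, file.path(out_dir, "data"))
    k <- config$k %||% cfg$n_clusters
  } else {
    st <- read_points(config$stations, "stations")
    pois <- read_points(config$pois, "pois")
    stations <- structure(list(stations = st, pois = pois,
                               n_categories = max(pois$category),
                               profiles = NULL), class = "station_set")
    panel <- read_panel_csv(config$panel)
    k <- config$k %||% 4L
  }
  target <- config$target_station %||% panel$station_ids[1]

  # -- clustering and station screening ------------------------------------
  stations <- build_poi_profiles(stations, radius_km = config$radius_km)
  clus <- hierarchical_cluster(stations$profiles, k = k)
  write_cluster_result(clus, file.path(out_dir, "cluster"))
  corr <- select_correlated_stations(target, clus, panel,
                                     r_min = config$station_r_min)
  utils::write.csv(corr, file.path(out_dir, "cluster", "correlated_stations.csv"),
                   row.names = FALSE)
  cf_log("info", "target %s: %d correlated stations kept", target, nrow(corr))

  # -- preprocessing -------------------------------------------------------
  series <- station_series(panel, target, corr$station_id)
  filled <- fill_gaps(series, seed = derive_seed(root, 2L))
  rep_corr <- pearson_matrix(filled)
  screening <- screen_features(rep_corr, target = "PM2.5",
                               r_min = config$feature_r_min)
  filled <- keep_features(filled, screening$kept)
  jsonlite::write_json(
    list(kept = screening$kept,
         dropped = screening$dropped,
         r_target = as.list(screening$r_target)),
    file.path(out_dir, "feature_screen.json"), auto_unbox = TRUE, digits = NA)

  results <- list()
  for (tau in config$horizons) {
    hdir <- file.path(out_dir, sprintf("h%03d", tau))
    dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
    wd <- split_and_window(filled, D = config$window_d, tau = tau)
    model_args <- config$model
    model_args$window_d <- config$window_d
    model_args$horizon_tau <- tau
    model_args$seed <- derive_seed(root, 3L)
    mcfg <- do.call(convformer_config, model_args)
    model <- build_convformer(mcfg, n_features = ncol(wd$values))
    model <- train_convformer(model, wd)
    write_checkpoint(model, file.path(hdir, "checkpoint.json"))
    utils::write.csv(model$history, file.path(hdir, "history.csv"),
                     row.names = FALSE)

    fc_err <- predict_convformer(model, wd, split = config$error_split,
                                 max_windows = mcfg$max_train_windows)
    fc_test <- predict_convformer(model, wd, split = "test",
                                  max_windows = config$max_test_windows)
    write_forecast_csv(fc_test, file.path(hdir, "predictions_test.csv"))

    dist <- collect_errors(fc_err)
    dist <- fit_error_kde(dist, max_errors = 800L,
                          seed = derive_seed(root, 4L))
    iv <- build_intervals(fc_test, dist, alphas = config$alphas)
    write_intervals_csv(iv, file.path(hdir, "intervals_test.csv"))

    metrics <- metric_report(fc_test, iv)
    metrics$point$per_step <- NULL
    jsonlite::write_json(metrics, file.path(hdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    results[[sprintf("h%03d", tau)]] <- list(forecast = fc_test,
                                             intervals = iv,
                                             metrics = metrics)
  }
  invisible(list(results = results, correlated = corr,
                 screening = screening, cluster = clus, out_dir = out_dir))
}

write_forecast_csv <- function(fc, path) {
  tau <- ncol(fc$point_predictions)
  n <- nrow(fc$point_predictions)
  df <- data.frame(
    sample = rep(seq_len(n), each = tau),
    t = rep(fc$t, each = tau),
    step = rep(seq_len(tau), n),
    prediction = as.vector(t(fc$point_predictions)),
    actual = as.vector(t(fc$actuals)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_intervals_csv <- function(iv, path) {
  rows <- lapply(seq_along(iv$levels), function(i) {
    key <- format_alpha(iv$levels[i])
    b <- iv$bounds[[key]]
    tau <- ncol(b$lower); n <- nrow(b$lower)
    data.frame(sample = rep(seq_len(n), each = tau),
               step = rep(seq_len(tau), n),
               alpha = iv$levels[i],
               lower = as.vector(t(b$lower)),
               upper = as.vector(t(b$upper)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
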