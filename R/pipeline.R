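#' End-to-end pipeline configuration
#'
#' Exactly one of `csv_path` or `sim_config` supplies the observations.
#'
#' @param csv_path path to a collar CSV, or `NULL`.
#' @param sim_config a [trajectory_config()], or `NULL`.
#' @param plantation named numeric `c(latitude=, longitude=)` hazard site.
#' @param radius_km buffer radius for the poaching rule (default 5).
#' @param mode label mode, `"latlong"` or `"spatiotemporal"`.
#' @param mlp an [mlp_config()].
#' @param baselines run the linear/polynomial/VAR baselines too.
#' @param horizon_steps number of future fixes to forecast.
#' @param cadence_hours collar cadence used for the forecast grid.
#' @param output_dir directory for graph/report/evaluation/manifest files.
#' @param seed integer seed for every stochastic stage.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(csv_path = NULL, sim_config = NULL,
                            plantation = c(latitude = 5.25, longitude = 118.70),
                            radius_km = 5, mode = c("latlong", "spatiotemporal"),
                            mlp = mlp_config(), baselines = TRUE,
                            horizon_steps = 12L, cadence_hours = 2,
                            output_dir = tempfile("poachrisk_run_"),
                            seed = 1L) {
  if (is.null(csv_path) == is.null(sim_config)) {
    stop("supply exactly one of `csv_path` or `sim_config`", call. = FALSE)
  }
  stopifnot(radius_km > 0, horizon_steps >= 1)
  mode <- match.arg(mode)
  structure(list(csv_path = csv_path, sim_config = sim_config,
                 plantation = plantation, radius_km = radius_km, mode = mode,
                 mlp = mlp, baselines = baselines,
                 horizon_steps = as.integer(horizon_steps),
                 cadence_hours = cadence_hours, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Forecast future fixes on the collar's time grid
#'
#' Builds future calendar feature rows `(day, month, year, hour)` at the
#' collar cadence, starting one step after the last observed timestamp
#' (calendar roll-over handled by real date arithmetic), and predicts
#' coordinates for each.
#'
#' @param model a fitted `"mlp_fit"`.
#' @param last_date,last_time last observed local date (`"YYYY-MM-DD"`) and
#'   time (`"HH:MM:SS"`).
#' @param horizon_steps number of future fixes (>= 1).
#' @param cadence_hours hours between fixes.
#' @return a tibble with `local_date`, `local_time`, the feature columns and
#'   the predicted label columns.
#' @export
forecast_future_fixes <- function(model, last_date, last_time,
                                  horizon_steps, cadence_hours = 2) {
  if (!is.numeric(horizon_steps) || length(horizon_steps) != 1L ||
      horizon_steps < 1) {
    stop("`horizon_steps` must be a positive count", call. = FALSE)
  }
  t_last <- as.POSIXct(paste(last_date, last_time), tz = "UTC")
  if (is.na(t_last)) stop("invalid last timestamp", call. = FALSE)
  times <- t_last + seq_len(horizon_steps) * cadence_hours * 3600
  feat <- tibble::tibble(
    day = as.integer(format(times, "%d")),
    month = as.integer(format(times, "%m")),
    year = as.integer(format(times, "%Y")),
    hour = as.integer(format(times, "%H"))
  )
  pred <- predict(model, feat)
  dplyr::bind_cols(
    tibble::tibble(local_date = format(times, "%Y-%m-%d"),
                   local_time = format(times, "%H:%M:%S")),
    feat, pred
  )
}

run_stage <- function(name, manifest_env, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest_env$timings[[name]] <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
}

#' Run the full pipeline
#'
#' Simulate or ingest observations, build the knowledge graph, extract
#' rows, train the network, forecast future fixes, insert them into the
#' graph, apply the buffer-zone poaching rule, and write the Turtle
#' graph, the poaching report, the evaluation CSV, a GeoJSON buffer ring
#' and a JSON run manifest to `config$output_dir`.  Fully reproducible
#' given the seed.
#'
#' @param config a [pipeline_config()].
#' @return a list with `evaluation` (an [evaluation_report()] tibble),
#'   `graph` (the final triple graph) and `manifest` (a list mirroring the
#'   manifest JSON).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(); env$timings <- list()
  vocab <- foo_vocabulary()
  counts <- list()
  files <- character(0)
  set.seed(config$seed)

  obs <- run_stage("ingest", env, {
    if (!is.null(config$sim_config)) {
      o <- simulate_trajectory(config$sim_config)
      csv <- file.path(config$output_dir, "observations.csv")
      write_observations_csv(o, csv)
      files <- c(files, csv)
      read_observations_csv(csv)
    } else {
      read_observations_csv(config$csv_path)
    }
  })
  counts$observations <- nrow(obs)

  graph <- run_stage("build_kg", env, {
    g <- map_observations_to_graph(obs, vocab)
    add_plantation(g, config$plantation[["latitude"]],
                   config$plantation[["longitude"]], vocab)
  })
  counts$triples_initial <- nrow(graph)

  rows <- run_stage("extract", env, select_observations(graph, vocab))
  counts$rows_extracted <- nrow(rows)

  mats <- run_stage("features", env, build_matrices(rows, mode = config$mode))
  split <- chronological_split(nrow(mats$features))

  model <- run_stage("train", env,
                     train_mlp(mats$features, mats$labels, split, config$mlp))
  test_pred <- predict(model, mats$features[split$test, ])
  test_rmse <- rmse(test_pred, mats$labels[split$test, ])

  results <- list("Sequential NN" = test_rmse$per_target)
  if (isTRUE(config$baselines)) {
    run_stage("baselines", env, {
      day_rows <- dplyr::bind_cols(mats$features["day"],
                                   rows[c("latitude", "longitude")])
      lin <- fit_linear_baseline(day_rows)
      pol <- fit_polynomial_baseline(day_rows)
      var <- fit_var_baseline(rows[c("latitude", "longitude")])
      results[["Linear Regression"]] <-
        setNames(lin$rmse$rmse, lin$rmse$target)
      results[["Polynomial Regression"]] <-
        setNames(pol$rmse$rmse, pol$rmse$target)
      results[["VAR Model"]] <- setNames(var$rmse$rmse, var$rmse$target)
      NULL
    })
  }

  preds <- run_stage("forecast", env, {
    last <- rows[nrow(rows), ]
    fc <- forecast_future_fixes(model, last$local_date, last$local_time,
                                config$horizon_steps, config$cadence_hours)
    if (config$mode == "latlong") {
      fc[, c("local_date", "local_time", "latitude", "longitude")]
    } else {
      fc[, c("local_date", "local_time", "latitude", "longitude")]
    }
  })
  counts$predictions <- nrow(preds)

  graph <- run_stage("insert_predictions", env,
                     insert_predictions(graph, preds, vocab))
  graph <- run_stage("reason", env,
                     apply_poaching_rule(graph, vocab, config$radius_km))
  counts$poaching_annotations <- attr(graph, "n_annotated")
  flags <- graph$object[graph$predicate == vocab$p_poaching]
  counts$poaching_positive <- sum(flags == "1")

  report <- run_stage("report", env, construct_poaching_report(graph, vocab))
  counts$report_triples <- nrow(report)
  counts$triples_final <- nrow(graph)

  graph_path <- file.path(config$output_dir, "graph.ttl")
  report_path <- file.path(config$output_dir, "report.ttl")
  eval_path <- file.path(config$output_dir, "evaluation.csv")
  buffer_path <- file.path(config$output_dir, "buffer.geojson")
  manifest_path <- file.path(config$output_dir, "manifest.json")
  serialize_turtle(graph, graph_path, vocab)
  serialize_turtle(report, report_path, vocab)
  evaluation <- evaluation_report(results)
  readr::write_csv(tibble::as_tibble(evaluation), eval_path, progress = FALSE)
  buffer_geojson(config$plantation[["latitude"]],
                 config$plantation[["longitude"]], config$radius_km,
                 path = buffer_path)
  files <- c(files, graph_path, report_path, eval_path, buffer_path,
             manifest_path)

  manifest <- list(
    config_digest = rlang::hash(config),
    seed = config$seed,
    counts = counts,
    files = basename(files),
    timings_s = lapply(env$timings, function(x) round(x, 3))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  missing_out <- files[!file.exists(files)]
  if (length(missing_out) > 0) {
    warning("missing output file(s): ", paste(missing_out, collapse = ", "))
  }
  list(evaluation = evaluation, graph = graph, manifest = manifest)
}
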