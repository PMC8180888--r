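#' Run the full pipeline in memory
#'
#' Simulate a seeded dataset, encode it to events, train the spiking network
#' layer by layer, fit the polynomial readout on the training split, and
#' evaluate the visibility sweep on the test split. This is the programmatic
#' equivalent of the command-line `simulate`/`train`/`fit-readout`/`predict`
#' chain.
#'
#' @param config A [pipeline_config()].
#' @param analyses Also compute direction tuning, DSI, speed selectivity and
#'   tracking profiles on the test split.
#' @param verbose Log progress.
#' @return A list: `dataset`, `network`, `readout`, `evaluation`
#'   (a `visibility_eval`), and (with `analyses = TRUE`) `tuning`, `dsi`,
#'   `speed`, `tracking`; plus `config` and its `hash`.
#' @export
run_pipeline <- function(config, analyses = FALSE, verbose = FALSE) {
  config <- validate_pipeline_config(config)
  scene <- config$scene
  log_msg <- function(...) if (verbose) message(sprintf(...))

  frontend <- config$frontend
  if (is.null(frontend)) {
    log_msg("auto-tuning frontend threshold")
    probe_cfg <- scene
    probe_cfg$noise_sigma <- 0
    probe <- with_seed(scene$seed, {
      launch <- draw_launch(scene, c(4.5, 6.5), c(25, 55), 0.72)
      render_frames(simulate_trajectory(scene, launch), probe_cfg)
    })
    base <- frontend_config(1, fps = scene$fps)
    frontend <- frontend_config(tune_threshold(probe, base), fps = scene$fps)
  }

  log_msg("simulating %d trajectories", config$n_trajectories)
  ds <- make_dataset(config$n_trajectories, scene,
                     split_fraction = config$split_fraction,
                     frontend = frontend)

  log_msg("training %d-layer network", length(config$layers))
  net <- new_network(scene$width, scene$height, layers = config$layers,
                     delays = config$delays, seed = config$seed)
  net <- train_network(net, ds$train$events, epochs = config$epochs,
                       verbose = verbose)

  log_msg("fitting readout")
  train_spikes <- run_dataset(net, ds$train)
  model <- fit_readout(train_spikes, ds$train, score = config$score)

  log_msg("evaluating visibility sweep")
  test_spikes <- run_dataset(net, ds$test)
  eval_tbl <- evaluate_visibility(net, model, ds$test, spikes = test_spikes)

  out <- list(dataset = ds, frontend = frontend, network = net,
              readout = model, evaluation = eval_tbl,
              config = config, hash = config_hash(unclass(config)))
  if (analyses) {
    curves <- direction_tuning(test_spikes, ds$test,
                               smooth_deg = config$analysis$smooth_deg)
    out$tuning <- curves
    out$dsi <- direction_selectivity_index(test_spikes, ds$test)
    out$speed <- speed_selectivity(test_spikes, ds$test, curves,
                                   n_perm = config$analysis$n_perm,
                                   alpha = config$analysis$alpha,
                                   seed = config$seed)
    out$tracking <- ball_distance(test_spikes, ds$test,
                                  threshold = config$analysis$ball_threshold)
  }
  out
}

#' Write evaluation and analysis artifacts as CSV
#'
#' Each file gets a `# hash: <config hash> seed: <seed>` comment line so
#' artifacts are traceable to the configuration that produced them.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- sprintf("# hash: %s seed: %d", result$hash, result$config$seed)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      as.data.frame(df), path, sep = ",", row.names = FALSE, append = TRUE,
      quote = FALSE))
    path
  }
  emit(result$evaluation, "evaluation.csv")
  if (!is.null(result$tuning)) {
    emit(result$tuning, "tuning_curves.csv")
    summary_tbl <- preferred_directions(result$tuning) |>
      dplyr::left_join(result$speed[, c("filter", "ks", "selective")],
                       by = "filter") |>
      dplyr::left_join(result$tracking[, c("filter", "d_n", "ball_coding")],
                       by = "filter")
    emit(summary_tbl, "filters.csv")
  }
  save_network(result$network, file.path(dir, "network.json"))
  save_readout(result$readout, file.path(dir, "readout.json"))
  invisible(dir)
}
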