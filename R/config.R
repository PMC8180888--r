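CONFIG_VERSION <- "1.0"

#' Full pipeline configuration
#'
#' Bundles scene, frontend, network, readout and analysis settings with a
#' global seed into one validated, version-stamped object that can be
#' written to and read from YAML. Unknown keys are rejected on load.
#'
#' @param scene A [scene_config()].
#' @param frontend A [frontend_config()], or `NULL` to auto-tune the
#'   threshold on the first rendered scene.
#' @param layers A list of [layer_params()].
#' @param delays A [delay_config()].
#' @param n_trajectories,split_fraction Dataset size and train fraction.
#' @param score A [score_config()].
#' @param analysis List of analysis settings (`smooth_deg`,
#'   `ball_threshold` or NULL for the scaled default, `n_perm`, `alpha`).
#' @param epochs STDP passes per layer.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list with a `version` stamp.
#' @export
pipeline_config <- function(scene = scene_config(),
                            frontend = NULL,
                            layers = default_layer_params(),
                            delays = delay_config(),
                            n_trajectories = 297, split_fraction = 0.7,
                            score = score_config(),
                            analysis = list(smooth_deg = 5,
                                            ball_threshold = NULL,
                                            n_perm = 1000, alpha = 0.05),
                            epochs = 1, seed = 1L) {
  structure(list(version = CONFIG_VERSION, scene = scene,
                 frontend = frontend, layers = layers, delays = delays,
                 n_trajectories = n_trajectories,
                 split_fraction = split_fraction,
                 score = score, analysis = analysis, epochs = epochs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_template_names <- function() {
  list(
    top = c("version", "scene", "frontend", "layers", "delays",
            "n_trajectories", "split_fraction", "score", "analysis",
            "epochs", "seed"),
    scene = names(unclass(scene_config())),
    frontend = names(unclass(frontend_config(1))),
    layer = names(unclass(default_layer_params()[[1]])),
    delays = "delays",
    score = names(unclass(score_config())),
    analysis = c("smooth_deg", "ball_threshold", "n_perm", "alpha")
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  assert_that(length(extra) == 0,
              sprintf("unknown configuration key(s) in %s: %s", where,
                      paste(extra, collapse = ", ")))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at every level and re-applies the constructors'
#' invariants.
#'
#' @param config A `pipeline_config` (or plain nested list from YAML).
#' @return The validated `pipeline_config` (classes restored), invisibly
#'   usable.
#' @export
validate_pipeline_config <- function(config) {
  tpl <- config_template_names()
  check_keys(config, tpl$top, "top level")
  check_keys(config$scene, tpl$scene, "scene")
  if (!is.null(config$frontend)) check_keys(config$frontend, tpl$frontend, "frontend")
  for (i in seq_along(config$layers))
    check_keys(config$layers[[i]], tpl$layer, sprintf("layers[[%d]]", i))
  check_keys(config$delays, tpl$delays, "delays")
  check_keys(config$score, tpl$score, "score")
  check_keys(config$analysis, tpl$analysis, "analysis")

  sc <- config$scene
  config$scene <- do.call(scene_config, sc[setdiff(names(sc), character())])
  if (!is.null(config$frontend))
    config$frontend <- do.call(frontend_config, unclass(config$frontend)[
      names(unclass(frontend_config(1)))])
  config$layers <- lapply(config$layers, function(l)
    do.call(layer_params, unclass(l)))
  config$delays <- delay_config(unlist(config$delays$delays %||% config$delays))
  s <- unclass(config$score)
  config$score <- score_config(kernel = s$kernel, tau = s$tau,
                               sigma_min = s$sigma_min, eps = s$eps)
  structure(config, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly (writer); a validated `pipeline_config`
#'   (reader).
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$scene <- structure(raw$scene, class = "scene_config")
  validate_pipeline_config(structure(raw, class = "pipeline_config"))
}

#' Save / load a network checkpoint (JSON)
#'
#' Stores layer parameters, kernel weights, the delay configuration, the
#' seed, a format version and the configuration hash.
#'
#' @param network An `snn_network`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `snn_network` (reader).
#' @export
save_network <- function(network, path) {
  layers <- lapply(network$layers, function(l) {
    list(params = l[setdiff(names(l), c("weights", "in_channels"))],
         in_channels = l$in_channels,
         dim = dim(l$weights),
         weights = as.numeric(l$weights))
  })
  obj <- list(format = "snntraj-network-1", width = network$width,
              height = network$height, delays = network$delays$delays,
              seed = network$seed, layers = layers)
  obj$hash <- config_hash(obj[setdiff(names(obj), "hash")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  assert_that(identical(obj$format, "snntraj-network-1"),
              "not an snntraj network checkpoint")
  layers <- lapply(obj$layers, function(l) {
    p <- lapply(l$params, function(v) if (length(v) == 1) v[[1]] else unlist(v))
    c(p, list(weights = array(as.numeric(unlist(l$weights)),
                              dim = as.integer(unlist(l$dim))),
              in_channels = l$in_channels[[1]]))
  })
  structure(list(width = obj$width, height = obj$height, layers = layers,
                 delays = delay_config(as.numeric(unlist(obj$delays))),
                 seed = obj$seed),
            class = "snn_network")
}

#' Save / load a fitted readout (JSON)
#'
#' @param model An `snn_readout`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `snn_readout` (reader).
#' @export
save_readout <- function(model, path) {
  obj <- list(format = "snntraj-readout-1",
              coeffs = model$coeffs, prior = model$prior,
              y_range = model$y_range, score = unclass(model$score),
              min_spikes = model$min_spikes)
  obj$hash <- config_hash(obj[setdiff(names(obj), "hash")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_readout
#' @export
load_readout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(obj$format, "snntraj-readout-1"),
              "not an snntraj readout file")
  s <- obj$score
  structure(list(coeffs = as_tibble(obj$coeffs), prior = obj$prior,
                 y_range = obj$y_range,
                 score = score_config(kernel = s$kernel, tau = s$tau,
                                      sigma_min = s$sigma_min, eps = s$eps),
                 min_spikes = obj$min_spikes),
            class = "snn_readout")
}
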