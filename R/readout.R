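#' Run a network over every trajectory of a dataset split
#'
#' Convenience wrapper: runs [run_network()] (inference) on each row's event
#' stream and stacks the spikes with the trajectory `id`.
#'
#' @param network A trained `snn_network`.
#' @param split A dataset tibble from [make_dataset()] with an `events`
#'   list-column.
#' @param layer Keep only spikes of this layer (default: the output layer);
#'   `NULL` keeps all layers.
#' @return A spike tibble with columns `id`, `t`, `layer`, `filter`, `x`,
#'   `y`, `u`.
#' @export
run_dataset <- function(network, split, layer = length(network$layers)) {
  assert_that("events" %in% names(split),
              "split needs an `events` list-column; encode the dataset first")
  rows <- purrr::map2(split$id, split$events, function(id, ev) {
    sp <- run_network(network, ev)
    dplyr::mutate(sp, id = id, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(layer)) out <- dplyr::filter(out, .data$layer == !!layer)
  out
}

#' Fit the polynomial-regression readout
#'
#' For every output-layer filter with at least `min_spikes` training spikes,
#' fits the quadratic surface
#' `Y = a00 + a10 x + a01 y + a20 x^2 + a02 y^2 + a11 x y`
#' by least squares, with the spiking neuron's map position `(x, y)` as
#' input and the trajectory's reception height as target. Each filter also
#' gets its training RMSE (the reliability weight used by the score), a
#' left/right direction label (majority ball direction over its training
#' spikes), and the global training-mean reception height used as the naive
#' prior.
#'
#' @param spikes Output-layer spike tibble with columns `id`, `filter`,
#'   `x`, `y` (e.g. from [run_dataset()]).
#' @param trajectories Tibble with one row per trajectory: `id`,
#'   `reception_y`, `direction` (a [make_dataset()] split works directly).
#' @param min_spikes Minimum training spikes for a usable filter (default 6,
#'   the coefficient count).
#' @param y_range Candidate-score range `c(min, max)` in pixels (defaults to
#'   the frame's y range inferred from the trajectories if available).
#' @param score Score-integration settings from [score_config()].
#' @return An `snn_readout` object; see [tidy.snn_readout()].
#' @export
fit_readout <- function(spikes, trajectories, min_spikes = 6,
                        y_range = NULL, score = score_config()) {
  needed <- c("id", "reception_y", "direction")
  assert_that(all(needed %in% names(trajectories)),
              "trajectories need columns id, reception_y, direction")
  df <- dplyr::inner_join(spikes,
                          trajectories[, needed],
                          by = "id")
  assert_that(nrow(df) > 0, "no spikes matched the supplied trajectories")
  if (is.null(y_range)) {
    h <- if ("truth" %in% names(trajectories))
      attr(trajectories$truth[[1]], "height") else NULL
    h <- h %||% (ceiling(max(df$reception_y)) + 1)
    y_range <- c(0, h - 1)
  }
  fits <- df |>
    dplyr::group_by(.data$filter) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < min_spikes) {
        return(tibble(filter = key$filter, n_spikes = n, usable = FALSE,
                      a00 = NA_real_, a10 = NA_real_, a01 = NA_real_,
                      a20 = NA_real_, a02 = NA_real_, a11 = NA_real_,
                      rmse = NA_real_,
                      direction = names(which.max(table(g$direction)))))
      }
      fit <- lm(reception_y ~ x + y + I(x^2) + I(y^2) + I(x * y), data = g)
      cf <- coef(fit)
      cf[is.na(cf)] <- 0  # rank-deficient positions: drop the term
      rmse <- sqrt(mean(fit$residuals^2))
      dirs <- table(g$direction)
      tibble(filter = key$filter, n_spikes = n, usable = TRUE,
             a00 = cf[["(Intercept)"]], a10 = cf[["x"]], a01 = cf[["y"]],
             a20 = cf[["I(x^2)"]], a02 = cf[["I(y^2)"]],
             a11 = cf[["I(x * y)"]],
             rmse = rmse, direction = names(which.max(dirs)))
    }) |>
    dplyr::bind_rows()
  assert_that(any(fits$usable), "no filter has enough training spikes")
  prior <- mean(trajectories$reception_y)
  structure(list(coeffs = fits, prior = prior, y_range = y_range,
                 score = score, min_spikes = min_spikes),
            class = "snn_readout")
}

#' Score-integration settings
#'
#' Each output spike adds a kernel to a 1 px-resolution score array over
#' candidate reception heights, centred on the filter's prediction with peak
#' height `1 / max(rmse, eps)` and width proportional to the RMSE (sd
#' `max(rmse, sigma_min)`), so reliable filters dominate. The whole array
#' leaks exponentially between spikes.
#'
#' @param kernel `"gaussian"` (default) or `"triangular"` (half-width
#'   `2 * max(rmse, sigma_min)`).
#' @param tau Score leak time constant in seconds (`Inf` disables the leak).
#' @param sigma_min Lower bound on the kernel width, pixels.
#' @param eps Lower bound on the RMSE used in the peak height.
#' @return A `score_config` list.
#' @export
score_config <- function(kernel = c("gaussian", "triangular"), tau = 0.5,
                         sigma_min = 1, eps = 1e-6) {
  kernel <- match.arg(kernel)
  assert_that(tau > 0, "tau must be > 0 (use Inf for no leak)")
  structure(list(kernel = kernel, tau = tau, sigma_min = sigma_min,
                 eps = eps), class = "score_config")
}

#' Evaluate a filter's quadratic prediction surface
#'
#' @param model An `snn_readout`.
#' @param filter Filter index.
#' @param x,y Map coordinates of the spiking neuron.
#' @return Predicted reception height in pixels.
#' @export
predict_y <- function(model, filter, x, y) {
  cf <- model$coeffs[model$coeffs$filter == filter, ]
  assert_that(nrow(cf) == 1 && isTRUE(cf$usable),
              sprintf("filter %s is not usable", as.character(filter)))
  cf$a00 + cf$a10 * x + cf$a01 * y + cf$a20 * x^2 + cf$a02 * y^2 +
    cf$a11 * x * y
}

#' Initialise an empty score state
#'
#' @param model An `snn_readout`.
#' @return A `score_state`: candidate heights `y_grid` (1 px bins over the
#'   model's y range), a zero `score` array, and `last_update = 0`.
#' @export
score_state <- function(model) {
  grid <- seq(floor(model$y_range[1]), ceiling(model$y_range[2]), by = 1)
  structure(list(y_grid = grid, score = numeric(length(grid)),
                 last_update = 0), class = "score_state")
}

#' Add one spike's prediction to the score
#'
#' Applies the exponential leak since the last update, then adds the
#' filter's kernel (see [score_config()]) centred on its predicted height.
#' Spikes from unusable filters are ignored.
#'
#' @param state A [score_state()].
#' @param spike One spike: a list/row with `t`, `filter`, `x`, `y`.
#' @param model An `snn_readout`.
#' @return The updated `score_state`.
#' @export
update_score <- function(state, spike, model) {
  cf <- model$coeffs[model$coeffs$filter == spike$filter, ]
  if (nrow(cf) != 1 || !isTRUE(cf$usable)) return(state)
  sc <- model$score
  if (is.finite(sc$tau) && spike$t > state$last_update)
    state$score <- state$score * exp(-(spike$t - state$last_update) / sc$tau)
  state$last_update <- max(state$last_update, spike$t)
  yp <- predict_y(model, spike$filter, spike$x, spike$y)
  peak <- 1 / max(cf$rmse, sc$eps)
  sigma <- max(cf$rmse, sc$sigma_min)
  kern <- if (sc$kernel == "gaussian") {
    peak * exp(-(state$y_grid - yp)^2 / (2 * sigma^2))
  } else {
    peak * pmax(0, 1 - abs(state$y_grid - yp) / (2 * sigma))
  }
  state$score <- state$score + kern
  state
}

#' Decode the predicted reception height from the score
#'
#' Argmax of the score array. For the Gaussian kernel the peak is refined by
#' parabolic interpolation of the log-score around the maximal bin (exact
#' for a single kernel, sub-pixel for sums). An all-zero score (no spikes
#' yet) falls back to the training-mean prior.
#'
#' @param state A [score_state()].
#' @param model An `snn_readout`.
#' @return Predicted reception height in pixels.
#' @export
decode_prediction <- function(state, model) {
  s <- state$score
  if (max(s) <= 0) return(model$prior)
  i <- which.max(s)
  if (model$score$kernel == "gaussian" && i > 1 && i < length(s) &&
      s[i - 1] > 0 && s[i + 1] > 0) {
    l <- log(s[(i - 1):(i + 1)])
    denom <- l[1] - 2 * l[2] + l[3]
    if (is.finite(denom) && denom < 0) {
      off <- 0.5 * (l[1] - l[3]) / denom
      if (abs(off) <= 0.5) return(state$y_grid[i] + off)
    }
  }
  state$y_grid[i]
}

#' Replay a set of spikes through the score
#'
#' @param spikes Spike tibble (`t`, `filter`, `x`, `y`), any order.
#' @param model An `snn_readout`.
#' @return The final `score_state` after all spikes (processed in time
#'   order).
#' @export
accumulate_score <- function(spikes, model) {
  state <- score_state(model)
  if (!nrow(spikes)) return(state)
  spikes <- dplyr::arrange(spikes, t)
  for (i in seq_len(nrow(spikes))) {
    state <- update_score(state, spikes[i, ], model)
  }
  state
}

#' Decode the throw direction from observed spikes
#'
#' Majority vote of the spiking filters' training direction labels over all
#' observed spikes; ties go to the most recent spike's label. Decoupled from
#' the quadratic fit.
#'
#' @param spikes Spike tibble observed so far (`t`, `filter`).
#' @param model An `snn_readout`.
#' @return `"left"`, `"right"`, or `NA_character_` (abstain: no spike from a
#'   usable filter).
#' @export
predict_direction <- function(spikes, model) {
  lab <- model$coeffs[, c("filter", "direction", "usable")]
  df <- dplyr::inner_join(as_tibble(spikes), lab, by = "filter")
  df <- df[df$usable, ]
  if (!nrow(df)) return(NA_character_)
  counts <- table(df$direction)
  top <- counts[counts == max(counts)]
  if (length(top) > 1) {
    df$direction[which.max(df$t)]
  } else {
    names(top)
  }
}

#' Visibility sweep of end-point prediction error
#'
#' For each test trajectory and each visibility percentage `p`, only spikes
#' up to `p`% of the trajectory duration are scored (the simulation being
#' causal, this equals presenting the truncated stream); the score is reset
#' between trajectories. Reports the mean and SD of the absolute error
#' `|prediction - reception height|` and the number of direction errors per
#' percentage, alongside the naive baseline that always predicts the
#' training mean.
#'
#' @param network A trained `snn_network` (used only when `spikes` is NULL).
#' @param model An `snn_readout`.
#' @param split A test-set tibble from [make_dataset()] (columns `id`,
#'   `duration`, `reception_y`, `direction`, and `events` if `spikes` is
#'   NULL).
#' @param percentages Visibility percentages of trajectory duration.
#' @param spikes Optional precomputed output-layer spikes from
#'   [run_dataset()]; avoids re-running the network.
#' @return A `visibility_eval` tibble: `percentage`, `mean_ae`, `sd_ae`,
#'   `direction_errors`, `n_trajectories`, `baseline_ae`. Per-trajectory
#'   details are in attribute `details`; an abstention (no spikes yet)
#'   counts as a direction error.
#' @export
evaluate_visibility <- function(network, model, split,
                                percentages = c(15, 30, 45, 60, 75, 90),
                                spikes = NULL) {
  if (is.null(spikes)) spikes <- run_dataset(network, split)
  baseline_ae <- mean(abs(model$prior - split$reception_y))
  percentages <- sort(percentages)
  # precompute per-spike kernel parameters for usable filters
  cf <- model$coeffs[model$coeffs$usable, ]
  sp_all <- dplyr::inner_join(
    as_tibble(spikes)[, c("id", "t", "filter", "x", "y")],
    cf[, c("filter", "a00", "a10", "a01", "a20", "a02", "a11", "rmse",
           "direction")],
    by = "filter")
  sc <- model$score
  sp_all$yp <- with(sp_all, a00 + a10 * x + a01 * y + a20 * x^2 + a02 * y^2 +
                      a11 * x * y)
  sp_all$peak <- 1 / pmax(sp_all$rmse, sc$eps)
  sp_all$sigma <- pmax(sp_all$rmse, sc$sigma_min)
  grid <- score_state(model)$y_grid

  details <- list()
  for (i in seq_len(nrow(split))) {
    id_i <- split$id[i]
    sp_i <- dplyr::arrange(sp_all[sp_all$id == id_i, ], t)
    n_i <- nrow(sp_i)
    score <- numeric(length(grid)); last_t <- 0; ptr <- 0
    tally <- c(left = 0, right = 0); last_lab <- NA_character_
    for (p in percentages) {
      cutoff <- p / 100 * split$duration[i]
      while (ptr < n_i && sp_i$t[ptr + 1] <= cutoff) {
        ptr <- ptr + 1
        tt <- sp_i$t[ptr]
        if (is.finite(sc$tau) && tt > last_t)
          score <- score * exp(-(tt - last_t) / sc$tau)
        last_t <- max(last_t, tt)
        score <- score + if (sc$kernel == "gaussian") {
          sp_i$peak[ptr] * exp(-(grid - sp_i$yp[ptr])^2 /
                                 (2 * sp_i$sigma[ptr]^2))
        } else {
          sp_i$peak[ptr] *
            pmax(0, 1 - abs(grid - sp_i$yp[ptr]) / (2 * sp_i$sigma[ptr]))
        }
        tally[sp_i$direction[ptr]] <- tally[sp_i$direction[ptr]] + 1
        last_lab <- sp_i$direction[ptr]
      }
      st <- structure(list(y_grid = grid, score = score, last_update = last_t),
                      class = "score_state")
      pred <- decode_prediction(st, model)
      dir_hat <- if (ptr == 0) NA_character_
        else if (tally["left"] > tally["right"]) "left"
        else if (tally["right"] > tally["left"]) "right"
        else last_lab
      details[[length(details) + 1]] <- tibble(
        id = id_i, percentage = p,
        prediction = pred, truth = split$reception_y[i],
        ae = abs(pred - split$reception_y[i]),
        direction_pred = dir_hat, direction_truth = split$direction[i],
        direction_error = is.na(dir_hat) | dir_hat != split$direction[i],
        n_spikes = ptr)
    }
  }
  details <- dplyr::bind_rows(details)
  out <- details |>
    dplyr::group_by(.data$percentage) |>
    dplyr::summarise(mean_ae = mean(.data$ae), sd_ae = sd(.data$ae),
                     direction_errors = sum(.data$direction_error),
                     n_trajectories = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(baseline_ae = baseline_ae)
  structure(out, details = details,
            class = c("visibility_eval", class(out)))
}

#' @rdname fit_readout
#' @param x An `snn_readout`.
#' @param ... Unused.
#' @export
print.snn_readout <- function(x, ...) {
  n_use <- sum(x$coeffs$usable)
  cat(sprintf(
    "<snn_readout> %d/%d usable filters, prior %.2f px, mean RMSE %.2f px\n",
    n_use, nrow(x$coeffs), x$prior,
    mean(x$coeffs$rmse[x$coeffs$usable])))
  invisible(x)
}

#' Tidy an `snn_readout`
#'
#' @param x An `snn_readout`.
#' @param ... Unused.
#' @return One row per filter: coefficients `a00`..`a11`, training `rmse`,
#'   `direction` label, `n_spikes`, `usable`.
#' @export
#' @method tidy snn_readout
tidy.snn_readout <- function(x, ...) x$coeffs

#' @rdname tidy.snn_readout
#' @return For `glance()`: a one-row summary (filter counts, mean RMSE,
#'   prior).
#' @export
#' @method glance snn_readout
glance.snn_readout <- function(x, ...) {
  tibble(n_filters = nrow(x$coeffs), n_usable = sum(x$coeffs$usable),
         mean_rmse = mean(x$coeffs$rmse[x$coeffs$usable]),
         prior = x$prior)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
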