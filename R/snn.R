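#' @useDynLib snntraj, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Layer parameters for the spiking network
#'
#' One layer of the convolutional spiking network: leaky integrate-and-fire
#' neurons tied into `n_filters` shared 5 x 5 kernels (stride 1, valid
#' convolution), trained with a simplified multiplicative STDP rule and
#' regulated by lateral inhibition (`f_inst`) and a transient homeostatic
#' threshold penalty (`f_long`, `t_thresh`). See [default_layer_params()] for
#' the calibrated three-layer parameter set shipped as defaults.
#'
#' @param n_filters Number of convolutional filters (>= 1).
#' @param w_max Weight-to-potential scale: an incoming spike through weight
#'   `W` adds `W * w_max` to the membrane potential.
#' @param tau_memb Membrane leak time constant, seconds.
#' @param tau_ltp LTP window, seconds: an afferent whose last spike precedes
#'   the postsynaptic spike by less than `tau_ltp` is potentiated, every
#'   other afferent in the receptive field is depressed.
#' @param a_ltp,a_ltd Potentiation / depression amplitudes of the
#'   multiplicative rule `dW = (1 - W) a_ltp` / `dW = -W a_ltd`, which
#'   soft-bounds weights in (0, 1).
#' @param f_inst Lateral-inhibition factor: a spike reduces the other
#'   filters' potentials at the same position by `f_inst * U_propinh`, where
#'   `U_propinh` is the mean squared membrane potential across filters there.
#' @param f_long Homeostatic factor: each spike adds an inverted-V threshold
#'   penalty of peak `f_long * U_propinh` rising and falling over `t_thresh`
#'   seconds each.
#' @param t_thresh Rise (and fall) time of the threshold penalty, seconds.
#' @param u_thresh Base firing threshold in potential units (rest = 0).
#' @param patch,stride Receptive-field geometry; only 5 and 1 are supported.
#' @return A `layer_params` list.
#' @export
layer_params <- function(n_filters, w_max, tau_memb, tau_ltp, a_ltp, a_ltd,
                         f_inst, f_long, t_thresh, u_thresh = 1,
                         patch = 5, stride = 1) {
  assert_that(patch == 5 && stride == 1,
              "only 5x5 patches with stride 1 are supported")
  assert_that(n_filters >= 1, "n_filters must be >= 1")
  assert_that(tau_memb > 0 && tau_ltp > 0 && t_thresh > 0,
              "time constants must be > 0")
  assert_that(a_ltp > 0 && a_ltd > 0, "a_ltp and a_ltd must be > 0")
  structure(list(n_filters = as.integer(n_filters), w_max = w_max,
                 tau_memb = tau_memb, tau_ltp = tau_ltp,
                 a_ltp = a_ltp, a_ltd = a_ltd, f_inst = f_inst,
                 f_long = f_long, t_thresh = t_thresh, u_thresh = u_thresh,
                 patch = 5L, stride = 1L),
            class = "layer_params")
}

#' Default three-layer parameter set
#'
#' The calibrated per-layer parameters used throughout: time constants in
#' seconds, weight scales on a base threshold of 1 potential unit.
#'
#' @param n_filters Optional length-3 integer vector overriding the filter
#'   counts (defaults 60, 80, 100).
#' @param u_thresh Base firing threshold (shared across layers).
#' @return A list of three [layer_params()].
#' @export
default_layer_params <- function(n_filters = c(60L, 80L, 100L), u_thresh = 1) {
  stopifnot(length(n_filters) == 3)
  list(
    layer_params(n_filters[1], w_max = 1.873, tau_memb = 0.01,
                 tau_ltp = 0.0754, a_ltp = 0.00195, a_ltd = 0.0005,
                 f_inst = 3.0, f_long = 2.89, t_thresh = 0.031,
                 u_thresh = u_thresh),
    layer_params(n_filters[2], w_max = 0.813, tau_memb = 0.052,
                 tau_ltp = 0.0236, a_ltp = 0.0131, a_ltd = 0.00118,
                 f_inst = 2.82, f_long = 2.41, t_thresh = 0.023,
                 u_thresh = u_thresh),
    layer_params(n_filters[3], w_max = 1.308, tau_memb = 0.039,
                 tau_ltp = 0.0368, a_ltp = 0.00815, a_ltd = 0.00198,
                 f_inst = 3.46, f_long = 1.9, t_thresh = 0.051,
                 u_thresh = u_thresh)
  )
}

#' Input delay configuration
#'
#' Every sensor event is duplicated onto three delay lines (delay selection):
#' with ON/OFF polarity this yields 6 input channels per pixel, letting STDP
#' select the delay that synchronises inputs for a preferred motion
#' direction and speed. Defaults are 0, 1 and 2 frame periods at 240 fps.
#'
#' @param delays Numeric length-3 vector `(0, d1, d2)` in seconds with
#'   `0 <= d1 <= d2`.
#' @return A `delay_config`.
#' @export
delay_config <- function(delays = c(0, 1, 2) / 240) {
  assert_that(length(delays) == 3 && delays[1] == 0 &&
                delays[2] >= 0 && delays[3] >= delays[2],
              "delays must be (0, d1, d2) with 0 <= d1 <= d2")
  structure(list(delays = as.numeric(delays)), class = "delay_config")
}

#' Duplicate an event stream onto delay lines
#'
#' @param stream An `event_stream` (or tibble with `t`, `x`, `y`,
#'   `polarity`), sorted by time.
#' @param config A [delay_config()].
#' @return A tibble with the delayed copies: columns of `stream` plus
#'   `delay` (0-based delay index) and `channel` (`2 * delay + polarity`,
#'   the layer-1 input channel), re-sorted by `(t, y, x, channel)`.
#' @export
duplicate_with_delays <- function(stream, config) {
  assert_that(!is.unsorted(stream$t), "stream must be sorted by time")
  out <- purrr::map(seq_along(config$delays), function(d) {
    dplyr::mutate(as_tibble(stream),
                  t = .data$t + config$delays[d],
                  delay = d - 1L,
                  channel = 2L * (d - 1L) + .data$polarity)
  })
  dplyr::arrange(dplyr::bind_rows(out), t, y, x, channel)
}

#' Construct a spiking network
#'
#' Builds the layer stack over a given sensor size and initialises every
#' weight independently and uniformly on [0.3, 0.7] (seeded). Layer k has a
#' `(width - 4k) x (height - 4k)` retinotopic map; layer 1 sees 6 input
#' channels (ON/OFF x 3 delays), deeper layers see the previous layer's
#' filters.
#'
#' @param width,height Sensor size in pixels.
#' @param layers A list of [layer_params()] (default [default_layer_params()]).
#' @param delays A [delay_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return An `snn_network`: list with `width`, `height`, `layers` (each the
#'   params plus a `weights` array of dim `(n_filters, 5, 5, in_channels)`
#'   indexed `[filter, dy, dx, channel]`), `delays`, `seed`.
#' @export
new_network <- function(width, height, layers = default_layer_params(),
                        delays = delay_config(), seed = 1L) {
  assert_that(inherits(delays, "delay_config"), "delays must be a delay_config")
  in_ch <- 6L
  in_w <- as.integer(width); in_h <- as.integer(height)
  built <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    lp <- layers[[k]]
    assert_that(inherits(lp, "layer_params"), "layers must be layer_params")
    assert_that(in_w >= 5 && in_h >= 5,
                sprintf("layer %d input %dx%d too small for a 5x5 patch",
                        k, in_w, in_h))
    w <- with_seed(child_seed(seed, k), {
      array(runif(lp$n_filters * 25 * in_ch, 0.3, 0.7),
            dim = c(lp$n_filters, 5, 5, in_ch))
    })
    built[[k]] <- c(unclass(lp), list(weights = w, in_channels = in_ch))
    in_ch <- lp$n_filters
    in_w <- in_w - 4L; in_h <- in_h - 4L
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 layers = built, delays = delays, seed = as.integer(seed)),
            class = "snn_network")
}

#' Map size of a network layer
#' @param network An `snn_network`.
#' @param layer Layer index (1-based).
#' @return Integer `c(width, height)` of the layer's retinotopic map.
#' @export
map_size <- function(network, layer) {
  c(network$width - 4L * layer, network$height - 4L * layer)
}

cpp_layer_list <- function(network, n_active) {
  lapply(network$layers[seq_len(n_active)], function(l)
    list(n_filters = l$n_filters, w_max = l$w_max, tau_memb = l$tau_memb,
         tau_ltp = l$tau_ltp, a_ltp = l$a_ltp, a_ltd = l$a_ltd,
         f_inst = l$f_inst, f_long = l$f_long, t_thresh = l$t_thresh,
         u_thresh = l$u_thresh, weights = as.numeric(l$weights)))
}

#' Run the network on an event stream
#'
#' Event-driven simulation: spikes are delivered through a global
#' time-ordered queue (input delay lines included); each delivery applies
#' the membrane leak, integrates the weighted input, and on a threshold
#' crossing emits a spike (reset to rest, lateral inhibition of the other
#' filters at that position, registration of the homeostatic threshold
#' penalty, propagation to the next layer and, when `learning_layer`
#' matches, an STDP update of the shared kernel). Simultaneous events are
#' processed in `(t, layer, y, x, channel)` order; the result is fully
#' deterministic.
#'
#' @param network An [new_network()] object.
#' @param events An `event_stream` (or tibble with `t`, `x`, `y`,
#'   `polarity`); every event must lie inside the sensor frame.
#' @param learning_layer 0 for pure inference, otherwise the 1-based index
#'   of the (single) layer whose kernels learn by STDP.
#' @param n_active Number of layers to simulate (default: all; during
#'   layer-wise training only layers up to the learning layer are active).
#' @return A spike tibble `t`, `layer` (1-based), `filter` (1-based), `x`,
#'   `y` (0-based map coordinates), `u` (membrane value at the spike). When
#'   `learning_layer > 0` the updated network is attached as attribute
#'   `network`.
#' @export
run_network <- function(network, events, learning_layer = 0L,
                        n_active = length(network$layers)) {
  assert_that(inherits(network, "snn_network"), "network must be an snn_network")
  n_active <- max(1L, min(as.integer(n_active), length(network$layers)))
  res <- run_snn_cpp(as.numeric(events$t), as.integer(events$x),
                     as.integer(events$y), as.integer(events$polarity),
                     network$width, network$height,
                     cpp_layer_list(network, n_active),
                     network$delays$delays,
                     as.integer(learning_layer), n_active)
  spikes <- as_tibble(res$spikes)
  if (learning_layer > 0) {
    for (k in seq_len(n_active)) {
      dim_k <- dim(network$layers[[k]]$weights)
      network$layers[[k]]$weights <- array(res$weights[[k]], dim = dim_k)
    }
    attr(spikes, "network") <- network
  }
  spikes
}

#' Train the network layer by layer with STDP
#'
#' Unsupervised training: layer k learns while layers below it are frozen
#' (inference only) and layers above it are inactive. Trajectories are
#' presented individually; between presentations the network state is fully
#' reset (the "reset" gap mode, equivalent to a long silent gap since all
#' state decays to baseline within the layer time constants), or, in
#' "strict" mode, the streams are concatenated with literal 2 s silent gaps
#' and simulated as one stream.
#'
#' @param network An `snn_network`.
#' @param streams A list of event tibbles (one per trajectory).
#' @param epochs Passes through the training streams per layer.
#' @param gap_mode `"reset"` (default) or `"strict"` (literal 2 s gaps).
#' @param gap Silent-gap length in seconds for `"strict"` mode.
#' @param shuffle Shuffle presentation order each epoch (seeded from the
#'   network seed).
#' @param verbose Print per-layer spike counts and weight-change norms.
#' @return The trained `snn_network`, with a `diagnostics` attribute: a
#'   tibble of per-layer, per-presentation output-spike counts and mean
#'   absolute kernel change.
#' @export
train_network <- function(network, streams, epochs = 1, gap_mode = c("reset", "strict"),
                          gap = 2, shuffle = TRUE, verbose = FALSE) {
  gap_mode <- match.arg(gap_mode)
  assert_that(length(streams) >= 1, "need at least one training stream")
  diag_rows <- list()
  if (gap_mode == "strict") {
    streams <- list(concat_streams(streams, gap = gap))
  }
  for (k in seq_along(network$layers)) {
    for (ep in seq_len(epochs)) {
      order_idx <- if (shuffle && length(streams) > 1) {
        with_seed(child_seed(network$seed, k * 1000L + ep),
                  sample(seq_along(streams)))
      } else seq_along(streams)
      for (i in order_idx) {
        w_before <- network$layers[[k]]$weights
        spikes <- run_network(network, streams[[i]], learning_layer = k,
                              n_active = k)
        network <- attr(spikes, "network")
        dw <- mean(abs(network$layers[[k]]$weights - w_before))
        diag_rows[[length(diag_rows) + 1]] <- tibble(
          layer = k, epoch = ep, stream = i,
          n_spikes = sum(spikes$layer == k), mean_abs_dw = dw)
      }
      if (verbose) {
        last <- dplyr::bind_rows(diag_rows)
        last <- last[last$layer == k & last$epoch == ep, ]
        message(sprintf("layer %d epoch %d: %d spikes, mean |dW| %.2e",
                        k, ep, sum(last$n_spikes), mean(last$mean_abs_dw)))
      }
    }
  }
  attr(network, "diagnostics") <- dplyr::bind_rows(diag_rows)
  network
}

#' Concatenate event streams with silent gaps
#'
#' @param streams List of event tibbles.
#' @param gap Gap in seconds inserted after each stream's last event.
#' @return One combined event tibble; attribute `offsets` gives each
#'   stream's time shift.
#' @export
concat_streams <- function(streams, gap = 2) {
  offset <- 0
  out <- vector("list", length(streams))
  offsets <- numeric(length(streams))
  for (i in seq_along(streams)) {
    s <- as_tibble(streams[[i]])
    offsets[i] <- offset
    out[[i]] <- dplyr::mutate(s, t = .data$t + offset)
    offset <- offset + (if (nrow(s)) max(s$t) else 0) + gap
  }
  res <- dplyr::bind_rows(out)
  attr(res, "offsets") <- offsets
  res
}

# ---- neuron-level operations (reference semantics, used in tests/docs) ----

#' Single-neuron state
#'
#' Explicit state of one LIF neuron, for stepping the neuron-level
#' operations directly (the network simulator keeps this state internally).
#'
#' @param u Membrane potential.
#' @param last_update Time of the last leak application, seconds.
#' @param penalties Tibble with columns `t`, `a`: past own-spike times and
#'   penalty amplitudes.
#' @return A `neuron_state` list.
#' @export
neuron_state <- function(u = 0, last_update = 0,
                         penalties = tibble(t = double(), a = double())) {
  structure(list(u = u, last_update = last_update, penalties = penalties),
            class = "neuron_state")
}

#' Apply the membrane leak up to time t
#'
#' Exponential decay toward rest (0):
#' `u(t) = u_rest + (u(t_k) - u_rest) exp(-(t - t_k) / tau_memb)`.
#'
#' @param state A [neuron_state()].
#' @param t Time in seconds, `>= state$last_update`.
#' @param params A [layer_params()].
#' @return The updated `neuron_state`.
#' @export
leak_membrane <- function(state, t, params) {
  assert_that(t >= state$last_update, "time must not reverse")
  state$u <- state$u * exp(-(t - state$last_update) / params$tau_memb)
  state$last_update <- t
  state
}

#' Integrate one incoming spike
#'
#' Adds `weight * w_max` to the membrane potential (leak must already have
#' been applied at the event time) and checks the threshold
#' `u_thresh + U_long(t)`; on a crossing the neuron spikes and resets to
#' rest.
#'
#' @param state A [neuron_state()] leaked to the event time.
#' @param weight Synaptic weight in [0, 1].
#' @param params A [layer_params()].
#' @return List with `state` (updated) and `spiked` (logical).
#' @export
integrate_event <- function(state, weight, params) {
  state$u <- state$u + weight * params$w_max
  thr <- params$u_thresh + threshold_penalty(state, state$last_update, params)
  spiked <- state$u >= thr
  if (spiked) state$u <- 0
  list(state = state, spiked = spiked)
}

#' One STDP update of a weight vector
#'
#' The simplified multiplicative rule applied at a postsynaptic spike:
#' afferents whose last spike falls inside the LTP window are potentiated by
#' `(1 - W) a_ltp`, all others (including afferents that never spiked) are
#' depressed by `W a_ltd`. Weights stay in (0, 1) by construction.
#'
#' @param w Numeric vector/array of weights.
#' @param potentiate Logical vector: TRUE where the LTP branch applies.
#' @param params A [layer_params()] (uses `a_ltp`, `a_ltd`).
#' @return Updated weights, same shape as `w`.
#' @export
stdp_step <- function(w, potentiate, params) {
  dw <- ifelse(potentiate, (1 - w) * params$a_ltp, -w * params$a_ltd)
  w + dw
}

#' STDP update from presynaptic spike times
#'
#' @param weights Weight array for one filter (any shape).
#' @param presyn_times Last presynaptic spike time per afferent (same shape;
#'   `-Inf` for afferents that never spiked).
#' @param t_post Postsynaptic spike time.
#' @param params A [layer_params()].
#' @return Updated weights.
#' @export
stdp_update <- function(weights, presyn_times, t_post, params) {
  finite <- is.finite(presyn_times)
  assert_that(all(t_post >= presyn_times[finite]),
              "postsynaptic spike must not precede presynaptic spikes")
  stdp_step(weights, (t_post - presyn_times) < params$tau_ltp, params)
}

#' Lateral inhibition at a retinotopic position
#'
#' On a spike, the membrane potentials of the other filters at the same
#' position are reduced by `f_inst * U_propinh`, where `U_propinh` is the
#' mean squared membrane potential over all filters at the position at spike
#' time (the spiker's value taken before its reset). Potentials may go below
#' rest; the leak then decays them back.
#'
#' @param u Numeric vector of membrane potentials per filter at one
#'   position, at spike time.
#' @param spiking_filter Index of the filter that spiked.
#' @param params A [layer_params()].
#' @return List with `u` (updated potentials; the spiker's entry untouched,
#'   reset is a separate step) and `u_propinh`.
#' @export
lateral_inhibit <- function(u, spiking_filter, params) {
  u_prop <- mean(u^2)
  others <- setdiff(seq_along(u), spiking_filter)
  u[others] <- u[others] - params$f_inst * u_prop
  list(u = u, u_propinh = u_prop)
}

#' Evaluate the homeostatic threshold penalty
#'
#' Each past own-spike at `t_s` with amplitude `A` contributes an inverted-V
#' term: `A (t - t_s) / T` on `[t_s, t_s + T]`, `A (2 - (t - t_s)/T)` on
#' `[t_s + T, t_s + 2T]`, zero outside, with `T = t_thresh`. Contributions
#' sum.
#'
#' @param state A [neuron_state()] whose `penalties` tibble has columns `t`
#'   (spike time) and `a` (amplitude).
#' @param t Evaluation time, seconds.
#' @param params A [layer_params()].
#' @return The penalty value `U_long(t)` (>= 0).
#' @export
threshold_penalty <- function(state, t, params) {
  p <- state$penalties
  if (!nrow(p)) return(0)
  dt <- t - p$t
  tt <- params$t_thresh
  contrib <- ifelse(dt < 0 | dt >= 2 * tt, 0,
                    ifelse(dt < tt, p$a * dt / tt, p$a * (2 - dt / tt)))
  sum(contrib, na.rm = TRUE)
}
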