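# Small layer parameterisations reused across cases (layer-1 calibrated
# values unless a case overrides them).
lp1 <- function(n_filters = 2, ...) {
  args <- list(n_filters = n_filters, w_max = 1.873, tau_memb = 0.01,
               tau_ltp = 0.0754, a_ltp = 0.00195, a_ltd = 0.0005,
               f_inst = 3.0, f_long = 2.89, t_thresh = 0.031)
  args[names(list(...))] <- list(...)
  do.call(layer_params, args)
}

test_that("delay duplication triples the stream with equal channel counts", {
  ev <- random_grid_stream(50, 10, 10, seed = 3)
  dc <- delay_config(c(0, 1 / 240, 2 / 240))
  dup <- duplicate_with_delays(ev, dc)
  expect_equal(nrow(dup), 3 * nrow(ev))
  expect_false(is.unsorted(dup$t))
  expect_true(all(table(dup$delay) == nrow(ev)))
  one <- duplicate_with_delays(ev[1, ], dc)
  expect_equal(one$t, ev$t[1] + c(0, 1 / 240, 2 / 240), tolerance = 1e-15)
  # zero delays: three simultaneous copies per event
  dup0 <- duplicate_with_delays(ev, delay_config(c(0, 0, 0)))
  expect_equal(nrow(dup0), 3 * nrow(ev))
  expect_true(all(table(dup0$t) %% 3 == 0))
})

test_that("membrane leak follows the exponential closed form", {
  p <- lp1()
  s <- neuron_state(u = 1, last_update = 0)
  expect_equal(leak_membrane(s, 0, p)$u, 1)  # t = t_k: unchanged
  expect_equal(leak_membrane(s, p$tau_memb, p)$u, exp(-1), tolerance = 1e-12)
  # layer-1 constant 0.01 s over 0.02 s elapsed
  expect_equal(leak_membrane(s, 0.02, p)$u, exp(-2), tolerance = 1e-12)
  expect_error(leak_membrane(leak_membrane(s, 0.01, p), 0.005, p),
               "reverse")
  # monotone approach to rest with no input
  us <- sapply(seq(0, 0.05, by = 0.005), function(t) leak_membrane(s, t, p)$u)
  expect_true(all(diff(abs(us)) <= 0))
})

test_that("event integration adds W * w_max and resets on threshold", {
  p <- lp1()
  s <- neuron_state(u = 0, last_update = 0)
  r <- integrate_event(s, 0, p)
  expect_equal(r$state$u, 0); expect_false(r$spiked)
  r <- integrate_event(s, 0.5, p)
  expect_equal(r$state$u, 0.5 * 1.873)  # 0.9365
  expect_false(r$spiked)
  # just below threshold, one increment crosses: exactly one spike, reset
  s2 <- neuron_state(u = 0.999, last_update = 0)
  r2 <- integrate_event(s2, 0.5, p)
  expect_true(r2$spiked)
  expect_equal(r2$state$u, 0)
})

test_that("STDP has exact fixed points and the published increments", {
  p <- lp1()
  expect_equal(stdp_step(1, TRUE, p), 1)   # dW = 0 at W = 1 under LTP
  expect_equal(stdp_step(0, FALSE, p), 0)  # dW = 0 at W = 0 under LTD
  # W = 0.5, LTP amplitude 0.00195 within the 0.0754 s window
  got <- stdp_update(0.5, presyn_times = 0.0, t_post = 0.05, p)
  expect_equal(got - 0.5, 0.000975, tolerance = 1e-12)
  # outside the window (and never-spiked afferents) depress
  got2 <- stdp_update(c(0.5, 0.5), presyn_times = c(-1, -Inf),
                      t_post = 0.05, p)
  expect_equal(got2, c(0.5 - 0.5 * 5e-4, 0.5 - 0.5 * 5e-4))
})

test_that("random STDP updates keep weights strictly inside (0, 1)", {
  p <- lp1()
  set.seed(7)
  w <- runif(200, 0.3, 0.7)
  for (i in 1:500) {  # 10^5 scalar updates in vectorised blocks
    w <- stdp_step(w, runif(200) < 0.5, p)
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("lateral inhibition uses the mean squared potential", {
  p <- lp1()
  r <- lateral_inhibit(c(0.8, 0.6), spiking_filter = 1, p)
  expect_equal(r$u_propinh, 0.5)         # (0.64 + 0.36) / 2
  expect_equal(r$u[2], 0.6 - 3.0 * 0.5)  # non-spiker drops by 1.5
  expect_equal(r$u[1], 0.8)              # spiker handled by the reset
  # single filter: nothing to inhibit
  r1 <- lateral_inhibit(0.9, 1, p)
  expect_equal(r1$u, 0.9)
  # all-zero potentials: no change
  r0 <- lateral_inhibit(c(0, 0, 0), 2, p)
  expect_equal(r0$u, c(0, 0, 0))
})

test_that("the threshold penalty is an inverted V with bounded support", {
  p <- lp1(t_thresh = 0.02)
  s <- neuron_state(penalties = tibble::tibble(t = 0.1, a = 2))
  expect_equal(threshold_penalty(neuron_state(), 1, p), 0)
  expect_equal(threshold_penalty(s, 0.1, p), 0)
  expect_equal(threshold_penalty(s, 0.11, p), 1)        # halfway up
  expect_equal(threshold_penalty(s, 0.12, p), 2)        # peak at t_s + T
  expect_equal(threshold_penalty(s, 0.13, p), 1)        # halfway down
  expect_equal(threshold_penalty(s, 0.14, p), 0)        # support ends
  expect_equal(threshold_penalty(s, 1.00, p), 0)
  # contributions from several spikes sum
  s2 <- neuron_state(penalties = tibble::tibble(t = c(0.1, 0.11), a = c(2, 2)))
  expect_equal(threshold_penalty(s2, 0.12, p), 2 + 1)
})

test_that("event-driven and clock-driven simulations agree spike for spike", {
  tick <- 2^-17  # binary-exact, finer than 0.01 ms
  net <- new_network(8, 8, layers = list(lp1(2)),
                     delays = delay_config(c(0, 100, 200) * tick), seed = 21)
  for (s in 1:4) {
    ev <- random_grid_stream(150, 8, 8, duration = 0.02, seed = 100 + s)
    got <- run_network(net, ev)
    ora <- clock_sim(net, ev, tick = tick)
    expect_equal(nrow(got), nrow(ora$spikes))
    g <- got[order(got$t, got$layer, got$y, got$x, got$filter), ]
    o <- ora$spikes[order(ora$spikes$tick, ora$spikes$layer, ora$spikes$y,
                          ora$spikes$x, ora$spikes$filter), ]
    expect_equal(g$filter, o$filter)
    expect_equal(g$x, o$x); expect_equal(g$y, o$y)
    expect_true(all(abs(g$t - o$tick * tick) <= tick))
    expect_lt(max(abs(g$u - o$u) / pmax(abs(o$u), 1e-12)), 1e-9)
  }
})

test_that("two-layer propagation matches the clock-driven oracle", {
  tick <- 2^-17  # binary-exact, finer than 0.01 ms
  l2 <- layer_params(2, w_max = 0.813, tau_memb = 0.052, tau_ltp = 0.0236,
                     a_ltp = 0.0131, a_ltd = 0.00118, f_inst = 2.82,
                     f_long = 2.41, t_thresh = 0.023, u_thresh = 0.3)
  net <- new_network(10, 10, layers = list(lp1(2), l2),
                     delays = delay_config(c(0, 100, 200) * tick), seed = 5)
  ev <- random_grid_stream(400, 10, 10, duration = 0.02, seed = 9)
  got <- run_network(net, ev)
  ora <- clock_sim(net, ev, tick = tick)
  expect_gt(sum(got$layer == 2), 0)  # the deep layer actually fires
  expect_equal(nrow(got), nrow(ora$spikes))
  g <- got[order(got$t, got$layer, got$y, got$x, got$filter), ]
  o <- ora$spikes[order(ora$spikes$tick, ora$spikes$layer, ora$spikes$y,
                        ora$spikes$x, ora$spikes$filter), ]
  expect_equal(g$layer, o$layer)
  expect_equal(g$filter, o$filter)
  expect_lt(max(abs(g$u - o$u) / pmax(abs(o$u), 1e-12)), 1e-9)
})

test_that("STDP learning matches the clock-driven oracle kernel for kernel", {
  tick <- 2^-17  # binary-exact, finer than 0.01 ms
  net <- new_network(8, 8, layers = list(lp1(2, a_ltp = 0.05, a_ltd = 0.01)),
                     delays = delay_config(c(0, 100, 200) * tick), seed = 2)
  ev <- random_grid_stream(300, 8, 8, duration = 0.02, seed = 31)
  got <- run_network(net, ev, learning_layer = 1)
  net_after <- attr(got, "network")
  ora <- clock_sim(net, ev, tick = tick, learning_layer = 1)
  expect_gt(nrow(got), 0)
  expect_equal(as.numeric(net_after$layers[[1]]$weights),
               as.numeric(ora$weights[[1]]), tolerance = 1e-9)
  # weights moved but stayed inside (0, 1)
  expect_false(identical(net_after$layers[[1]]$weights,
                         net$layers[[1]]$weights))
  expect_true(all(net_after$layers[[1]]$weights > 0 &
                    net_after$layers[[1]]$weights < 1))
})

test_that("simulation respects basic structural contracts", {
  net <- new_network(12, 10, layers = list(lp1(3)), seed = 4)
  # empty stream: no spikes
  empty <- tibble::tibble(t = double(), x = integer(), y = integer(),
                          polarity = integer())
  expect_equal(nrow(run_network(net, empty)), 0)
  # single event with weights below threshold/(3 w_max) cannot fire anything
  # even if all three delayed copies accumulate without leak
  low <- net
  low$layers[[1]]$weights[] <- 0.15
  one <- tibble::tibble(t = 0, x = 5L, y = 5L, polarity = 1L)
  expect_equal(nrow(run_network(low, one)), 0)
  # out-of-frame events are rejected at ingest
  bad <- tibble::tibble(t = 0, x = 12L, y = 0L, polarity = 1L)
  expect_error(run_network(net, bad), "outside")
  # map bounds: layer-k coordinates within (W - 4k) x (H - 4k)
  ev <- random_grid_stream(500, 12, 10, seed = 8)
  sp <- run_network(net, ev)
  expect_true(all(sp$x >= 0 & sp$x <= 12 - 4 - 1))
  expect_true(all(sp$y >= 0 & sp$y <= 10 - 4 - 1))
  # determinism: identical runs give identical spikes
  expect_identical(run_network(net, ev), sp)
})

test_that("training is deterministic and a repeated pattern is learned", {
  # one repeated spatio-temporal pattern: a diagonal sweep in a 9x9 patch
  pat <- tibble::tibble(
    t = (0:4) * 2e-3, x = 2:6, y = 2:6, polarity = 1L)
  net <- new_network(9, 9, layers = list(lp1(1, a_ltp = 0.02, a_ltd = 0.004)),
                     delays = delay_config(c(0, 2e-3, 4e-3)), seed = 13)
  streams <- rep(list(pat), 60)
  trained <- train_network(net, streams)
  trained2 <- train_network(net, streams)
  expect_identical(trained$layers[[1]]$weights, trained2$layers[[1]]$weights)
  d <- attr(trained, "diagnostics")
  # kernel converged: late presentations barely move the weights
  expect_lt(mean(tail(d$mean_abs_dw, 5)), 1e-4)
  # the kernel's weight mass sits on the pattern's afferents: the ON
  # channels of every delay line (1-based channel indices 2, 4, 6); the OFF
  # channels never spike and are depressed to ~0
  w <- trained$layers[[1]]$weights  # (1, 5, 5, 6)
  mean_on <- mean(w[, , , c(2, 4, 6)])
  mean_off <- mean(w[, , , c(1, 3, 5)])
  expect_gt(mean_on, 100 * mean_off)
  expect_gt(max(w), 0.3)
  # zero training epochs leave the seeded initialisation untouched
  same <- train_network(net, streams[1], epochs = 1)
  expect_false(identical(net$layers[[1]]$weights, same$layers[[1]]$weights))
})

test_that("lateral inhibition decorrelates the learned filters", {
  cfg <- scene_config(width = 24, height = 24, ball_radius = 2, gravity = 0,
                      pixel_pitch = 0.02, noise_sigma = 0, seed = 3)
  fe <- frontend_config(0.4)
  mk <- function(angle) {
    tr <- simulate_trajectory(cfg, list(x0 = if (angle == 0) 4 else 19,
                                        y0 = 12, v0 = 2.4, angle0 = angle))
    encode_sequence(render_frames(tr, cfg), fe)
  }
  streams <- rep(list(mk(0), mk(180)), 15)
  base <- list(lp1(4, a_ltp = 0.01, a_ltd = 0.002))
  mean_cos <- function(net) {
    w <- net$layers[[1]]$weights
    m <- matrix(w, nrow = dim(w)[1])
    cs <- outer(seq_len(nrow(m)), seq_len(nrow(m)), Vectorize(function(i, j)
      sum(m[i, ] * m[j, ]) / sqrt(sum(m[i, ]^2) * sum(m[j, ]^2))))
    mean(cs[upper.tri(cs)])
  }
  net_inh <- train_network(new_network(24, 24, base, seed = 6), streams,
                           shuffle = FALSE)
  base0 <- list(lp1(4, a_ltp = 0.01, a_ltd = 0.002, f_inst = 0))
  net_no <- train_network(new_network(24, 24, base0, seed = 6), streams,
                          shuffle = FALSE)
  expect_lt(mean_cos(net_inh), mean_cos(net_no))
})

test_that("strict-gap training is equivalent to per-trajectory resets", {
  ev1 <- random_grid_stream(80, 8, 8, duration = 0.02, seed = 41)
  ev2 <- random_grid_stream(80, 8, 8, duration = 0.02, seed = 42)
  net <- new_network(8, 8, layers = list(lp1(2, a_ltp = 0.02, a_ltd = 0.005)),
                     seed = 9)
  a <- train_network(net, list(ev1, ev2), gap_mode = "reset", shuffle = FALSE)
  b <- train_network(net, list(ev1, ev2), gap_mode = "strict", shuffle = FALSE)
  expect_equal(a$layers[[1]]$weights, b$layers[[1]]$weights, tolerance = 1e-9)
})

test_that("network checkpoints round-trip through JSON", {
  net <- new_network(10, 10, layers = list(lp1(2)), seed = 77)
  path <- file.path(tempdir(), "net.json")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(back$layers[[1]]$weights, net$layers[[1]]$weights,
               tolerance = 1e-15)
  expect_equal(back$delays$delays, net$delays$delays)
  ev <- random_grid_stream(100, 10, 10, seed = 1)
  expect_equal(run_network(back, ev), run_network(net, ev))
})
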