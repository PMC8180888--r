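# Synthetic spike tables with known regression structure.
quad_surface <- function(cf, x, y) {
  cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * y^2 + cf[6] * x * y
}

make_readout_fixture <- function(cf, n = 120, filter = 1L, sigma = 0,
                                 seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 40); y <- runif(n, 0, 30)
  tibble::tibble(
    id = rep(seq_len(max(2, n %/% 10)), length.out = n),
    t = sort(runif(n, 0, 0.5)),
    layer = 3L, filter = filter, x = x, y = y,
    truth_y = quad_surface(cf, x, y) + rnorm(n, sd = sigma))
}

fixture_trajectories <- function(spikes) {
  # one reception height per trajectory: the mean of its spike targets
  spikes |>
    dplyr::group_by(id) |>
    dplyr::summarise(reception_y = mean(truth_y), .groups = "drop") |>
    dplyr::mutate(direction = "right")
}

test_that("linear and quadratic surfaces are recovered exactly", {
  # Y = 2 + 0.5 x: per-spike targets equal the surface, so the trajectory
  # grouping is bypassed by fitting on per-spike targets directly
  cf <- c(2, 0.5, 0, 0, 0, 0)
  sp <- make_readout_fixture(cf)
  trajs <- tibble::tibble(id = sp$id, reception_y = sp$truth_y,
                          direction = "right")
  # one pseudo-trajectory per spike so each spike carries its own target
  sp$id <- seq_len(nrow(sp)); trajs$id <- sp$id
  model <- fit_readout(sp, trajs)
  co <- tidy(model)
  expect_equal(unlist(co[1, c("a00", "a10", "a01", "a20", "a02", "a11")]),
               setNames(cf, c("a00", "a10", "a01", "a20", "a02", "a11")),
               tolerance = 1e-6)
  expect_lt(co$rmse[1], 1e-9)

  cf2 <- c(5, -0.3, 0.8, 0.01, -0.02, 0.005)
  sp2 <- make_readout_fixture(cf2, seed = 2)
  sp2$id <- seq_len(nrow(sp2))
  trajs2 <- tibble::tibble(id = sp2$id, reception_y = sp2$truth_y,
                           direction = "left")
  model2 <- fit_readout(sp2, trajs2)
  co2 <- tidy(model2)
  expect_equal(unlist(co2[1, c("a00", "a10", "a01", "a20", "a02", "a11")]),
               setNames(cf2, c("a00", "a10", "a01", "a20", "a02", "a11")),
               tolerance = 1e-6)
})

test_that("a constant target yields the intercept-only fit", {
  sp <- make_readout_fixture(c(68.2, 0, 0, 0, 0, 0))
  sp$id <- seq_len(nrow(sp))
  trajs <- tibble::tibble(id = sp$id, reception_y = 68.2, direction = "right")
  model <- fit_readout(sp, trajs)
  co <- tidy(model)
  expect_equal(co$a00[1], 68.2, tolerance = 1e-9)
  expect_equal(unlist(co[1, c("a10", "a01", "a20", "a02", "a11")]),
               setNames(numeric(5), c("a10", "a01", "a20", "a02", "a11")),
               tolerance = 1e-9)
  # the naive prior equals the training-mean reception height
  expect_equal(model$prior, 68.2)
  expect_equal(predict_y(model, 1, 123, -7), 68.2, tolerance = 1e-9)
})

test_that("quadratic evaluation matches direct arithmetic", {
  sp <- make_readout_fixture(c(1, 2, 3, 4, 5, 6))
  sp$id <- seq_len(nrow(sp))
  trajs <- tibble::tibble(id = sp$id, reception_y = sp$truth_y,
                          direction = "right")
  model <- fit_readout(sp, trajs)
  # (1,2,3,4,5,6) at (x, y) = (2, 3): 1 + 4 + 9 + 16 + 45 + 36 = 111
  expect_equal(predict_y(model, 1, 2, 3), 111, tolerance = 1e-6)
})

test_that("filters below the minimum spike count are unusable", {
  cf <- c(10, 1, 0, 0, 0, 0)
  big <- make_readout_fixture(cf, n = 60, filter = 1L)
  small <- make_readout_fixture(cf, n = 4, filter = 2L, seed = 3)
  sp <- dplyr::bind_rows(big, small)
  sp$id <- seq_len(nrow(sp))
  trajs <- tibble::tibble(id = sp$id, reception_y = sp$truth_y,
                          direction = "right")
  model <- fit_readout(sp, trajs)
  co <- tidy(model)
  expect_true(co$usable[co$filter == 1])
  expect_false(co$usable[co$filter == 2])
  expect_error(predict_y(model, 2, 0, 0), "not usable")
  g <- glance(model)
  expect_equal(g$n_usable, 1)
  # all-tiny filters: no usable filter at all
  expect_error(fit_readout(small, trajs[trajs$id %in% small$id, ]), "enough")
})

test_that("the score decodes a single spike's prediction exactly", {
  sp <- make_readout_fixture(c(30, 0.5, 0, 0, 0, 0))
  sp$id <- seq_len(nrow(sp))
  trajs <- tibble::tibble(id = sp$id, reception_y = sp$truth_y,
                          direction = "right")
  model <- fit_readout(sp, trajs, y_range = c(0, 119))
  st <- score_state(model)
  expect_true(all(st$score == 0))
  expect_equal(decode_prediction(st, model), model$prior)  # prior fallback
  one <- list(t = 0.1, filter = 1L, x = 17.3, y = 4.2)
  st2 <- update_score(st, one, model)
  yp <- predict_y(model, 1, 17.3, 4.2)
  expect_equal(decode_prediction(st2, model), yp, tolerance = 1e-6)
  # repeated spikes of the same filter and position keep the argmax put
  st3 <- st2
  for (i in 1:10) st3 <- update_score(st3, one, model)
  expect_equal(decode_prediction(st3, model), yp, tolerance = 1e-6)
  # decode is invariant to uniform positive scaling
  st4 <- st3; st4$score <- st4$score * 37.5
  expect_equal(decode_prediction(st4, model), decode_prediction(st3, model))
})

test_that("reliability weighting favours low-RMSE filters", {
  # two filters with constant predictions 50 and 100 px; rmse 1 vs 10 px
  model <- structure(list(
    coeffs = tibble::tibble(
      filter = c(1L, 2L), n_spikes = c(50L, 50L), usable = TRUE,
      a00 = c(50, 100), a10 = 0, a01 = 0, a20 = 0, a02 = 0, a11 = 0,
      rmse = c(1, 10), direction = c("right", "left")),
    prior = 60, y_range = c(0, 119), score = score_config(),
    min_spikes = 6), class = "snn_readout")
  st <- score_state(model)
  st <- update_score(st, list(t = 0, filter = 1L, x = 0, y = 0), model)
  st <- update_score(st, list(t = 0, filter = 2L, x = 0, y = 0), model)
  expect_lt(abs(decode_prediction(st, model) - 50), 1)
})

test_that("the score leaks toward zero and decoding falls back to the prior", {
  model <- structure(list(
    coeffs = tibble::tibble(
      filter = 1L, n_spikes = 50L, usable = TRUE, a00 = 40, a10 = 0,
      a01 = 0, a20 = 0, a02 = 0, a11 = 0, rmse = 2, direction = "right"),
    prior = 77, y_range = c(0, 119), score = score_config(tau = 0.1),
    min_spikes = 6), class = "snn_readout")
  st <- score_state(model)
  st <- update_score(st, list(t = 0, filter = 1L, x = 0, y = 0), model)
  peak0 <- max(st$score)
  # a later spike first decays the existing score by exp(-dt/tau)
  st2 <- update_score(st, list(t = 0.2, filter = 1L, x = 0, y = 0), model)
  expect_equal(max(st2$score), peak0 * exp(-2) + peak0, tolerance = 1e-9)
  expect_true(all(st2$score >= 0))
})

test_that("direction decoding is a majority vote with recency tie-break", {
  model <- structure(list(
    coeffs = tibble::tibble(
      filter = c(1L, 2L), n_spikes = 50L, usable = TRUE,
      a00 = 0, a10 = 0, a01 = 0, a20 = 0, a02 = 0, a11 = 0,
      rmse = 1, direction = c("right", "left")),
    prior = 60, y_range = c(0, 119), score = score_config(),
    min_spikes = 6), class = "snn_readout")
  mk <- function(filters, ts) tibble::tibble(t = ts, filter = filters)
  expect_identical(predict_direction(mk(c(1, 1, 1), 1:3 / 10), model), "right")
  # 7 right vs 3 left
  expect_identical(predict_direction(
    mk(c(rep(1, 7), rep(2, 3)), 1:10 / 10), model), "right")
  # tie: most recent spike wins
  expect_identical(predict_direction(mk(c(1, 2), c(0.1, 0.2)), model), "left")
  expect_identical(predict_direction(mk(c(2, 1), c(0.1, 0.2)), model), "right")
  # no spikes: abstain
  expect_identical(predict_direction(mk(integer(), numeric()), model),
                   NA_character_)
})

test_that("visibility evaluation is exact under an oracle readout", {
  # spikes whose predictions equal the truth by construction
  model <- structure(list(
    coeffs = tibble::tibble(
      filter = 1L, n_spikes = 50L, usable = TRUE, a00 = 0, a10 = 0,
      a01 = 1, a20 = 0, a02 = 0, a11 = 0, rmse = 0.5, direction = "right"),
    prior = 60, y_range = c(0, 119), score = score_config(),
    min_spikes = 6), class = "snn_readout")
  split <- tibble::tibble(
    id = 1:3, direction = "right", reception_y = c(20, 45, 80),
    duration = 0.4)
  # y coordinate equals the trajectory's reception height -> Y_pred = truth
  spikes <- dplyr::bind_rows(lapply(1:3, function(i)
    tibble::tibble(id = i, t = seq(0.01, 0.39, by = 0.02), layer = 3L,
                   filter = 1L, x = 0, y = split$reception_y[i])))
  ev <- evaluate_visibility(NULL, model, split, spikes = spikes)
  expect_true(all(ev$mean_ae < 1e-6))
  expect_true(all(ev$direction_errors == 0))
  expect_equal(ev$n_trajectories, rep(3, 6))
  # identical predictions when the last 10% contains no events
  sp90 <- spikes[spikes$t <= 0.9 * 0.4, ]
  ev2 <- evaluate_visibility(NULL, model, split,
                             percentages = c(90, 100), spikes = sp90)
  d <- attr(ev2, "details")
  expect_equal(d$prediction[d$percentage == 90],
               d$prediction[d$percentage == 100])
})

test_that("the sweep's incremental scoring matches the per-spike API", {
  set.seed(8)
  model <- structure(list(
    coeffs = tibble::tibble(
      filter = c(1L, 2L), n_spikes = 50L, usable = TRUE,
      a00 = c(20, 60), a10 = c(0.5, -0.2), a01 = c(0.1, 0.3),
      a20 = 0, a02 = 0, a11 = 0,
      rmse = c(2, 5), direction = c("right", "left")),
    prior = 60, y_range = c(0, 119), score = score_config(tau = 0.3),
    min_spikes = 6), class = "snn_readout")
  spikes <- tibble::tibble(
    id = 1L, t = sort(runif(40, 0, 0.4)), layer = 3L,
    filter = sample(1:2, 40, TRUE),
    x = runif(40, 0, 40), y = runif(40, 0, 30))
  split <- tibble::tibble(id = 1L, direction = "right", reception_y = 50,
                          duration = 0.4)
  ev <- evaluate_visibility(NULL, model, split, spikes = spikes)
  d <- attr(ev, "details")
  for (p in c(15, 45, 90)) {
    sp_p <- spikes[spikes$t <= p / 100 * 0.4, ]
    expect_equal(d$prediction[d$percentage == p],
                 decode_prediction(accumulate_score(sp_p, model), model),
                 tolerance = 1e-9)
    expect_identical(d$direction_pred[d$percentage == p],
                     predict_direction(sp_p, model))
  }
})

test_that("readout models round-trip through JSON", {
  sp <- make_readout_fixture(c(5, 1, -1, 0, 0, 0))
  sp$id <- seq_len(nrow(sp))
  trajs <- tibble::tibble(id = sp$id, reception_y = sp$truth_y,
                          direction = "right")
  model <- fit_readout(sp, trajs, y_range = c(0, 119))
  path <- file.path(tempdir(), "readout.json")
  save_readout(model, path)
  back <- load_readout(path)
  expect_equal(back$coeffs$a10, model$coeffs$a10, tolerance = 1e-12)
  expect_equal(back$prior, model$prior, tolerance = 1e-12)
  expect_equal(predict_y(back, 1, 3, 4), predict_y(model, 1, 3, 4),
               tolerance = 1e-9)
})
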