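# Look up per-spike ground truth (angle, speed, ball centre) at the nearest
# frame of the spike's trajectory. `truth_set` is a dataset split tibble with
# columns id and truth (list-column of trajectory_truth).
spike_ground_truth <- function(spikes, truth_set) {
  assert_that(all(c("id", "truth") %in% names(truth_set)),
              "truth_set needs columns id and truth")
  rows <- purrr::map2(truth_set$id, truth_set$truth, function(id, tr) {
    sp <- spikes[spikes$id == id, ]
    if (!nrow(sp)) return(NULL)
    fps <- attr(tr, "fps")
    idx <- pmin(nrow(tr), pmax(1, round(sp$t * fps) + 1))
    dplyr::mutate(sp,
                  ball_x = tr$x[idx], ball_y = tr$y[idx],
                  angle = tr$angle[idx], speed = tr$speed[idx])
  })
  dplyr::bind_rows(rows)
}

# Occurrence counts of each rounded direction (degree bins 0..359) over all
# frames of the presented throws.
direction_occurrences <- function(truth_set) {
  angles <- unlist(purrr::map(truth_set$truth, ~ round(.x$angle) %% 360))
  tabulate(angles + 1, nbins = 360)
}

#' Occurrence-normalised direction tuning curves
#'
#' For each filter, the spike count per 1-degree bin of the ball's direction
#' of motion (at the nearest frame to each spike) is divided by the number
#' of frames on which that direction occurred over all presented throws,
#' then normalised to unit maximum. The preferred direction `theta_c` is the
#' peak bin after circular boxcar smoothing (ties resolved by the circular
#' mean of the tied bins).
#'
#' Angles are degrees clockwise from vertical-up (90 = rightward,
#' 270 = leftward).
#'
#' @param spikes Spike tibble with columns `id`, `filter`, `t`.
#' @param truth_set Dataset split tibble (`id`, `truth` list-column).
#' @param smooth_deg Boxcar window (degrees, odd) used for peak finding.
#' @return A `tuning_curves` tibble: `filter`, `angle` (0..359), `theta_f`;
#'   attribute `summary` is a tibble `filter`, `theta_c`, `n_spikes`
#'   (`theta_c = NA` flags an empty curve).
#' @export
direction_tuning <- function(spikes, truth_set, smooth_deg = 5) {
  occ <- direction_occurrences(truth_set)
  st <- spike_ground_truth(spikes, truth_set)
  filters <- sort(unique(spikes$filter))
  curves <- list(); summaries <- list()
  for (f in filters) {
    ang <- round(st$angle[st$filter == f]) %% 360
    counts <- tabulate(ang + 1, nbins = 360)
    theta <- ifelse(occ > 0, counts / pmax(occ, 1), 0)
    n_sp <- sum(counts)
    if (n_sp == 0 || max(theta) == 0) {
      summaries[[length(summaries) + 1]] <-
        tibble(filter = f, theta_c = NA_real_, n_spikes = n_sp)
      next
    }
    theta <- theta / max(theta)
    curves[[length(curves) + 1]] <-
      tibble(filter = f, angle = 0:359, theta_f = theta)
    summaries[[length(summaries) + 1]] <-
      tibble(filter = f, theta_c = tuning_peak(theta, smooth_deg),
             n_spikes = n_sp)
  }
  out <- if (length(curves)) dplyr::bind_rows(curves) else
    tibble(filter = integer(), angle = integer(), theta_f = double())
  structure(out, summary = dplyr::bind_rows(summaries),
            class = c("tuning_curves", class(out)))
}

# Peak of a 360-bin circular curve after boxcar smoothing; ties -> circular
# mean of the tied bins.
tuning_peak <- function(theta, smooth_deg = 5) {
  half <- (smooth_deg - 1) / 2
  sm <- sapply(0:359, function(a) mean(theta[((a - half):(a + half)) %% 360 + 1]))
  tied <- which(sm == max(sm)) - 1
  if (length(tied) == 1) return(tied)
  # circular mean of tied bins
  rad <- tied * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

#' Per-filter preferred directions
#'
#' @param curves A `tuning_curves` object from [direction_tuning()].
#' @return The summary tibble (`filter`, `theta_c`, `n_spikes`).
#' @export
preferred_directions <- function(curves) attr(curves, "summary")

#' Direction-selectivity index per filter
#'
#' Contrasts each filter's spike counts under leftward vs rightward
#' presentations: `DSI = (R_pref - R_opp) / (R_pref + R_opp)`, with the
#' preferred side the larger count.
#'
#' @param spikes Spike tibble with columns `id`, `filter`.
#' @param directions Tibble `id`, `direction` ("left"/"right") giving each
#'   presentation's motion direction (a dataset split works directly).
#' @return Tibble `filter`, `n_left`, `n_right`, `preferred`, `dsi`.
#' @export
direction_selectivity_index <- function(spikes, directions) {
  df <- dplyr::inner_join(spikes, directions[, c("id", "direction")], by = "id")
  df |>
    dplyr::group_by(.data$filter) |>
    dplyr::summarise(n_left = sum(.data$direction == "left"),
                     n_right = sum(.data$direction == "right"),
                     .groups = "drop") |>
    dplyr::mutate(
      preferred = ifelse(.data$n_right >= .data$n_left, "right", "left"),
      dsi = abs(.data$n_right - .data$n_left) /
        pmax(1e-12, .data$n_right + .data$n_left))
}

# Two-sample Kolmogorov-Smirnov distance (ties allowed).
ks_distance <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  fa <- findInterval(pooled, sort(a)) / length(a)
  fb <- findInterval(pooled, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Speed selectivity against a direction-matched control
#'
#' Compares the distribution of ball speeds at a filter's spike times
#' (`Sf`) with a control distribution (`SfRand`) drawn from the pooled
#' ground-truth (direction, speed) frames, conditioned on directions sampled
#' from the filter's tuning curve. This controls for the correlation between
#' direction and speed imposed by ballistic kinematics: a filter is called
#' speed selective only if its spike speeds differ from what its direction
#' preference alone predicts. The decision uses the two-sample KS distance
#' against a permutation null (labels shuffled) at the 95th percentile.
#'
#' @param spikes Spike tibble (`id`, `filter`, `t`).
#' @param truth_set Dataset split tibble (`id`, `truth`).
#' @param curves [direction_tuning()] curves for the same spikes.
#' @param n_control_factor Control sample size as a multiple of the spike
#'   count.
#' @param n_perm Number of label permutations for the null.
#' @param alpha Test level (the null quantile used is `1 - alpha`).
#' @param min_spikes Below this many spike-speed samples the filter is
#'   flagged `insufficient` and not tested.
#' @param seed Integer seed for the control draw and permutations.
#' @return A `speed_profiles` tibble: `filter`, `n_spikes`, `ks`, `ks_crit`,
#'   `selective`, `insufficient`; attribute `samples` holds per-filter
#'   `Sf` / `SfRand` vectors.
#' @export
speed_selectivity <- function(spikes, truth_set, curves,
                              n_control_factor = 10, n_perm = 1000,
                              alpha = 0.05, min_spikes = 10, seed = 1L) {
  st <- spike_ground_truth(spikes, truth_set)
  # pooled ground truth: speed samples per rounded direction over all frames
  pool <- dplyr::bind_rows(purrr::map(truth_set$truth, function(tr)
    tibble(dir = round(tr$angle) %% 360, speed = tr$speed)))
  pool_by_dir <- split(pool$speed, pool$dir)
  filters <- sort(unique(spikes$filter))
  rows <- list(); samples <- list()
  for (f in filters) {
    sf <- st$speed[st$filter == f]
    if (length(sf) < min_spikes) {
      rows[[length(rows) + 1]] <- tibble(
        filter = f, n_spikes = length(sf), ks = NA_real_,
        ks_crit = NA_real_, selective = NA, insufficient = TRUE)
      next
    }
    th <- curves[curves$filter == f, ]
    res <- with_seed(child_seed(seed, f), {
      n_ctl <- n_control_factor * length(sf)
      dirs <- sample(th$angle, n_ctl, replace = TRUE, prob = th$theta_f)
      ctl <- vapply(as.character(dirs), function(d) {
        v <- pool_by_dir[[d]]
        if (is.null(v)) NA_real_ else v[sample.int(length(v), 1)]
      }, numeric(1))
      ctl <- ctl[!is.na(ctl)]
      ks_obs <- ks_distance(sf, ctl)
      both <- c(sf, ctl)
      n1 <- length(sf)
      null <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(both), n1)
        ks_distance(both[idx], both[-idx])
      }, numeric(1))
      list(ks = ks_obs, crit = quantile(null, 1 - alpha, names = FALSE),
           ctl = ctl)
    })
    samples[[as.character(f)]] <- list(sf = sf, sfrand = res$ctl)
    rows[[length(rows) + 1]] <- tibble(
      filter = f, n_spikes = length(sf), ks = res$ks, ks_crit = res$crit,
      selective = res$ks > res$crit, insufficient = FALSE)
  }
  structure(dplyr::bind_rows(rows), samples = samples,
            class = c("speed_profiles", "tbl_df", "tbl", "data.frame"))
}

#' Mean spike-to-ball distance and ball-coding flag
#'
#' The ball centre is mapped into each layer's retinotopic coordinates
#' (2 px offset per preceding layer under valid 5x5 convolution); `d_n` is
#' the mean Euclidean distance from a filter's spikes to the mapped centre
#' at the nearest frame. Filters with `d_n` strictly under the threshold are
#' flagged as ball-coding. The native threshold (6 px on a 128 x 120 frame)
#' is scaled with the frame diagonal for other resolutions.
#'
#' @param spikes Spike tibble (`id`, `filter`, `t`, `layer`, `x`, `y`).
#' @param truth_set Dataset split tibble (`id`, `truth`).
#' @param threshold Ball-coding threshold in pixels; `NULL` scales the
#'   native 6 px by the frame-diagonal ratio.
#' @return A `tracking_profiles` tibble: `filter`, `n_spikes`, `d_n`,
#'   `ball_coding`, `threshold`; attribute `distances` has the per-spike
#'   distances.
#' @export
ball_distance <- function(spikes, truth_set, threshold = NULL) {
  st <- spike_ground_truth(spikes, truth_set)
  if (is.null(threshold)) {
    w <- attr(truth_set$truth[[1]], "width")
    h <- attr(truth_set$truth[[1]], "height")
    threshold <- 6 * sqrt(w^2 + h^2) / sqrt(128^2 + 120^2)
  }
  st <- dplyr::mutate(st,
                      dist = sqrt((.data$x - (.data$ball_x - 2 * .data$layer))^2 +
                                    (.data$y - (.data$ball_y - 2 * .data$layer))^2))
  out <- st |>
    dplyr::group_by(.data$filter) |>
    dplyr::summarise(n_spikes = dplyr::n(), d_n = mean(.data$dist),
                     .groups = "drop") |>
    dplyr::mutate(ball_coding = .data$d_n < threshold, threshold = threshold)
  structure(out, distances = st,
            class = c("tracking_profiles", class(out)))
}
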