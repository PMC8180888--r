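#' Scene configuration for synthetic ballistic throws
#'
#' Describes the synthetic recording geometry: a fixed camera perpendicular to
#' the plane of a ball thrown between two positions roughly 2.3 m apart. The
#' defaults reproduce the native sensor format (128 x 120 px at 240 frames/s)
#' with a world-to-pixel scale chosen so a full throw spans most of the frame
#' width.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' x rightward and y downward, so a "higher" ball has a *smaller* y.
#'
#' @param width,height Sensor size in pixels.
#' @param fps Frame rate in frames per second.
#' @param ball_radius Ball radius in pixels.
#' @param pixel_pitch World-to-pixel scale in metres per pixel.
#' @param gravity Gravitational acceleration in m/s^2.
#' @param background_level,ball_level,arm_level Gray values in [0, 255].
#' @param arm_enabled Render an animated thrower-arm segment (a rotating
#'   rectangle; it swings forward during the launch and returns afterwards),
#'   providing non-ball motion for tracking analyses.
#' @param arm_length,arm_width Arm segment geometry in pixels. `NULL` scales
#'   them with the frame height.
#' @param distractor_enabled Render an independently moving horizontal bar
#'   that oscillates vertically (sinusoidally), providing sustained non-ball
#'   motion whose direction (up/down) never occurs on the ball's ballistic
#'   path — the stimulus used to probe unsupervised motion tracking.
#' @param distractor_x Bar centre column in pixels (`NULL`: 60% of width).
#' @param distractor_len,distractor_thickness Bar geometry in pixels
#'   (`NULL`: scaled with the frame).
#' @param distractor_period Oscillation period in seconds.
#' @param distractor_amplitude Half peak-to-peak vertical travel in pixels
#'   (`NULL`: 30% of height).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (gray values; 0 disables noise).
#' @param reception_x_left,reception_x_right Pixel columns of the left/right
#'   reception lines where the end point of a throw is read off. `NULL` places
#'   them 10 px inside the left border and 11 px inside the right border.
#' @param seed Integer seed controlling rendering noise and dataset draws.
#' @return A `scene_config` list.
#' @export
#' @examples
#' cfg <- scene_config(noise_sigma = 0)
#' cfg$fps
scene_config <- function(width = 128, height = 120, fps = 240,
                         ball_radius = 4, pixel_pitch = 0.02,
                         gravity = 9.81,
                         background_level = 40, ball_level = 220,
                         arm_level = 180,
                         arm_enabled = FALSE, arm_length = NULL,
                         arm_width = NULL,
                         distractor_enabled = FALSE, distractor_x = NULL,
                         distractor_len = NULL, distractor_thickness = NULL,
                         distractor_period = 0.5, distractor_amplitude = NULL,
                         noise_sigma = 0,
                         reception_x_left = NULL, reception_x_right = NULL,
                         seed = 1L) {
  reception_x_left <- reception_x_left %||% 10
  reception_x_right <- reception_x_right %||% (width - 11)
  arm_length <- arm_length %||% max(6, round(0.22 * height))
  arm_width <- arm_width %||% max(2, round(height / 30))
  distractor_x <- distractor_x %||% round(0.6 * width)
  distractor_len <- distractor_len %||% max(6, round(0.2 * width))
  distractor_thickness <- distractor_thickness %||% max(2, round(height / 24))
  distractor_amplitude <- distractor_amplitude %||% round(0.3 * height)
  cfg <- list(
    width = as.integer(width), height = as.integer(height), fps = fps,
    ball_radius = ball_radius, pixel_pitch = pixel_pitch, gravity = gravity,
    background_level = background_level, ball_level = ball_level,
    arm_level = arm_level, arm_enabled = isTRUE(arm_enabled),
    arm_length = arm_length, arm_width = arm_width,
    distractor_enabled = isTRUE(distractor_enabled),
    distractor_x = distractor_x, distractor_len = distractor_len,
    distractor_thickness = distractor_thickness,
    distractor_period = distractor_period,
    distractor_amplitude = distractor_amplitude,
    noise_sigma = noise_sigma,
    reception_x_left = reception_x_left,
    reception_x_right = reception_x_right,
    seed = as.integer(seed)
  )
  assert_that(cfg$width > 0 && cfg$height > 0 && cfg$fps > 0 &&
                cfg$ball_radius > 0,
              "width, height, fps and ball_radius must be positive")
  assert_that(cfg$noise_sigma >= 0, "noise_sigma must be >= 0")
  assert_that(cfg$reception_x_left >= 0 &&
                cfg$reception_x_right <= cfg$width - 1 &&
                cfg$reception_x_left < cfg$reception_x_right,
              "reception columns must lie inside the frame, left < right")
  structure(cfg, class = "scene_config")
}

# Direction angle convention: degrees clockwise from vertical-up, so 0 = up,
# 90 = horizontal rightward, 180 = down, 270 = horizontal leftward. `vy` is in
# the image frame (positive down).
direction_angle <- function(vx, vy) {
  (atan2(vx, -vy) * 180 / pi) %% 360
}

#' Simulate a ballistic ball trajectory
#'
#' Closed-form ballistic kinematics sampled at the scene frame rate:
#' `x(t) = x0 + vx t`, `y_world(t) = y0_world + vy t - g t^2 / 2`, converted
#' to image pixels (y down). The trajectory is truncated at the first crossing
#' of the reception column on the side the ball travels towards, or when the
#' ball leaves the field of view.
#'
#' @param config A [scene_config()].
#' @param launch A list with `x0`, `y0` (launch centre, pixels), `v0` (launch
#'   speed, m/s, > 0) and `angle0` (degrees above horizontal; 0 launches
#'   rightward, 180 leftward; use e.g. 135 for an up-left throw).
#' @param max_duration Hard cap on the simulated time in seconds (slow or
#'   non-crossing trajectories are truncated there).
#' @return A `trajectory_truth` tibble with one row per frame: `t` (s),
#'   `x`, `y` (ball centre, px), `vx`, `vy` (px/s), `angle` (direction of
#'   motion, degrees clockwise from vertical-up), `speed` (px/s). Attributes:
#'   `launch`, `direction` ("left"/"right"), `reception_x`, `reception_y`
#'   (crossing height in px, `NA` if the throw leaves the frame first),
#'   `crossing_time`, `fps`, `width`, `height`.
#' @export
#' @examples
#' cfg <- scene_config()
#' tr <- simulate_trajectory(cfg, list(x0 = 10, y0 = 86, v0 = 5, angle0 = 40))
#' attr(tr, "reception_y")
simulate_trajectory <- function(config, launch, max_duration = 5) {
  assert_that(inherits(config, "scene_config"), "config must be a scene_config")
  assert_that(launch$v0 > 0, "launch speed must be > 0")
  assert_that(launch$x0 >= 0 && launch$x0 <= config$width - 1 &&
                launch$y0 >= 0 && launch$y0 <= config$height - 1,
              "launch position must be inside the frame")
  pitch <- config$pixel_pitch
  g <- config$gravity
  vx_px <- launch$v0 * cos(launch$angle0 * pi / 180) / pitch
  vy0_px <- -launch$v0 * sin(launch$angle0 * pi / 180) / pitch # y down
  g_px <- g / pitch

  x_of <- function(t) launch$x0 + vx_px * t
  y_of <- function(t) launch$y0 + vy0_px * t + 0.5 * g_px * t^2

  # end of visibility: ball centre out of frame by more than its radius
  r <- config$ball_radius
  margin_ok <- function(t) {
    x <- x_of(t); y <- y_of(t)
    x >= -r & x <= config$width - 1 + r & y >= -r & y <= config$height - 1 + r
  }

  direction <- if (vx_px >= 0) "right" else "left"
  reception_x <- if (direction == "right") config$reception_x_right else
    config$reception_x_left

  t_cross <- NA_real_
  if (abs(vx_px) > 1e-12) {
    tc <- (reception_x - launch$x0) / vx_px
    if (tc > 0 && tc <= max_duration) t_cross <- tc
  }

  # exit time: first sampled time when the ball is no longer visible
  dt <- 1 / config$fps
  t_max_guess <- min(max_duration,
                     if (!is.na(t_cross)) t_cross + 2 * dt else max_duration)
  ts_dense <- seq(0, t_max_guess, by = dt)
  visible <- margin_ok(ts_dense)
  if (!visible[1]) abort("trajectory never enters the field of view")
  first_exit <- which(!visible)[1]
  t_exit <- if (is.na(first_exit)) Inf else ts_dense[first_exit]

  t_end <- min(t_exit, max_duration,
               if (!is.na(t_cross)) t_cross + dt else Inf)
  crossed <- !is.na(t_cross) && t_cross < t_exit
  reception_y <- if (crossed) y_of(t_cross) else NA_real_
  if (crossed && (reception_y < 0 || reception_y > config$height - 1)) {
    crossed <- FALSE
    reception_y <- NA_real_
  }

  times <- seq(0, t_end, by = dt)
  if (length(times) < 2) abort("trajectory too short to sample at this fps")
  vy_px <- vy0_px + g_px * times
  vx_vec <- rep(vx_px, length(times))
  out <- tibble(
    t = times,
    x = x_of(times), y = y_of(times),
    vx = vx_vec, vy = vy_px,
    angle = direction_angle(vx_vec, vy_px),
    speed = sqrt(vx_vec^2 + vy_px^2)
  )
  structure(out,
            class = c("trajectory_truth", class(out)),
            launch = launch, direction = direction,
            reception_x = reception_x,
            reception_y = if (crossed) reception_y else NA_real_,
            crossing_time = if (crossed) t_cross else NA_real_,
            fps = config$fps, width = config$width, height = config$height)
}

# Rasterise a filled disk onto a height x width matrix of pixel-centre
# coordinates (0-based).
rasterise_disk <- function(frame, cx, cy, r, level) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  frame[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- level
  frame
}

# Rasterise a thick segment from (x1,y1) to (x2,y2) with half-width hw.
rasterise_segment <- function(frame, x1, y1, x2, y2, hw, level) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- if (len2 < 1e-12) 0 else pmin(1, pmax(0, ((xs - x1) * dx + (ys - y1) * dy) / len2))
  d2 <- (xs - (x1 + tt * dx))^2 + (ys - (y1 + tt * dy))^2
  frame[d2 <= hw^2] <- level
  frame
}

#' Render a trajectory as a grayscale frame sequence
#'
#' The ball is drawn as a filled disk (no anti-aliasing) at each ground-truth
#' centre. With `arm_enabled`, a thrower-arm segment pivoting near the launch
#' point swings forward during the first 40% of the frames and returns during
#' the remainder. Additive Gaussian noise (`noise_sigma`) is applied last;
#' rendering is deterministic given `config$seed`.
#'
#' @param truth A `trajectory_truth` from [simulate_trajectory()].
#' @param config The [scene_config()] used to simulate it.
#' @return A `frame_sequence`: a `height x width x n_frames` array of gray
#'   values in [0, 255] with attribute `fps`.
#' @export
render_frames <- function(truth, config) {
  assert_that(inherits(truth, "trajectory_truth"), "truth must be a trajectory_truth")
  assert_that(isTRUE(all.equal(attr(truth, "fps"), config$fps)),
              "truth was not sampled at config$fps")
  n <- nrow(truth)
  h <- config$height; w <- config$width
  frames <- array(config$background_level, dim = c(h, w, n))
  launch <- attr(truth, "launch")
  n_fwd <- max(1, floor(0.4 * n))
  for (i in seq_len(n)) {
    fr <- frames[, , i]
    if (config$distractor_enabled) {
      # horizontal bar oscillating vertically: pure up/down motion, a
      # direction absent from the ballistic path
      ph <- 2 * pi * truth$t[i] / config$distractor_period
      yd <- config$height / 2 + config$distractor_amplitude * sin(ph)
      fr <- rasterise_segment(fr,
                              config$distractor_x - config$distractor_len / 2,
                              yd,
                              config$distractor_x + config$distractor_len / 2,
                              yd,
                              config$distractor_thickness / 2,
                              config$arm_level)
    }
    if (config$arm_enabled) {
      px <- launch$x0
      py <- min(h - 1, launch$y0 + config$arm_length)
      s <- if (attr(truth, "direction") == "right") 1 else -1
      # arm orientation, degrees clockwise from vertical-up at the pivot
      phi <- if (i <= n_fwd) {
        140 - 100 * (i - 1) / max(1, n_fwd - 1)
      } else {
        40 + 100 * (i - n_fwd) / max(1, n - n_fwd)
      }
      tipx <- px + s * config$arm_length * sin(phi * pi / 180)
      tipy <- py - config$arm_length * cos(phi * pi / 180)
      fr <- rasterise_segment(fr, px, py, tipx, tipy,
                              config$arm_width / 2, config$arm_level)
    }
    fr <- rasterise_disk(fr, truth$x[i], truth$y[i], config$ball_radius,
                         config$ball_level)
    frames[, , i] <- fr
  }
  if (config$noise_sigma > 0) {
    frames <- with_seed(config$seed, {
      frames + rnorm(length(frames), sd = config$noise_sigma)
    })
    frames[frames < 0] <- 0
    frames[frames > 255] <- 255
  }
  structure(frames, fps = config$fps, class = "frame_sequence")
}

# Draw one set of launch parameters from configured ranges.
draw_launch <- function(config, speed_range, angle_range, y0_frac) {
  rightward <- runif(1) < 0.5
  v0 <- runif(1, speed_range[1], speed_range[2])
  ang <- runif(1, angle_range[1], angle_range[2])
  y0 <- round(y0_frac * config$height)
  if (rightward) {
    list(x0 = config$reception_x_left, y0 = y0, v0 = v0, angle0 = ang)
  } else {
    list(x0 = config$reception_x_right, y0 = y0, v0 = v0, angle0 = 180 - ang)
  }
}

#' Generate a seeded train/test dataset of synthetic throws
#'
#' Draws launch parameters (both directions, a range of speeds and elevation
#' angles), simulates and renders each throw, and splits the set into
#' disjoint train and test partitions. Throws whose trajectory leaves the
#' field of view before crossing the reception line are discarded and
#' redrawn, so every item has a defined reception height (mirroring a
#' recording session in which every throw is caught).
#'
#' @param n_trajectories Number of throws (>= 2).
#' @param config A [scene_config()].
#' @param split_fraction Training fraction in (0, 1); the train split gets
#'   `round(split_fraction * n)` items.
#' @param speed_range,angle_range Launch-speed (m/s) and elevation-angle
#'   (degrees) ranges.
#' @param y0_frac Launch height as a fraction of frame height.
#' @param frontend Optional [frontend_config()]. When supplied, each item is
#'   encoded to an event stream immediately and the raw frames are dropped
#'   (memory-friendly for large sets).
#' @param keep_frames Keep the rendered frames in the output (default: only
#'   when no `frontend` is given).
#' @return A list with `train` and `test` tibbles (columns `id`, `direction`,
#'   `reception_y`, `duration`, and list-columns `launch`, `truth`, plus
#'   `frames` and/or `events`), and `config`.
#' @export
make_dataset <- function(n_trajectories, config, split_fraction = 0.7,
                         speed_range = c(4.5, 6.5), angle_range = c(25, 55),
                         y0_frac = 0.72,
                         frontend = NULL, keep_frames = is.null(frontend)) {
  assert_that(n_trajectories >= 2, "need at least 2 trajectories")
  assert_that(split_fraction > 0 && split_fraction < 1,
              "split_fraction must be in (0, 1)")
  n_train <- round(split_fraction * n_trajectories)
  assert_that(n_train >= 1 && n_train <= n_trajectories - 1,
              "n too small to populate both splits")

  items <- with_seed(config$seed, {
    out <- vector("list", n_trajectories)
    i <- 1
    attempts <- 0
    while (i <= n_trajectories) {
      attempts <- attempts + 1
      if (attempts > 50 * n_trajectories)
        abort("could not draw enough in-frame trajectories; widen the ranges")
      launch <- draw_launch(config, speed_range, angle_range, y0_frac)
      tr <- tryCatch(simulate_trajectory(config, launch), error = function(e) NULL)
      if (is.null(tr) || is.na(attr(tr, "reception_y"))) next
      out[[i]] <- list(launch = launch, truth = tr)
      i <- i + 1
    }
    out
  })

  rows <- purrr::imap(items, function(it, i) {
    cfg_i <- config
    cfg_i$seed <- child_seed(config$seed, i)
    frames <- render_frames(it$truth, cfg_i)
    row <- tibble(
      id = i,
      direction = attr(it$truth, "direction"),
      reception_y = attr(it$truth, "reception_y"),
      duration = max(it$truth$t),
      launch = list(it$launch),
      truth = list(it$truth)
    )
    if (!is.null(frontend)) row$events <- list(encode_sequence(frames, frontend))
    if (keep_frames) row$frames <- list(frames)
    row
  })
  all <- dplyr::bind_rows(rows)

  idx_train <- with_seed(child_seed(config$seed, 997L),
                         sort(sample.int(n_trajectories, n_train)))
  list(train = all[idx_train, ],
       test = all[setdiff(seq_len(n_trajectories), idx_train), ],
       config = config)
}

#' Write / read trajectory ground truth
#'
#' CSV with one row per frame (`t,x,y,vx,vy,angle,speed`) plus a JSON sidecar
#' (same path with extension `.json`) holding the launch parameters,
#' direction, reception height and scene metadata.
#'
#' @param truth A `trajectory_truth`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `trajectory_truth` (reader).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  side <- list(
    launch = attr(truth, "launch"), direction = attr(truth, "direction"),
    reception_x = attr(truth, "reception_x"),
    reception_y = attr(truth, "reception_y"),
    crossing_time = attr(truth, "crossing_time"),
    fps = attr(truth, "fps"), width = attr(truth, "width"),
    height = attr(truth, "height")
  )
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  structure(df,
            class = c("trajectory_truth", class(df)),
            launch = as.list(side$launch), direction = side$direction,
            reception_x = side$reception_x,
            reception_y = side$reception_y %||% NA_real_,
            crossing_time = side$crossing_time %||% NA_real_,
            fps = side$fps, width = side$width, height = side$height)
}
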