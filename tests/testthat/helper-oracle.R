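# Independent clock-driven reference simulator for the spiking network.
#
# Dense state, fixed ticks: every neuron's membrane potential is decayed once
# per tick; deliveries scheduled on a tick are applied after the decay, in
# (layer, y, x, channel) order, mirroring the event queue's tie-breaks. Used
# as the oracle for the event-driven simulator on streams whose event times
# lie on the tick grid.

clock_sim <- function(network, events, tick = 2^-17, learning_layer = 0) {
  del <- network$delays$delays
  layers <- network$layers
  nl <- length(layers)

  # expand delay lines exactly as the implementation does (same arithmetic)
  deliv <- do.call(rbind, lapply(seq_along(del), function(d)
    data.frame(t = events$t + del[d], x = events$x, y = events$y,
               c = 2L * (d - 1L) + events$polarity)))
  deliv$tick <- as.integer(round(deliv$t / tick))

  in_w <- network$width; in_h <- network$height; in_ch <- 6L
  st <- list()
  for (k in seq_len(nl)) {
    mw <- in_w - 4L; mh <- in_h - 4L
    st[[k]] <- list(
      u = array(0, dim = c(layers[[k]]$n_filters, mw, mh)),
      pen = vector("list", layers[[k]]$n_filters * mw * mh),
      last_in = array(-Inf, dim = c(in_ch, in_w, in_h)),
      decay = exp(-tick / layers[[k]]$tau_memb),
      in_w = in_w, in_h = in_h, in_ch = in_ch, mw = mw, mh = mh)
    in_ch <- layers[[k]]$n_filters
    in_w <- mw; in_h <- mh
  }

  penalty_at <- function(pen, tt, t_thresh) {
    if (is.null(pen) || !nrow(pen)) return(0)
    dt <- tt - pen$t
    sum(ifelse(dt < 0 | dt >= 2 * t_thresh, 0,
               ifelse(dt < t_thresh, pen$a * dt / t_thresh,
                      pen$a * (2 - dt / t_thresh))))
  }

  spikes <- list()
  max_tick <- max(deliv$tick)
  weights <- lapply(layers, function(l) l$weights)

  for (tk in 0:max_tick) {
    for (k in seq_len(nl)) st[[k]]$u <- st[[k]]$u * st[[k]]$decay
    tt <- tk * tick
    empty_pend <- data.frame(x = integer(), y = integer(), c = integer())
    pending <- rep(list(empty_pend), nl)
    dd <- deliv[deliv$tick == tk, , drop = FALSE]
    if (nrow(dd)) pending[[1]] <- dd[order(dd$y, dd$x, dd$c), c("x", "y", "c")]
    for (k in seq_len(nl)) {
      lay <- layers[[k]]
      while (nrow(pending[[k]])) {
        p <- pending[[k]]
        pending[[k]] <- empty_pend
        p <- p[order(p$y, p$x, p$c), , drop = FALSE]
        for (r in seq_len(nrow(p))) {
          ex <- p$x[r]; ey <- p$y[r]; ec <- p$c[r]
          st[[k]]$last_in[ec + 1, ex + 1, ey + 1] <- tt
          for (Y in max(0, ey - 4):min(st[[k]]$mh - 1, ey)) {
            for (X in max(0, ex - 4):min(st[[k]]$mw - 1, ex)) {
              dy <- ey - Y; dx <- ex - X
              for (f in seq_len(lay$n_filters)) {
                st[[k]]$u[f, X + 1, Y + 1] <- st[[k]]$u[f, X + 1, Y + 1] +
                  weights[[k]][f, dy + 1, dx + 1, ec + 1] * lay$w_max
                nidx <- f + lay$n_filters * (X + st[[k]]$mw * Y)
                thr <- lay$u_thresh +
                  penalty_at(st[[k]]$pen[[nidx]], tt, lay$t_thresh)
                uu <- st[[k]]$u[f, X + 1, Y + 1]
                if (uu >= thr) {
                  spikes[[length(spikes) + 1]] <- data.frame(
                    tick = tk, layer = k, filter = f, x = X, y = Y, u = uu)
                  uprop <- mean(st[[k]]$u[, X + 1, Y + 1]^2)
                  if (learning_layer == k) {
                    for (cc in seq_len(st[[k]]$in_ch))
                      for (ddy in 0:4) for (ddx in 0:4) {
                        ti <- st[[k]]$last_in[cc, X + ddx + 1, Y + ddy + 1]
                        wij <- weights[[k]][f, ddy + 1, ddx + 1, cc]
                        weights[[k]][f, ddy + 1, ddx + 1, cc] <-
                          if (tt - ti < lay$tau_ltp)
                            wij + (1 - wij) * lay$a_ltp
                          else wij - wij * lay$a_ltd
                      }
                  }
                  others <- setdiff(seq_len(lay$n_filters), f)
                  st[[k]]$u[others, X + 1, Y + 1] <-
                    st[[k]]$u[others, X + 1, Y + 1] - lay$f_inst * uprop
                  st[[k]]$pen[[nidx]] <- rbind(
                    st[[k]]$pen[[nidx]],
                    data.frame(t = tt, a = lay$f_long * uprop))
                  st[[k]]$u[f, X + 1, Y + 1] <- 0
                  if (k < nl) {
                    pending[[k + 1]] <- rbind(
                      pending[[k + 1]],
                      data.frame(x = X, y = Y, c = f - 1))
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  list(spikes = if (length(spikes)) do.call(rbind, spikes) else
         data.frame(tick = integer(), layer = integer(), filter = integer(),
                    x = integer(), y = integer(), u = double()),
       weights = weights)
}

# Random event stream on the tick grid, inside a w x h sensor.
random_grid_stream <- function(n, w, h, duration = 0.02, tick = 2^-17,
                               seed = 1) {
  set.seed(seed)
  tibble::tibble(
    t = sort(sample.int(round(duration / tick), n, replace = TRUE)) * tick,
    x = sample.int(w, n, replace = TRUE) - 1L,
    y = sample.int(h, n, replace = TRUE) - 1L,
    polarity = sample(0:1, n, replace = TRUE)
  )
}
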