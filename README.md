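# snntraj

Event-based prediction of ball-trajectory end points with a spiking neural
network, in R.

A fixed camera watches a ball thrown between two positions about 2.3 m
apart. `snntraj` emulates the full processing chain of a bio-inspired
vision system that predicts, long before the throw is over, the height at
which the ball will cross a fixed reception line and whether it travels
left or right:

1. **Event-camera emulation.** Consecutive frames are differenced, filtered
   with a centre–surround difference-of-Gaussians, thresholded, and emitted
   as an address-event stream `(t, x, y, polarity)`. Suprathreshold
   magnitudes are converted to spike latencies (largest first):
   `Δt_rel = (1 − m) / fps`, so each frame's spikes tile the inter-frame
   interval.
2. **Spiking network.** A three-layer convolutional network of leaky
   integrate-and-fire neurons, `U(t) = U_rest + (U(t_k) − U_rest)
   e^{−(t−t_k)/τ_memb}`, with 5×5 weight-shared kernels (stride 1). Each
   sensor event is duplicated onto three delay lines (six input channels:
   ON/OFF × delays), so a purely weight-based rule can select the delay
   that synchronises inputs for a preferred motion — the mechanism behind
   direction and speed selectivity. Learning is a simplified multiplicative
   STDP, `ΔW = (1 − W)·a_LTP` if `t_post − t_pre < τ_LTP`, else
   `ΔW = −W·a_LTD`, regulated by lateral inhibition across filters at a
   position and a transient inverted-V threshold penalty.
3. **Readout.** Per output filter, a second-degree polynomial
   `Y_pred = a00 + a10 x + a01 y + a20 x² + a02 y² + a11 xy` maps spiking
   neurons' map positions to the reception height; each spike adds a kernel
   weighted by `1/RMSE` to a leaky score over candidate heights, whose
   argmax is the prediction. Left/right is a majority vote over the spiking
   filters' training direction labels.
4. **Analyses.** Occurrence-normalised direction tuning curves `θf`,
   speed selectivity against a direction-matched resampled control (KS +
   permutation test), and unsupervised motion tracking via the mean
   spike-to-ball distance `D_n`.

The recordings behind the original study are not public, so the package
ships a synthetic-scene generator (`make_dataset()`) producing ballistic
throws with exact ground truth — closed-form kinematics rendered at
240 fps, optional thrower-arm and oscillating-bar distractor motion — and
every packaged experiment runs on those scenes.

## Worked example

A scaled study: 64 × 48 px scenes, 80 throws (60 train / 20 test), layers
of 16/20/24 filters, one STDP pass per layer.

```r
library(snntraj)

scene <- scene_config(width = 64, height = 48, fps = 240, ball_radius = 2,
                      pixel_pitch = 0.04, noise_sigma = 0, seed = 101)

# detection threshold tuned for ~0.3% active pixels per frame
probe <- render_frames(
  simulate_trajectory(scene, list(x0 = 10, y0 = 35, v0 = 5, angle0 = 40)),
  scene)
fe <- frontend_config(tune_threshold(probe, frontend_config(1, fps = 240)),
                      fps = 240)

ds  <- make_dataset(80, scene, split_fraction = 0.75,
                    speed_range = c(4.5, 6), angle_range = c(25, 50),
                    frontend = fe)
net <- new_network(64, 48, layers = default_layer_params(c(16L, 20L, 24L)),
                   seed = 101) |>
  train_network(ds$train$events)

model <- fit_readout(run_dataset(net, ds$train), ds$train)
model
#> <snn_readout> 24/24 usable filters, prior 22.79 px, mean RMSE 4.78 px

evaluate_visibility(net, model, ds$test)
#>   percentage  mean_ae    sd_ae direction_errors n_trajectories baseline_ae
#> 1         15 4.966554 3.321590                6             20    5.550469
#> 2         30 4.522036 3.129050                0             20    5.550469
#> 3         45 4.125112 2.867836                0             20    5.550469
#> 4         60 3.678925 2.559391                0             20    5.550469
#> 5         75 3.295192 2.276414                0             20    5.550469
#> 6         90 2.958558 1.983411                0             20    5.550469
```

Reading the table: seeing only the first 15% of each throw, the network
predicts the reception height with a mean absolute error of 5.0 px (the
naive baseline — always predicting the training-mean height of 22.8 px —
errs by 5.6 px); with 90% visible the error falls to 3.0 px, the spread of
errors narrows from 3.3 to 2.0 px, and the left/right call is error-free
from 30% visibility onward.

`autoplot(evaluate_visibility(...))` draws the sweep; `plot_kernels(net, 1)`
shows the learned ON/OFF × delay kernels; `direction_tuning()` /
`speed_selectivity()` / `ball_distance()` characterise what the filters
became selective to. A thin command-line wrapper lives at
`inst/cli/snntraj.R` (`simulate`, `run`, `default-config`).

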