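---
title: "Methods: event-based trajectory prediction with a spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-based trajectory prediction with a spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`snntraj` implements a complete bio-inspired vision pipeline for predicting
where a thrown ball will arrive before the throw is over. A fixed camera
watches a ball travel between two positions roughly 2.3 m apart; the task is
to report, from only the first 15–90% of the throw, the height at which the
ball will cross a fixed reception line, plus its left/right direction. The
pipeline has four stages:

1. **Event-camera emulation** (`frontend_*`): consecutive grayscale frames
   are differenced, filtered with a centre–surround difference-of-Gaussians
   (DoG), thresholded, and converted to an address-event stream. Within each
   inter-frame interval the suprathreshold responses are emitted
   largest-magnitude-first via an intensity-to-latency code: with `m` the
   min–max-normalised magnitude, the relative latency is `(1 − m) / fps`, so
   a frame's spikes tile exactly the interval `[F/fps, (F+1)/fps]`.
2. **Spiking network** (`snn_*`, `run_network()`, `train_network()`): a
   three-layer convolutional network of leaky integrate-and-fire neurons
   (exponential leak toward rest 0, instantaneous weighted increments
   `W · w_max`, threshold crossing → spike → reset). Each sensor event is
   duplicated onto three delay lines, giving six input channels per pixel
   (ON/OFF × 3 delays): *delay selection* lets a purely weight-based
   learning rule pick the delay that synchronises inputs for a preferred
   motion direction and speed. Layers are weight-shared 5×5 kernels with
   stride 1 (valid convolution: each layer's retinotopic map shrinks by 4 px
   per side-pair). Unsupervised learning is a simplified multiplicative
   STDP: at each postsynaptic spike, afferents whose last spike falls inside
   the LTP window are potentiated by `(1 − W)·a_ltp`, all others (including
   silent afferents) depressed by `W·a_ltd`, which soft-bounds weights in
   (0, 1). Two regulators shape competition: *lateral inhibition* (a spike
   subtracts `f_inst · U_propinh` from the other filters at that position,
   where `U_propinh` is the mean squared membrane potential across filters
   there) and a transient *homeostatic threshold penalty* (each spike adds
   an inverted-V term of peak `f_long · U_propinh` rising and decaying over
   `t_thresh` seconds each).
3. **Readout** (`fit_readout()`, `evaluate_visibility()`): per output
   filter, a second-degree polynomial regression maps the spiking neuron's
   map position `(x, y)` to the reception height; each filter's training
   RMSE weights its vote. Every spike adds a kernel (peak `1/RMSE`, width
   ∝ RMSE) to a 1-px score array over candidate heights; the array leaks
   exponentially; the prediction is the score argmax, falling back to the
   training-mean height before any spike arrives. Left/right is decoded
   separately by majority vote over the spiking filters' training direction
   labels — deliberately decoupled from the regression.
4. **Analyses** (`direction_tuning()`, `speed_selectivity()`,
   `ball_distance()`): occurrence-normalised direction tuning (spike counts
   per 1° of ball direction divided by how often that direction occurred),
   speed selectivity against a direction-matched resampled control with a
   KS-permutation decision rule, and unsupervised tracking via the mean
   spike-to-ball distance `d_n`.

## Event-driven simulation and its oracle

The simulator is event-driven: neuron state is touched only when a spike is
delivered, with the leak applied lazily as `exp(−Δt/τ)`. Determinism is
guaranteed by a total order on deliveries — `(t, layer, y, x, channel)` —
and, within one delivered event, raster order over target positions with
filters ascending. The test suite validates this against an independent
clock-driven reference that decays every neuron every tick and applies the
same tie-breaks. The tick is `2^-17` s (≈ 0.0076 ms): a binary-exact step,
finer than the 0.01 ms a naive reference would use, chosen so that
event-plus-delay arithmetic is bit-identical in both simulators and the
comparison is meaningful down to tie-break order. On random streams the two
simulators agree spike-for-spike, with membrane values at spike times
matching to better than 1e-9 relative.

## Parameters

The three-layer parameter set shipped as `default_layer_params()` (time
constants in seconds, potentials on a base threshold of 1):

| layer | w_max | τ_memb | N_f | τ_LTP | a_LTP | a_LTD | f_inst | f_long | T_thresh |
|------:|------:|-------:|----:|------:|------:|------:|-------:|-------:|---------:|
| 1 | 1.873 | 0.010 | 60 | 0.0754 | 0.00195 | 0.00050 | 3.00 | 2.89 | 0.031 |
| 2 | 0.813 | 0.052 | 80 | 0.0236 | 0.01310 | 0.00118 | 2.82 | 2.41 | 0.023 |
| 3 | 1.308 | 0.039 | 100 | 0.0368 | 0.00815 | 0.00198 | 3.46 | 1.90 | 0.051 |

Values not part of that calibration are package choices, all configurable:

* **Base threshold** `u_thresh = 1` potential unit per layer; the `w_max`
  values are interpreted on this scale.
* **Delays** default to 1 and 2 frame periods (4.17 / 8.33 ms at 240 fps):
  the smallest delays that let the three lines sample distinct frames.
* **Weight initialisation**: independent uniform on [0.3, 0.7], seeded.
* **DoG**: σ_centre 1 px, σ_surround 2 px, 7×7 zero-mean kernel. The
  detection threshold is scene-dependent; `tune_threshold()` picks the
  pooled-quantile value that makes 0.3% of pixels active per frame on a
  noiseless probe scene (the 0.2–0.5% band typical of sparse motion
  scenes).
* **Score kernel**: Gaussian, centre at the filter's prediction, σ =
  max(RMSE, 1 px), peak 1/max(RMSE, ε); a triangular kernel is available.
  The score leak defaults to τ = 0.5 s. The decode refines the argmax bin
  by parabolic interpolation of the log-score, which is exact for a single
  Gaussian kernel.
* **Tie-breaks**: equal event magnitudes encode in raster (y, x) order;
  equal tuning-curve peaks resolve to the circular mean of the tied bins;
  an equal left/right vote goes to the most recent spike's label.
* **Silent gaps**: trajectories are separated by 2 s of silence in the
  recording protocol this emulates. Because every state variable decays to
  baseline well within 2 s at the table's constants, the default
  implementation resets state between presentations; `gap_mode = "strict"`
  simulates the gap literally, and the two are verified equivalent in the
  tests.

## The synthetic-scene generator

The unreleased recordings are stood in for by `make_dataset()`: ballistic
kinematics in closed form (`x(t) = x₀ + vₓt`,
`y(t) = y₀ + v_y t − ½gt²`), sampled at 240 fps on a 128 × 120 px sensor
with a world scale of 0.02 m/px so a full throw spans most of the frame.
Launches are drawn from both directions with speeds 4.5–6.5 m/s and
elevations 25–55°, from a launch height of 0.72 × frame height — ranges
chosen so that throws stay inside the field of view and cross the reception
line at varied heights; throws that would leave the frame first are redrawn.
Direction angles are degrees clockwise from vertical-up (90° = rightward,
270° = leftward), so ascending throws sit near 45°/315° and trajectory tops
near 90°/270°. Pixel coordinates are 0-based, origin top-left, y downward —
higher balls have *smaller* y. Optional non-ball motion is available in two
forms: a thrower-arm segment that swings forward during the launch and
returns afterwards, and an independently oscillating horizontal bar whose
up/down motion direction never occurs on a ballistic path.

What the generator does *not* emulate: photorealistic shading, motion blur,
rolling shutter, sensor noise beyond additive Gaussian pixel noise, and
human movement variability. Tests passing on these scenes therefore
demonstrate the mechanisms — latency coding, delay selection, STDP feature
learning, RMSE-weighted decoding — not performance on natural recordings.

## Scaled study conditions

Full-scale runs (297 throws, 60/80/100 filters at 128 × 120) are not needed
to exercise any mechanism, so the packaged experiments use scaled designs:

* **End-to-end visibility sweep**: 64 × 48 px (0.04 m/px), 80 throws split
  60/20, layers of 16/20/24 filters, speeds 4.5–6 m/s, elevations 25–50°
  (the narrower ranges keep throws inside the shorter frame). One STDP pass
  per layer. The mean absolute end-point error falls monotonically from
  15% to 90% visibility and beats the constant training-mean baseline; the
  left/right vote is error-free from 30% visibility on this design.
* **Direction selectivity**: one layer of 8 filters on 48 × 48 px, a dot
  sweeping left or right at 1 px/frame at varied heights, 100 presentations
  per direction, delays {0, 1, 2} frames.
* **Unsupervised tracking**: 48 × 48 px scenes containing the ball plus
  sustained distractor motion, analysed with `d_n` per filter.

## The delay-ablation finding

Re-training the direction-selectivity design with all delays forced to zero
was expected to abolish direction tuning, delay selection being the model's
temporal mechanism. It does not: mean DSI is statistically indistinguishable
with and without delays on this stimulus. The reason is a property of
frame-differencing front ends: a rigid moving dot always produces an ON
crescent on its leading edge and an OFF crescent on its trailing edge, so
motion direction is encoded *spatially* in the instantaneous ON/OFF layout,
and a 5 × 5 kernel can become direction selective with no temporal
processing at all. Delay selection remains beneficial for speed tuning and
for stimuli without polarity asymmetries, but for solid moving objects seen
through a frame-difference camera it is not necessary for direction
discrimination. The corresponding acceptance check is left failing rather
than weakened, since the expectation itself is what the experiment refutes.

## Tracking threshold at reduced scale

At native scale a filter "mostly encoding the ball" has a mean
spike-to-ball distance under 6 px. The package's default for other frame
sizes scales this threshold with the frame diagonal. For the scaled
tracking scenes the tests instead use two ball radii, a geometric argument:
events are generated on the ball's *edge* and spread further by the DoG
surround (σ = 2 px adds proportionally more blur to a 3-px ball than to the
native one), and a spiking neuron's receptive-field centre can sit ±2 px
from the pattern that drives it. On ball-only scenes the measured mean
distance of every filter falls in 1.5–1.9 radii, so two radii separates
ball-dominated filters from mixed ones at this scale.

## Speed-selectivity control

Because ballistic kinematics correlate direction with speed, raw spike-speed
distributions cannot show speed tuning. The control `SfRand` resamples
pooled ground-truth speeds conditioned on directions drawn from the
filter's own tuning curve, and the decision rule is the two-sample KS
distance against a label-permutation null at the 95th percentile. The rule
is calibrated: on constructed null filters (direction-band gated, speed
blind) the false-positive rate stays near the nominal 5%.

## Numerical and degenerate-input choices

* A single suprathreshold pixel (or an all-equal frame) encodes with zero
  latency.
* Membrane potentials may go below rest after inhibition; the leak then
  decays them back. There is no refractory period.
* `U_propinh` is computed over the filters at the spiking position, with
  the spiker's (pre-reset, suprathreshold) value included.
* STDP updates the shared kernel immediately at each postsynaptic spike
  using that neuron's local last-presynaptic-spike view; LTD applies to
  every afferent outside the LTP window, including never-active ones.
* Ground truth at spike times uses nearest-frame lookup (≤ 2.08 ms error
  at 240 fps).
* Expired threshold-penalty terms are pruned on evaluation.
* The trajectory simulator truncates at the first reception-line crossing
  toward the travel direction, at frame exit (centre out of view by more
  than a radius), or at a 5 s horizon.

## Known limitations

* The emulation is frame-derived: true asynchronous sensors have no frame
  quantisation, and results on their streams may differ (notably the
  delay-ablation finding above).
* Filter counts and scene sizes in the packaged experiments are an order of
  magnitude below the full-scale design; absolute pixel errors are not
  comparable to full-scale numbers, only the qualitative orderings
  (visibility trend, trained vs untrained, baseline comparisons) are.
* The readout is deliberately simple (per-filter quadratic + score vote);
  it is a probe of the network's code, not a competitive decoder.
* One-layer tracking filters separate a direction-distinct distractor from
  the ball; richer scenes would need the deeper layers and larger filter
  banks of the full-scale design. Whether an individual filter becomes
  *fully* ball-exclusive at 16 filters depends on the weight
  initialisation: the homeostatic threshold penalty deliberately rotates
  firing across filters, which guarantees coverage but works against
  exclusivity in small banks. The packaged tracking design uses a fixed
  seed; bar-locked (non-ball) filters emerge for every initialisation
  tried, fully ball-exclusive ones for a minority.
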