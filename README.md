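# iaakit

Flying honeybees actively position their antennae, and the inter-antennal
angle (IAA) — the angle between the base-to-tip lines of the left and right
antennae — is set by two antagonistic sensory inputs: frontal **airflow**
(sensed by Johnston's organ) pushes the antennae forward and *decreases*
IAA, while front-to-back **optic flow** (sensed by the compound eyes) pushes
them backward and *increases* it. `iaakit` implements the complete
measurement-and-analysis chain for this behaviour, for behavioural
physiologists working from high-speed video of tethered or freely flying
bees:

* **Geometry** — 11-parameter DLT camera calibration, two-view linear
  triangulation, IAA from four digitized landmarks, digitization error from
  antennal-length variation, and groundspeed/airspeed/windspeed vector
  algebra (groundspeed = airspeed + windspeed).
* **Circular statistics** — circular mean/SD and a permutation
  implementation of **Moore's paired circular test**
  (R\* = |Σᵢ rankᵢ·(cos θᵢ, sin θᵢ)| / n^{3/2} over ranked rectangular pair
  differences; exact enumeration of all 2ⁿ within-pair swaps for n ≤ 20),
  plus ANOVA + Tukey HSD contrasts against a hypothetical zero mean.
* **Airflow response** — steady-state binning, plateau normalization,
  four-parameter logistic fits IAA(v) = lower + A·logistic(−(v − v50)/k),
  and detection of the *dynamic region* (the airspeed interval over which
  IAA changes significantly with each 0.5 m/s step).
* **Optic-flow response** — per-bee saturation-threshold detection,
  change-prediction scoring of randomized temporal-frequency sequences
  against a scrambled-data null, low-range graded responses, and sinusoid
  tracking.
* **Multimodal analyses** — regime-transition ΔIAA antagonism, constant-cue
  offset classification (adaptation / uniform offset / nonuniform), and a
  crossmodal speedometer calibration (tf = k·v inside the airspeed dynamic
  range, giving the extrapolating estimator v̂ = tf/k).
* **Synthetic data** — a generative bee model (sigmoid airspeed response,
  adapting optic-flow change-integrator saturating at a per-bee threshold,
  wrapped-Gaussian frame noise, two-camera landmark projection, free-flight
  trajectories holding groundspeed against wind) so the entire pipeline runs
  and is tested without any external recordings.

## Worked example

Ten synthetic tethered bees on the 0–5.5 m/s airspeed ramp, then a
threshold + prediction analysis of a randomized 1–25 cps optic-flow
sequence:

```r
library(iaakit)

fig1 <- run_experiment(list(kind = "fig1_tethered_ramp", n_bees = 10, seed = 1))
str(fig1$summary)
#> List of 4
#>  $ amplitude   : num 35.2
#>  $ midpoint    : num 2.27
#>  $ region_lower: num 1.5
#>  $ region_upper: num 3

fig2 <- run_experiment(list(kind = "fig2_random", seed = 1, n_scrambles = 200))
str(fig2$summary)
#> List of 6
#>  $ threshold      : int 10
#>  $ motion_score   : num 1
#>  $ direction_score: num 1
#>  $ n_scored       : int 23
#>  $ p_motion       : num 0.00498
#>  $ p_direction    : num 0.00498
```

Reading the output: the fitted airspeed response has a plateau-to-plateau
amplitude of ~35° centred at ~2.3 m/s, and the stepwise Moore tests across
bees bound the dynamic region at 1.5–3 m/s — below and above it the
response is saturated. The optic-flow analysis finds the bee's saturation
threshold at 10 cps; using only that threshold, the direction and
occurrence of the IAA response to every stimulus change in a randomized
sequence are predicted (23 scored transitions from 25 stimuli; the
transition out of the first stimulus reflects onset positioning and is
excluded) with perfect scores, and 200 scrambled reassignments of the same
responses never reach the observed score (empirical p ≈ 0.005, the minimum
attainable at that scramble count).

A command-line entry point with subcommands (`simulate`, `reconstruct`,
`analyze-airflow`, `analyze-opticflow`, `analyze-multimodal`, `report`) is
installed at `system.file("cli", "iaakit.R", package = "iaakit")`; all
subcommands take `--config <json>`, `--seed`, `--outdir`, `--log-level`.

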