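---
title: "Models and methods behind iaakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iaakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaakit)
```

## The behaviour and the measurement

Flying honeybees hold each antenna at an actively maintained position; the
inter-antennal angle (IAA) between the two base-to-tip lines summarizes
that position in one number. Two sensory channels shift the maintained set
point in opposite directions: frontal airflow, transduced by Johnston's
organ at the pedicel–flagellum joint, brings the antennae forward (IAA
decreases), while front-to-back optic flow from the compound eyes pushes
them backward (IAA increases). Hair-plate reflexes then hold whatever set
point these inputs select. `iaakit` implements the analyses used to
characterize each channel and their combination, plus a synthetic
generator so everything is testable end to end.

## The generative set-point model

A synthetic bee (`make_bee_profile()`) maintains

$$S(t) = \text{baseline} - A\,\sigma\!\left(\frac{v(t) - v_{50}}{k}\right)
        + G(t) + O(t),$$

with $\sigma$ the logistic function, $v(t)$ the airspeed, and measured IAA
$= S + \varepsilon$, $\varepsilon$ wrapped-Gaussian with SD
$\sigma_\varepsilon$ (wrapped because every downstream statistic is
circular; at the degree-scale SDs involved the wrapping is numerically
inert, which is exactly why circular and linear summaries agree on this
data). Units: degrees for all angles and amplitudes, m/s for airspeeds,
cycles/s (cps) for grating temporal frequency, seconds for time constants.

**Airflow channel.** The response is an absolute, sustained sigmoid of
airspeed: amplitude $A = 35°$ (tethered value; free flight is nearer 25°),
midpoint $v_{50} = 2.25$ m/s. The slope scale is $k = 0.09$ m/s, chosen
once so that the set-point change across any 0.5 m/s step outside the
1.5–3 m/s dynamic region stays below the measurement noise floor of the
reference design ($\sigma_\varepsilon\sqrt{2/n} \approx 0.05°$ at
$\sigma_\varepsilon = 0.8°$, $n = 500$ frames/bin). A cruder requirement —
"99% of the amplitude inside the dynamic region" — would allow $k$ up to
about 0.14 m/s, but would leave a systematic plateau drift of over a degree
that the across-bee paired test detects at the study's sample sizes,
contradicting the plateau observation the generator is supposed to embody.

**Optic-flow channel.** The antennae track *changes* in temporal frequency
rather than its absolute value, and only while at least one of the two
levels is below a per-bee saturation threshold $\theta$ (default 10 cps;
14 cps in some individuals). The state $G$ is an adapting change
integrator:

$$\frac{dG}{dt} = -\frac{G}{\tau}
  + \gamma\,\frac{d}{dt}\,\mathrm{clip}(\varphi(t), -\theta, \theta),$$

i.e. an impulse $\gamma\,\Delta\mathrm{clip}(\varphi)$ at each stimulus
transition and exponential decay otherwise. This single mechanism
reproduces three observations at once: a graded, saturating response to an
ascending ramp; no absolute-value trend when a randomized sequence is
reshuffled into ascending order (old impulses have decayed); and a graded
*absolute* response when moving gratings are interleaved with static
screens (each static epoch resets $G$ toward zero, so the next impulse is
proportional to the absolute level). Neither $\gamma$ (default 1 °/cps) nor
$\tau$ (default 4 s) is an empirically published value; $\tau$ must be
short against the 25 s randomized protocol for the reshuffling result and
long against the 1 s epochs for detectability, which brackets it to a few
seconds. A consequence worth knowing: steady-state bins sample the response
after partial decay, so the fitted low-range slope underestimates $\gamma$
by roughly $e^{-\Delta t/\tau}$, where $\Delta t$ is the delay from epoch
onset to the sampled frames.

**Onset.** The first moving-grating stimulus elicits a sharp one-time
positioning adjustment. It is modeled as an additive jump (default 5°)
decaying with $\tau$ — additive to, not replacing, the change response at
that first transition; with both readings defensible we chose the simpler
composition. This is why the first stimulus bin is excluded from threshold
detection and why the transition out of stimulus 1 is never scored.

**The "matched" optic-flow mode.** The combined-cue (regime) experiments
pair stimuli at matched heights of the two response curves: A = (0.5 m/s,
0.3 cps), B = (2.5 m/s, 0.9 cps), C = (4 m/s, 1.8 cps). A single linear
gain cannot realize that pairing — the B→A airspeed step spans ~33° of the
sigmoid while 0.6 cps of optic flow spans only ~0.6° at any plausible
$\gamma$ — so `of_mode = "matched"` makes the low-range optic-flow
response mirror the bee's own airspeed sigmoid through the piecewise-linear
map defined by the three regime pairs. This is precisely the crossmodal
calibration hypothesis the package's `crossmodal_calibrate()` formalizes:
the optic-flow speedometer is scaled against the absolute airspeed sense.
Regime trials sample the 0.2 s immediately after the step, before
adaptation erodes the optic-flow component; co-varied steps then cancel to
within the frame noise while single-cue steps shift the IAA by their full
amount, in the directions the behaviour shows (airspeed down → backward,
IAA up; optic flow down → forward, IAA down).

## Statistical design choices

**Moore's paired test by permutation.** For pairs
$(\alpha_i, \beta_i)$ the rectangular differences
$(\cos\alpha_i - \cos\beta_i, \sin\alpha_i - \sin\beta_i)$ are ranked by
magnitude (average ranks on ties) and
$R^* = \bigl|\sum_i r_i(\cos\theta_i, \sin\theta_i)\bigr| / n^{3/2}$. The
null swaps the order within each pair — a sign flip of each difference —
and we enumerate all $2^n$ patterns exactly when $n \le 20$ and the
requested permutation count allows, otherwise sample with the add-one
estimator $(\#\{R^*_\text{perm} \ge R^*\} + 1)/(n_\text{perm} + 1)$.
Permutation rather than the published critical-value table: exact at small
$n$, no transcription risk, and the table could be added later without API
change. Note the test detects a common *direction of the rectangular
differences*; a fixed angular shift is therefore detectable only when the
base angles are concentrated, which IAA samples always are. All-zero
differences return $R^* = 0$, $p = 1$ by convention.

**Pairing.** How samples are paired is not dictated by the data format:
within-bee comparisons pair equal-index frames of two equal-size bins (the
larger bin is subsampled, seeded); across-bee comparisons pair per-bee bin
circular means, so N pairs = N bees. Both choices are recorded in the
output metadata.

**Family-wise decisions in set detection.** Two procedures ask "is this
whole set of comparisons null?": saturation-threshold detection (all pairs
among bins at or above a candidate threshold) and dynamic-region detection
(all consecutive airspeed steps). Testing each comparison at raw
$\alpha = 0.05$ makes the correct set essentially unacceptable — with 120
pairwise tests the true saturation set survives with probability
$0.95^{120} \approx 0.002$, and a flat airspeed response shows a spurious
"significant" step almost half the time across 11 steps. Both procedures
therefore Holm-correct within the family and decide at family-wise
$\alpha$. Two practical consequences: the per-pair permutation count must
make $1/(n_\text{perm}+1)$ smaller than $\alpha/m$ for the largest family
(hence the 9999 default in `detect_threshold()`), and across-bee step
detection needs enough bees for the exhaustive minimum $2/2^n$ to clear
$\alpha/m$ — about 9; the reference design uses 10.

**Hypothetical zero mean.** ΔIAA groups are compared with each other *and*
with zero via one ANOVA: the zero hypothesis enters as a degenerate
all-zero group and decisions come from Tukey HSD contrasts. The zero
group's absent variance slightly deflates the pooled error term — a mild
anticonservatism accepted to keep every comparison inside one familiar
procedure.

**Sigmoid fitting.** `fit_airspeed_sigmoid()` fits the decreasing
four-parameter logistic by `nls` (port algorithm, box constraints
$A \ge 0$, $k > 0$, $v_{50}$ inside the sampled range) over a small
multistart grid, with a Nelder–Mead fallback; the reported amplitude is the
plateau difference. Normalization maps the slow-plateau mean (0–1.5 m/s)
to 1 and the fast-plateau mean (3–5.5 m/s) to 0, so the normalized curve
*decreases* with airspeed — reported plots use this decreasing convention
even where legend wording suggests the opposite orientation, and we follow
the plots.

**Prediction scoring.** From 25 stimuli, 24 consecutive transitions exist;
the transition out of stimulus 1 is excluded (onset positioning), giving
the 23 scored transitions the published scores use as denominator. A
change is predicted when $\min(\varphi_\text{from}, \varphi_\text{to}) <
\theta$; a transition starting exactly at $\theta$ upward predicts no
change (the clipped difference is zero) — the tie-break is recorded in the
audit table. The direction score counts *all* scored transitions, a
no-change prediction matched by no observed change counting as correct, so
both scores share one denominator. Scramble significance permutes whole
per-bin response blocks (preserving within-bin correlation), and reports
both the empirical permutation p and, for comparability with the original
analysis, a one-sample t test of the scrambled score distribution against
the observed value — the latter conflates a fixed observation with a
distribution and is included only as a reference point.

## What the generator does and does not emulate

It reproduces: per-bee set points spread over ~85–100°, wrapped-Gaussian
frame noise (0.8° tethered, ~3° free flight), the sigmoid airspeed
response with its plateaus, threshold-saturated change responses to optic
flow, onset adjustments, two-camera projective geometry with digitization
noise calibrated to the published 0.5–1.5% (tethered) and 3–5% (free
flight) antennal-length variation, and free-flight trajectories whose
groundspeed fluctuates around 0.43 m/s independent of windspeed.

It does not emulate: wingbeat-locked oscillations or any aerodynamics,
trial-to-trial set-point drift within a bee, lens distortion, landmark
mistracking or occlusion, latencies in the hair-plate reflex, or
between-session variability. Consequently a green test establishes that the
*analysis chain* recovers what the stated model puts in at realistic noise;
it does not establish robustness to structured artefacts real video
produces. The near-zero trial-to-trial variance also means some Moore tests
are far more powerful here than on real data — e.g. the small systematic
residual left by adaptation in the large co-varied B→A regime step is
"significant" on synthetic bees while real between-trial scatter would
swallow it.

## Numerical and degenerate-input conventions

Angles are wrapped to [0, 360) and differences to (−180, 180]; IAA itself
lives in [0, 180] by construction of the arccosine. Antipodal samples with
zero resultant return an undefined-mean flag rather than an arbitrary
angle. Triangulation refuses ray pairs whose design matrix condition
number exceeds 10⁸; calibration refuses coplanar point sets by QR rank.
Epochs shorter than the requested steady-state window are used in full
with a warning. The logistic fit reports non-convergence rather than
returning a silent local optimum, and flat data yield amplitude ≈ 0 rather
than an error. All randomness flows through explicit seeds; the caller's
RNG state is never touched, and identical configurations produce
byte-identical result bundles (the config hash excludes only the output
directory and log level).

## Known limitations

The low-range protocol includes a 0 cps level so the six 6 s + 3 s blocks
total the published 54 s; whether the original fifth moving level was 0 or
the protocol had other structure cannot be determined from the text. The
printed angular-speed equivalences (1.8 cps ↔ 18 °/s, 25 cps ↔ ~300 °/s)
are inconsistent with the stated formula (which yields 23.4 and 325.5 °/s
at 0.44 cycles/cm and 10 cm); `angular_speed()` implements the formula and
does not reconcile the approximations. The crossmodal calibration is a
formalization of a hypothesis, not a reproduction of a printed fit — no
quantitative calibration mapping was ever published.
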