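---
title: "Fuzzy ISODATA canopy localization: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy ISODATA canopy localization: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyclust)
```

## The measurement problem

A downward-pointing ultrasonic sensor moving along a sprayer boom returns a
1-D stream of distances. Over a row of crop plants that stream is a mixture
of a few discrete echo levels: the canopy (top leaf layer), one or more
lower leaf layers, and the soil where it is visible between plants. Boom
height control needs the sensor-to-canopy distance, and, when available,
the sensor-to-ground distance; everything else in the stream is a nuisance.
The package treats this as a 1-D clustering problem with an *unknown number
of levels*: fuzzy c-means fits the levels, and split/merge rules adapt the
cluster count to the structure present.

## The clustering model

Fuzzy c-means minimises
$J(U,V) = \sum_i \sum_j (u_{ij})^q \lVert X_j - V_i \rVert^2$
over memberships $U$ (columns summing to 1) and centers $V$ by alternating
two exact coordinate minimisations: centers become membership-weighted
means, memberships follow the inverse-squared-distance rule. Each
half-step can only lower $J$, so the objective trace is non-increasing — a
property the test suite asserts on every logged run. Iteration stops when
the largest membership change falls below `epsilon`.

Assumptions worth stating:

- **Levels are compact and separated.** Echo levels several cm apart with
  sub-cm noise are the regime the method is built for; heavily overlapping
  levels will be fused.
- **Euclidean geometry.** The updates are stated for general dimension $d$
  and the code supports $d > 1$, but all range-scan work is $d = 1$.
- **$q = 2$.** The standard fuzziness exponent; exposed in
  `isodata_config()` but rarely worth moving.

### Numerical conventions

- *Coincident samples.* The membership formula divides by the distance to
  each center, so a sample lying exactly on a center is singular. By the
  standard continuity limit it receives membership 1 there, split uniformly
  when several centers coincide. Exact zero squared distances are detected
  by computing each $\lVert X_j - V_i \rVert^2$ directly (no expanded
  quadratic form, which loses the exact zero to cancellation).
- *Initialisation.* The default is deterministic: $c$ provisional centers
  at evenly spaced quantiles (probabilities $(2i-1)/2c$) of the data,
  followed by a crisp nearest-center assignment. On layered range data each
  occupied level with non-negligible mass captures a quantile, which makes
  the default both reproducible and well-placed. Duplicate quantile centers
  (data with fewer distinct values than $c$) are collapsed, and provisional
  clusters left empty are dropped, so the effective starting count can be
  below `c_init`. A seeded random initialisation is available
  (`initial_partition(..., method = "random")`) for sensitivity checks and
  for demonstrating that convergence reduces the partition entropy from a
  genuinely fuzzy start.
- *Degenerate clusters.* A cluster whose weights $(u_{ij})^q$ all underflow
  to zero has no defined center; this raises an error naming the cluster
  rather than silently producing `NaN`.
- *Iteration caps.* The inner loop is capped at `max_inner = 300`
  iterations as a guardrail; hitting the cap returns a state flagged
  `converged = FALSE` with a warning, never an exception, so a caller can
  inspect the partial fit.

## Split, merge, and the outer loop

After each converged fit, samples are hard-assigned to their nearest center
(ties to the lowest index; centers are kept sorted ascending, so ties go to
the shallower cluster). Per-cluster statistics use the population form
(divisor $n_i$): mean member distance $\bar D_i$ and standard deviation
$\sigma_i = \sqrt{\tfrac{1}{n_i}\sum \lVert X - V_i \rVert^2}$.

A cluster splits into $V_i \pm 0.5\sigma_i$ when *all three* strict
inequalities hold: $\sigma_i > \theta_S$, $\bar D_i > \bar D$ (the global
mean distance), and $n_i > 2(\theta_n + 1)$. Two centers closer than
$\theta_c$ merge into their count-weighted mean; candidate pairs are
processed in ascending distance order with at most one merge per cluster
per round — a deterministic policy for the (rare) case of three mutually
close centers. For $d > 1$ the split displaces centers along the axis of
maximum within-cluster variance, since adding a scalar to a vector is only
well-defined at $d = 1$.

The outer loop repeats {fit, assign, split, merge} until a round proposes
no change. A single adjustment pass invalidates the converged memberships
(a split cluster's samples still carry the old memberships), so looping
back to the fuzzy fit is the default; `max_outer = 1` gives single-pass
behaviour for callers who want the raw adjustment. The loop is capped at
`max_outer = 10` rounds; in practice layered scans settle in one or two.
Clusters emptied by hard reassignment are deleted and logged. Every split,
merge and deletion is recorded in the model's event log with its round
number, so a fit is fully auditable.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `c_init`  | 3     | —  | starting cluster count: canopy, lower leaves, ground |
| `epsilon` | 1e-4  | —  | membership convergence tolerance |
| `q`       | 2     | —  | fuzziness exponent |
| `theta_n` | 20    | samples | minimum cluster size scale; split needs $n_i > 2(\theta_n+1)$ |
| `theta_S` | 5     | cm | split threshold on $\sigma_i$ |
| `theta_c` | 2     | cm | merge threshold on center distance |

These defaults are tuned for corn-scale canopies sampled at a few hundred
points per pass. `theta_n` should shrink for faster passes (fewer samples
per plant); no automatic speed-to-`theta_n` mapping is attempted.

## Ground plausibility

The farthest cluster is only *called* ground when its center lies within
`ground_tol` (default 5 cm) of the known mounting height `nominal_ground`.
Once the canopy closes over, no soil echo returns and the farthest cluster
is a leaf layer — typically 10 cm or more above the soil — which the
tolerance rule rejects while leaving the canopy estimate untouched. The
5 cm default matches the accuracy generally considered acceptable for boom
height control; the rule is monotone by construction (raising the
tolerance can only turn detection on, never off).

## What the simulator emulates — and what it does not

`simulate_scan()` reproduces the bench geometry of a boom-sensor
experiment: plants at 0.3 m spacing under a rail, a sensor 81 cm above the
soil travelling at 0.5–6 km/h, and a fixed ranging rate (default 45 Hz,
set so a five-plant pass at 6 km/h collects about 40 points). The sample
count is exactly `floor(track / (speed * sample_interval))`, so data
volume falls inversely with speed — the mechanism behind the error-versus-
speed trend. Each sample reads the layer directly under the sensor
(canopy in the middle of the plant footprint, deeper leaf layers toward
its edges, soil in the gaps) plus Gaussian noise (default sd 0.5 cm, a
realistic ultrasonic ranging jitter on leaf surfaces). With probability
`dropout_prob` (default 0.05) the first echo is lost — the inclined-leaf
effect — and the sensor reports the next deeper visible surface instead
(or, under the alternative `"max-range"` policy, its ceiling reading).

Two deliberate idealisations:

- **Discrete layers.** Each leaf level is a single distance, not a
  continuous arch of leaf surfaces. Passing tests on such scans shows the
  pipeline resolves well-separated levels; it does *not* show performance
  on the continuous within-level spread of real canopies.
- **Point footprint.** The 10° beam cone, which mixes adjacent layers near
  level edges, is not modelled; neither are temperature, wind, or boom
  vibration.

The growth-stage presets (`stage_preset()`) mirror how corn's echo
structure develops: 3-leaf = canopy + ground (2 levels), 4-leaf adds one
lower leaf layer (3), 5-leaf two (4), and 6-leaf three with the ground
occluded (4 levels, no soil echo). The 3- and 4-leaf presets use typical
bench distances (63.25 cm; 59.81/65.53 cm). For the 4-level presets the
adjacent layers are spaced 11–12 cm apart. That spacing is a consequence
of the discrete-layer idealisation: a cluster spanning two single-valued
levels with gap $g$ and mass fractions $w_a, w_b$ has
$\sigma = g\sqrt{w_a w_b}/(w_a+w_b) \le g/2$, so with the default
$\theta_S = 5$ cm a split — and hence recovery of all four levels from a
3-cluster start — is only reachable when adjacent levels sit more than
about two thresholds apart. Real scans reach the same split through the
continuous spread within each level, which the idealisation removes.

### Common random numbers across speeds

Noise and dropout draws are attached to a fixed spatial lattice (pitch =
the sample spacing at 0.5 km/h) rather than to sample indices. Because the
sampling grids at 1, 2, and 4 km/h are exact sub-grids of the 0.5 km/h
grid (and 6 km/h a sub-grid of 2 km/h), scans of the same seed at
different speeds share their noise wherever they share a position. The
speed sweep therefore compares speeds as a paired design: differences in
mean error reflect the sample-count effect rather than independent noise
realisations. `speed_sweep()` additionally reuses replicate seeds across
speeds.

## Baselines

The k-means baseline uses Lloyd's algorithm (`stats::kmeans`) from a
seeded random draw of initial centers, retried if an initialisation
empties a cluster. The seed is part of the interface precisely because
k-means' result depends on it — the test suite includes a tiny fixture on
which some seeds reach the global optimum (verified against exhaustive
assignment enumeration) and others do not. Mean and median need no
configuration and serve as the "no segmentation" reference.

## Problem sizes and runtime

The test and acceptance workloads are sized for interactive runs: scans of
40–486 samples (the realistic range across 0.5–6 km/h at 45 Hz), 20
replicates for recovery and sweep checks, 1000 random partitions for the
entropy bounds, and exhaustive k-means enumeration at $n = 9, c = 3$. The
full suite completes in well under a minute on one core.

## Known limitations

- Levels closer than roughly the noise scale fuse; the method reports
  fewer clusters rather than guessing.
- The split rule cannot separate two *discrete* sub-levels closer than
  about $2\theta_S$ (see above); with continuous within-level spread this
  matters less.
- Parameter choice is manual. `theta_n`, `theta_S`, `theta_c` interact
  with plant scale and sensor speed, and poor values degrade the cluster
  count; no auto-tuning is attempted.
- One scan, one canopy distance: per-plant segmentation along the travel
  axis and boom control decisions are out of scope.
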