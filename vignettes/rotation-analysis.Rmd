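---
title: "Quantifying sibling cell-pair rotations: methods and models"
author: "dyadrot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sibling cell-pair rotations: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadrot)
```

## The problem

In the zebrafish neuromast, a unipotent progenitor divides into two sibling
hair cells. In about half of these dyads the siblings exchange positions by
rotating around their common centroid, an angular movement of up to 180
degrees that completes within a few hundred minutes. dyadrot quantifies this
movement from tracked centroid tables (MTrackJ-style exports), relates it to
cell morphology and neighbor topology (Tissue-Analyzer-style exports), and
implements a two-particle Metropolis model of the rotation.

All computation uses micrometres, minutes and degrees. The x axis is the
anteroposterior (A-P) axis of the organ (x increasing posterior), and
positive angles are counter-clockwise from +x.

## Kinematic pipeline

Each pair is centered frame-wise on the midpoint of the two centroids, which
removes common drift and makes the two tracks exact mirror images. The
positional angle $\alpha(t)$ of the inter-cell axis is differenced frame to
frame, each change wrapped to the minimal representative in $(-180, 180]$ —
valid because at a 200 s frame interval rotations never approach 180 degrees
per frame. From the changes $\Delta\alpha$ we accumulate:

* the cumulative signed angle $\Sigma(t) = \sum_{u \le t} \Delta\alpha(u)$,
* the turn $|\Sigma(t)|$, and
* the arc length $\sum_{u\le t} |\Delta\alpha(u)|$.

A pair *inverts* iff its final turn strictly exceeds the 90-degree critical
angle (exactly 90 is a local rearrangement). Scalar statistics:

* **overshoot** — maximal turn minus final turn;
* **wobbling** — arc length minus final turn, the only reading of
  "angle changes minus final turn" that is nonnegative and vanishes exactly
  for monotone rotations;
* **noise** — summed path length of the centered cells over the first 200
  frames divided by the summed start-to-end chords, $\ge 1$, with pairs
  excluded when a cell's chord is below 2 µm. Because centered siblings are
  exact mirrors, the two cells contribute identical ratios; the pooled
  (sum/sum) aggregation is the default and a per-cell mean is available;
* **start/final angles** — circular (unit-vector) means of the first/last
  ten positional angles, correct across the $\pm 180$ branch cut;
* **handedness** — the sign of the final cumulative angle (CCW positive).

```{r}
pars <- pair_synthesis_params(wobble_sd_deg = 5)
pair <- cell_pair(generate_pair_tracks(pars, seed = 1),
  "cell_a", "cell_b",
  genotype = "synthetic"
)
m <- rotation_metrics(pair, run_config(unit_scale = 1))
t(round(m[, c(
  "final_turn_deg", "overshoot_deg", "wobbling_deg", "noise",
  "Ic_min", "Id_min", "duration_min"
)], 2))
```

## Phase segmentation

The cumulative angle of inverting pairs is fitted by the four-parameter
logistic
$$f(t) = c + \frac{d - c}{1 + e^{-b (t - a)}},$$
with midpoint $a$ (min), steepness $b$ (1/min) and asymptotes $c, d$ (deg).
The rotation onset and termination are the times where the tangent through
the inflection point meets the asymptotes. The tangent at $t = a$ has slope
$b(d-c)/4$ and passes through $(a, (c+d)/2)$, giving
$$I_c = a - 2/b, \qquad I_d = a + 2/b,$$
so Phase 2 lasts $4/b$ minutes. Phases 1/2/3 are the intervals before
$I_c$, between $I_c$ and $I_d$, and after $I_d$.

Fitting is nonlinear least squares (Levenberg-Marquardt) with deterministic
multi-starts — $a$ over the observed time quartiles, $b$ over
$\{0.01, 0.05, 0.1, 0.5\}$ per min, $c$/$d$ from the first/last decile means
— ranked by residual RMS with ties broken toward the smaller $b$.
Non-convergence (e.g. a constant series, where $b$ is unidentifiable) is
flagged per pair, never silently passed. The fit is only attempted for pairs
already classified as inverting.

## Morphology and topology

Pair circularity is the isoperimetric ratio $C = 4\pi A / P^2$ with $A$ the
summed cell areas and $P$ the summed perimeters minus twice the shared
junction length (the homotypic junction is interior to the pair outline);
$C$ is defined only at frames where the siblings share a bond, and values
above 1 (possible with segmentation noise) are clamped with a flag.

Interface chirality: the exported interface polyline is rigidly rotated and
translated so its endpoints sit at $(\mp L/2, 0)$ (no reflection, traversal
preserved), resampled to 64 arc-length-uniform points, and scored by

* x-asymmetry: $\mathrm{mean}\,|y(u) - y(1-u)| / (2L)$ — zero for mirror-even
  curves, large for chiral sigmoids;
* y-asymmetry: $\mathrm{mean}\,|y| / L$ — the net bow.

A sigmoid call (x-asymmetry above $\tau_S$) takes precedence over a curve
call (y-asymmetry above $\tau_C$); otherwise the interface is straight. The
chiral classes are written `S` and `Z` (the mirrored S). The study quantified
"notable asymmetry" only qualitatively, so both thresholds default to 0.05 of
the endpoint separation and are configurable; mirroring a polyline provably
swaps `S` and `Z` and fixes `I` and `C`, which the tests exercise on random
curves.

Topology: per-frame neighbor graphs are built from the bond table, sibling A
being the cell that retrospectively finishes anterior. The cumulative
neighbor difference $D(T) = \sum_{t \le T} (N_t - M_t)$ stays near zero under
symmetric neighbor exchange and grows linearly when one sibling (the
"popular" cell) consistently has more neighbors. Because the sibling-sibling
edge enters both counts it cancels from $D$ exactly, so including it is
immaterial (tested). The popular-cell call — a two-sided sign test on the
per-frame differences at $\alpha = 0.05$, signed by the least-squares slope
of $D(T)$ — is this package's operationalization of a qualitative
description.

Epithelial flow: Pearson correlations of frame-to-frame A-P displacements
(not positions, which are trivially autocorrelated for confined cells) for
every unordered pair of tracks, classed as HC-HC, HC-other or other-other.
Mirror-rotating siblings give $R = -1$ exactly; independent background cells
give class means near zero. Published correlation values derive from imaging
data that is not deposited, so the tests assert the qualitative structure,
not the printed numbers.

## Synthetic data: what it emulates, and what not

The generators reproduce the statistical structure the analyses assume, at
the study's acquisition settings (200 s frames, observation capped at 500
min, so 150 frames): logistic-in-time axis angles for inverting pairs
(defaults $a = 100$ min, $b = 0.08$/min — a 50 min Phase 2 — and a 170-degree
net turn), sub-critical sinusoidal rocking (30 degrees) for non-inverting
pairs, per-frame Gaussian wobble injected in angle space (default 5 degrees;
the study reports no per-genotype magnitude, so this is a free fixture
parameter), phase-locked junction/circularity bumps peaking between $I_c$
and $I_d$, neighbor series with exact built-in bias, and jittered stationary
epithelium tracks. Wobble in angle space keeps the angular path statistics
analytic; it does not emulate segmentation jitter in x/y, cell divisions or
deaths, out-of-plane motion, or tracking gaps — so green tests certify the
estimators, not robustness to those artifacts.

## The two-cell Metropolis model

Each sibling is a particle on a circle with its angle to the A-P axis as the
single degree of freedom, on a 0.25-degree lattice. Cells repel through the
repulsive term of a Lennard-Jones potential on circular distance,
$U = (d/\Delta)^{12}$ with $d = 180°$ so the interaction spans the whole
domain, which keeps the pair near diametral opposition. Each cell feels one
Gaussian well $V_j = -e^{-\mathrm{dist}(\theta_j,\mu_j)^2 / 2\sigma^2}$ of
depth $\omega_j$; the Hamiltonian is
$H = \rho U + \omega_1 V_1 + \omega_2 V_2$, with the wells switched on only
after an initial breaking time. One cell at a time proposes a one-lattice
move; moves are accepted with probability $\min(1, e^{-\beta \Delta H})$.
The initial axis angle is drawn from $N(180°, 50°)$ and the cells placed
diametrically opposed (an independent-draw initializer is available behind a
flag). The asymmetric model puts the wells on opposite poles
($\mu = 0°, 180°$); the symmetric model puts both on one pole, creating a
competition.

**Choice of well width.** With the pair locked near 180-degree separation,
the axis angle $\varphi$ of the symmetric model minimizes
$\omega_1 V(x) + \omega_2 V(180 - x)$ in the distance $x$ of the deep-well
cell from the shared pole. For narrow wells ($\sigma \ll 180°$) the two
attractors never overlap across the enforced separation: the outcome is
kinetically frozen and depends on the absolute depths. In the wide-well
(quasi-harmonic) limit the compromise is
$$x^\ast = 180° \, \frac{r}{1 + r}, \qquad r = \omega_{\min}/\omega_{\max},$$
which depends only on the *relative* depth — the regime the reported
final-angle behaviour singles out (robust asymmetric model; symmetric model
sensitive to $r$, with a deviation near 60 degrees at $r = 1/2$). The
default $\sigma = 240°$ was fixed by the included calibration sweep
(`calibrate_well_width()`, which also shows 180-300 degrees behaves
equivalently); $\beta = 2$ sets the stationary angular spread to roughly 20
degrees, and $n = 2\times10^5$ steps lets a half-domain rotation complete
with about a two-fold margin (the repulsion-locked pair advances through
alternating single-cell moves, roughly three-fold slower than a free
particle). $\rho = 1$ and the $r^{-12}$ exponent are declared fixture
choices; the functional form is config-switchable.

```{r}
sw <- sweep_replicates("symmetric", depth_ratios = 0.5, n_reps = 10, seed = 1)
median(sw$final_angle_dev_deg)
```

Simulated trajectories are subsampled to 150 observations and pushed through
the *same* empirical pipeline (`sim_to_pair()`, then angle series, logistic
fit, noise) — the model readouts and the data readouts share one code path,
with the displacement exclusion disabled because simulated cells live on a
fixed circle.

## Numerical and design notes

* Angle wrapping assumes no inter-frame rotation exceeds 180 degrees;
  observed Phase-2 durations (tens of minutes) versus the 200 s frame
  interval support this by two orders of magnitude.
* Exactly-90-degree final turns are non-inverting (strict inequality).
* Zero final cumulative angle leaves handedness undefined (flagged tie).
* Circular means use unit-vector averaging; an antipodal degenerate set
  returns NA rather than an arbitrary direction.
* The pixel size of the source microscope is deliberately *not* defaulted:
  `run_config()` requires `unit_scale` explicitly.
* Coincident centroids make the positional angle undefined and raise an
  error naming the frame; orphan bonds and non-monotonic or duplicated
  frames are validation errors, not warnings.
* The two-sample Anderson-Darling test (used for noise distributions) is
  computed from the pooled-rank statistic with a seeded permutation p-value,
  since no installed implementation exists; Wilcoxon-Mann-Whitney (one-sided,
  reference stochastically less), t, Kolmogorov-Smirnov and binomial tests
  use base R.
* The Metropolis chain in C++ draws its uniforms from R's RNG in a fixed
  order, so the pure-R reference stepper reproduces it bit-for-bit decision
  and lattice-wise under a shared seed; energies agree to 1e-12 (the two
  languages associate the power differently).

## Problem sizes

The shipped tests and the acceptance script use 150-frame pairs, cohorts of
up to 200 pairs, 100 replicates per simulated condition and $10^5$-step
equilibrium chains — sizes chosen so the full suite completes in well under
a minute of simulation time while keeping every statistical margin wide.

## Known limitations

* Interfaces are classified per exported 2-D polyline; no 3-D reconstruction
  across focal planes is attempted.
* Neighbor counting assumes no cell division or death during the recording,
  as observed in the source system.
* The symmetric/asymmetric model contrast is qualitative by construction;
  printed empirical correlations, shape-class percentages and inversion
  frequencies derive from undeposited imaging data and are not asserted.
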