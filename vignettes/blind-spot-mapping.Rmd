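---
title: "Mapping the blind spot: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the blind spot: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindspotr)
```

The physiological blind spot is the region of the monocular visual field
projecting onto the optic disc: roughly an upright oval about 6° wide and
7° tall, centered near 16° temporal and 2° below the horizontal meridian,
but individually variable enough that it must be mapped per observer
before any experiment that hides stimuli inside it. `blindspotr`
implements a stepwise psychophysical mapping block — border points
detection, staircase refinement, and validation — together with a
simulated observer that stands in for the human participant and
eye-tracker, and the precision statistics used to analyze repeated blocks.

This vignette describes the model underlying each procedure, the
parameters that matter and their defaults, the choices made where the
procedure leaves room, and what the simulation does and does not
establish about real data.

## Geometry

All stimulus coordinates are eccentricities in degrees of visual angle
relative to the fixation object. Conversions go through a screen model
(physical size, resolution, viewing distance; square pixels enforced at
construction within 1%). A pixel offset `n` from screen center converts
per axis as `atan(n * cm_per_pix / distance)`; on the default apparatus
(40 × 30 cm, 1280 × 960 pix, 57 cm) this makes 1 cm at screen center
subtend almost exactly 1°, the fixation object at (−300, 0) pix sit 9.34°
left of center, and a 12 pix probe subtend 0.38°. The per-axis arctangent
(rather than the `2·atan(half)` convention) is used because it is the
convention under which those landmark values are exact.

```{r geometry}
scr <- default_screen()
c(pix_to_deg(300, scr), pix_to_deg(12, scr))
```

## The simulated observer

The observer's ground truth is an axis-aligned ellipse (center, width,
height). Visibility of a point stimulus is

  p(yes) = guess + (1 − guess − lapse) · σ(d / s),

where `d` is the signed distance to the ellipse boundary (negative
inside), `s` is the boundary softness in degrees (`boundary_slope`; 0
degenerates to a hard step with p = 0.5 exactly on the boundary), and σ
is the standard logistic. The signed distance is the normalized radial
coordinate rescaled by the local along-ray half-diameter: exact Euclidean
distance on the principal axes, and a smooth monotone proxy elsewhere —
only its sign, zero set, and monotonicity are relied upon.

Response noise has four sources, all off by default in `ideal_observer()`
and set to plausible desk-scale values in `default_observer()`:

* `lapse_rate`, `guess_rate` (default 0.02 each): misreported clearly
  visible / clearly invisible stimuli.
* `fixation_jitter_sd` (default 0.3°): one isotropic Gaussian gaze offset
  drawn per trial. Trials are brief (a few hundred ms), so a single
  offset per trial is an adequate model; no within-trial drift is
  simulated.
* `click_error_sd` (default 0.2°): positional error of moving-probe
  reports, applied along the movement axis, plus an optional systematic
  `click_bias` (default 0) for observers who click late.

Extended stimuli (heat-map cells, scaling ellipses) are reported seen if
*any* part is visible: their see-probability is the maximum of the point
model over a deterministic sample of 64 outline and 25 interior points.
For rectangles this is exact for a hard boundary (a convex ellipse
contains a rectangle iff it contains its corners, and all corners are
sampled); for soft boundaries it is an accurate upper-envelope
approximation. This "any part" rule is what makes near-size validation
ellipses easy to see: they protrude past the true boundary somewhere even
when their area is mostly blind.

The default observer's geometry (center (16.00, −2.05), 6.28 × 7.02°)
mirrors the average adult right-eye blind spot, so simulated studies
produce outputs on the scale practitioners expect.

## Border points detection

The standard three-step procedure moves a small probe forth and back
along straight paths; the observer clicks where it disappears and
reappears. Each round trip (forward + backward pass) reports each of the
path's two border points twice; with the default three round trips each
point is the mean of six clicks. Path 1 is horizontal through the prior
search region's vertical center; path 2 is vertical through the midpoint
of path 1's points; path 3 is horizontal through the midpoint of path 2's
points. The location estimate is the intersection of paths 2 and 3; the
height is the separation of path 2's points and the width that of
path 3's. Because a vertical chord of an axis-aligned ellipse is always
centered on the horizontal axis (and vice versa), this construction is
exact for the elliptical model even when path 1 is off-center — which is
also why the estimate is invariant to small shifts of the prior region.

Choices worth noting:

* **Prior search region.** The real tool lets the observer steer the
  probe; in simulation the first path needs a starting rectangle. The
  default `[12°, 20°] × [−6°, 2°]` brackets the canonical blind spot. A
  path that misses the scotoma entirely raises an error rather than
  silently re-centering; the caller can widen the prior.
* **Click clustering.** Clicks along a path are sorted and split at the
  largest gap, then each subgroup is averaged. For separated borders this
  equals the lower/upper-half split and is deterministic; subgroups
  smaller than two clicks, odd counts, or a gap that does not dominate
  the subgroup spread raise a degenerate-cluster error.
* **Gaze jitter in probe runs.** Each pass samples one gaze offset, which
  shifts the effective boundary before the click positions are generated.
  This keeps the fixation-jitter parameter meaningful in the detection
  section and propagates realistic block-to-block location scatter.
* **Medium/High path placement.** Medium mode adds vertical paths at
  `cx ± w/4` and horizontal paths at `cy ± h/4` (14 points over 7 paths);
  High adds four more at `± w/8`, `± h/8` (22 points). The quarter-axis
  placement samples the quadrants symmetrically and is configurable; High
  mode is provided but should be considered lightly exercised.

## Staircase refinement

Raw border points target the 50%-visibility boundary. The staircase
section drives each one to a level with known psychometric meaning using
a transformed 1-up-3-down rule: a point target is presented along the ray
from the border point toward the estimated location, displaced by the
current increment (pixels; positive = toward the center). One "yes" moves
it up (deeper); after the first reversal, only three *consecutive* "no"
answers move it down, the counter resetting on any "yes" — the reading of
"every three negative answers" under which the procedure's asymptotic
target P(no) = 0.5^(1/3) ≈ 0.794 actually holds. Before the first
reversal the rule is 1-up-1-down, so the run descends quickly from its
deliberately invisible start (initial increment 50 pix).

Defaults: step schedule [30, 15, 7, 3] pix applied largest first and
advanced at each reversal (capped at the smallest step), 20 successful
trials, 4 scheduled reversals, threshold = the final trial's increment.
Two conventions are fixed here that the rule statement leaves open:

* The reversal-causing move itself uses the *new* (smaller) step, the
  common convention in transformed up-down implementations; it affects
  only transient behavior.
* Termination is exactly `n_trials` successful trials even if fewer than
  `n_reversals` reversals occurred — the final-1-trial threshold was
  chosen in the source procedure as an expectation that the 4th reversal
  has happened by then, not an enforcement. Set `require_reversals = TRUE`
  to extend the run until the scheduled reversal count is reached.

Negative increments (outside the raw point) are permitted without bound.
Trials whose sampled gaze exceeds the fixation tolerance (default 1.5°,
boundary-inclusive) are logged, discarded, and re-run with fresh
randomness; a guard errors after 1000 attempts for one trial.

`convergence_probability()` checks the rule's asymptotics by Monte-Carlo:
many long fixed-small-step staircases against an arbitrary monotone
psychometric, evaluating the psychometric at the grand mean of each run's
second-half levels. With 2000 runs of 200 trials it lands within a point
of the 79.4% theoretical invisibility target, and the 1-up-1-down variant
lands at 50%, as transformed up-down theory requires.

## Validation

**Heat map** (the gold standard): a rectangle of 1.1 × estimated width by
1.2 × estimated height, centered on the estimated location, gridded into
congruent cells (default 10 × 10); each cell is probed by a cell-filling
rectangular target, 10 times per cell in one global shuffled order. Cells
with visibility below a threshold (default 0.5) constitute the estimated
blind spot; width and height are outer-edge separations of the member
columns and rows. Connectivity is *not* enforced — real maps can contain
an isolated, faintly light-sensitive cell inside the blind spot, and the
procedure should report it rather than smooth it away. The rectangle is
built from the staircase-adjusted size estimates, since the section runs
after the staircase in a full block. Note one intrinsic bias: under the
any-part-visible rule a cell reads blind only when *fully* contained, so
each side can lose up to one partially covered cell; the size estimate is
quantized from below (within two cells per axis, shrinking in absolute
terms as the grid is refined).

**Scaling** (the default, much faster): ellipses with the estimated
aspect ratio at 10 uniformly spaced scaling coefficients in [0.6, 1.2],
10 trials each, presented at the estimated location. Visibility per size
is fitted with the two-parameter logistic

  f(x) = 100% / (1 + exp(−t (x − x0))),

by unweighted least squares on the percentage scale, multi-started over
`x0` at each observed size and several slope magnitudes, with `t > 0`
enforced (visibility rises with size; f(x0) = 50%). Degenerate data (all
0% or all 100%) are refused rather than extrapolated.
`zero_visible_size()` reports the largest tested coefficient at and below
which nothing was ever seen — the quantity behind "safe zone" reasoning —
and is `NA` when even the smallest probe was sometimes seen (with a 2%
guess rate and 100 scaling trials per block, that happens in a fair
fraction of single blocks; it is meant to be applied to data pooled
across blocks).

## Precision statistics

Repeated blocks per observer are summarized by the standard distance

  Stdist = sqrt( (1/n) Σ [(xᵢ − x̄)² + (yᵢ − ȳ)²] ),

the RMS distance of block estimates from their centroid (translation- and
rotation-invariant). Per-observer summaries use sample (n − 1) SDs;
study-level aggregation averages means arithmetically but aggregates SD
and Stdist columns as root-mean-squares (the average of SDs is the square
root of the mean variance). The precision quotient divides the location
Stdist by the minor axis (the smaller of width and height). Border-point
precision per stage is the sum of the four cardinal points' Stdists;
stages are compared with a classical paired t, and width-SD vs height-SD
with a pooled-variance (not Welch) two-sample t. The safe zone is the
chosen coefficient (default 0.5) times the *smallest* per-observer mean
width and height — column minima, applied exactly as stated. Reported
values are rounded half-away-from-zero to two decimals; computation is at
full precision and p-values are reported, never used as pass/fail
criteria.

```{r stats}
summarize_study(reference_observers())
```

## What the simulation does and does not show

The simulated observer makes every procedure testable end to end and
supports parameter-recovery studies: under the default noise (jitter
0.3°, click error 0.2°, 2% lapse/guess), low-mode blocks recover the true
location well within 0.5° and the detection-stage sizes within a few
percent. Two caveats matter when reading such results:

* **Raw vs adjusted sizes.** The detection-stage (50%-boundary) sizes are
  the unbiased estimates of the true axes; the staircase-adjusted sizes
  sit at the 21%-visible level and are *deliberately* conservative
  (roughly 10% smaller under the default observer, more with heavier
  jitter, which flattens the effective psychometric). Parameter-recovery
  claims in this package therefore refer to the raw sizes; the adjusted
  sizes are the conservative final estimates a cautious experimenter
  would use.
* **Model mismatch is absent.** The simulated scotoma *is* an ellipse, so
  the simulation cannot detect errors caused by real, irregular blind
  spot shapes; it validates the procedures' internal logic, noise
  robustness, and statistics, not their anatomical fidelity. Filling-in
  phenomenology, retinal physiology, and pupillary responses are out of
  scope.

## Problem sizes and numerical conventions

The test suite and the reproduction script use desk-scale sizes chosen to
exercise the asymptotics without waste: 2000 staircases × 200 trials for
the convergence estimate (standard error well under the 2-point
tolerance), 100 seeded blocks for parameter recovery, and heat-map grids
up to 40 × 40 for convergence checks. Other conventions: the fixation
gate is boundary-inclusive (a gaze exactly at tolerance is valid);
staircase increments convert pixels to degrees through the same arctan
screen model as all other quantities; sigmoid fits use `optim`
(L-BFGS-B) with a multi-start grid, and exact-recovery of noiseless
logistic data holds to 1e-6; all randomness flows through R's global RNG
so a block is bit-reproducible given (protocol, observer, seed).
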