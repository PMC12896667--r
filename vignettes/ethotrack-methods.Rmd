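---
title: "Methods: rule-based behavior classification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based behavior classification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethotrack)
```

## The problem

Zoo behavioral studies traditionally code video by hand: an observer
watches footage and writes down, second by second, what the animal is
doing according to a predefined ethogram. Pose-estimation software can
replace part of this work by tracking a few anatomical keypoints (here:
nose, head, shoulder, hip) in every frame. `ethotrack` implements the
post-processing that turns such keypoint tracks into per-second behavior
labels, quantifies how well the automated labels agree with a human
coder, and runs the non-parametric statistics used to compare behavior
between observation periods (for example before and after an olfactory
enrichment) and between individuals.

Everything operates in image pixel coordinates with the y-down
convention (origin top-left), because the classification thresholds are
defined on the camera image: "the head is 60 pixels *below* the
shoulder" means `head_y - shoulder_y >= 60`.

## The classification rules

Each second of a 1 fps track is assigned exactly one of five categories
by `classify_track()`:

| Category | Condition |
|---|---|
| Lying Down | hip **or** shoulder inside the lying rectangle (default `x` 1080–1720, `y` 270–400; closed boundaries) |
| Foraging/Feeding | `head_y - shoulder_y >= 60` **or** `nose_y - shoulder_y >= 90` |
| Locomotion | static label Standing, and mean hip/shoulder displacement from the previous second `> 0.5 ×` body length (hip-to-shoulder distance) |
| Standing | default when nothing else qualifies |
| Not Labeled | hip **and** shoulder both missing |

Several details of this rule set were genuinely open and are fixed here
as package decisions:

* **Precedence.** Lying Down is tested before Foraging/Feeding. A lying
  animal's head is typically low, so the head-drop rule would fire
  spuriously; zone membership is the stronger cue. Whether a
  low-head-while-lying frame should instead count as foraging is not
  decidable from geometry alone, so the zone wins.
* **Threshold senses.** "At least" thresholds are inclusive (`>=`); the
  displacement threshold is strict (`>`). Zone boundaries are closed. A
  displacement of exactly half a body length therefore stays Standing.
* **Displacement combination.** "Displacement of hip and shoulder" is
  read as the arithmetic mean of the two keypoint displacements.
  `rule_config(displacement =)` also offers `"max"` and `"both"` for
  sensitivity analyses.
* **Body length reference.** The body length dividing the displacement
  is taken from the current frame. If it is zero (degenerate detection,
  hip on top of shoulder), the locomotion rule cannot fire.
* **Missing keypoints.** A second is Not Labeled only when both anchor
  points (hip and shoulder) are missing. A missing head and nose merely
  disable the foraging rule; the frame can still be Standing or Lying
  Down. The first observed second can never be Locomotion because there
  is no previous frame.

`apply_locomotion()` additionally requires the previous frame to be the
immediately preceding second (`time_s` difference of exactly 1), so
gaps in a track never produce spurious locomotion labels across them.

## The synthetic-data generator

No public pose dataset accompanies this problem domain, so every stage
is validated on synthetic data with known ground truth.

**Behavior sequences.** `simulate_behavior_sequence()` draws a
semi-Markov chain at 1 Hz: the animal stays in its current behavior
with probability `1 - 1/mean_dwell_s[b]` (geometric dwell — the
simplest model consistent with per-second sampling) and otherwise jumps
according to a row-stochastic transition matrix. With the default
zero-diagonal jump matrix the stated dwell means are exact. The default
dwells (Standing 20 s, Lying Down 60 s, Foraging/Feeding 30 s,
Locomotion 5 s) are plausible magnitudes for a large, mostly inactive
captive ungulate, chosen once as placeholders: no published dwell-time
statistics exist for this setting, and none of the package's guarantees
depend on them.

**Keypoint geometry.** `realize_keypoints()` places the four keypoints
so that each second satisfies its own behavior's rule and violates all
others by at least `margin_px` (default 25 px):

* lying frames put shoulder and hip inside the lying rectangle, one
  margin from its edges;
* terrestrial frames sit on a horizontal plane two margins below the
  rectangle, so lying-to-standing transitions displace the anchors by
  exactly three margins — below the locomotion threshold (half of the
  200 px default body length) with one margin to spare;
* locomotion seconds translate the body by 0.75 body lengths (safely
  above the 0.5 threshold), standing/foraging seconds drift by half a
  margin;
* foraging frames drop head and nose to threshold-plus-margin.

Gaussian coordinate jitter and whole-frame occlusion are applied *after*
the geometry. Noise-free tracks are therefore classified with 100 %
agreement by construction — this is the end-to-end oracle — and the
margin quantifies how much jitter the rules tolerate: the generator
warns when `margin_px <= jitter_px`. Occlusion drops all four keypoints
of a frame jointly; partial dropout is representable in the track format
but not generated by default.

The coordinate frame is fixed at 1920 × 1080 px to match the default
lying-zone constants; both are configurable together.

**What the generator does not emulate.** Real pose output has
correlated, non-Gaussian errors (identity swaps, limb confusions,
systematic occlusion near enclosure furniture), behaviors that blend
into each other, and postures the four-point skeleton cannot separate
(subtle head/mouth movements while standing). A perfect round trip on
synthetic data therefore validates the *implementation* of the rules,
not their *biological adequacy* on real footage — the published
validation counts bundled in `inst/extdata/` show what real-world
agreement looks like (strong for lying, weak for locomotion).

**Study tables.** `simulate_study_table()` draws each observation day's
time-budget proportions from per-individual, per-period Dirichlet
distributions (default baseline concentration ≈ 20 across six
categories, giving realistic day-to-day scatter). An enrichment effect
is a shift of concentration mass onto a category (`scent_effect`);
`scent_effect = 0` gives exchangeable null tables used for the type-I
error check. **Tracking points** come from a two-component Gaussian
mixture whose weights shift between periods, emulating attraction
toward a scent location.

## Evaluating automated against manual coding

`build_confusion()` counts predicted-vs-manual labels over co-observed
seconds. The manual out-of-sight category and the predicted not-labeled
category describe the same state — no usable observation — and are
paired as a single axis category on both sides; without this pairing
the matrix would not be square and one-vs-rest metrics would be
ill-defined.

`per_class_metrics()` decomposes the matrix one-vs-rest and reports
precision, accuracy, sensitivity, specificity, and the True Skill
Statistic `TSS = sensitivity + specificity - 1`, which is insensitive
to class prevalence (1 = perfect, 0 = no better than chance). Ratios
with zero denominators are `NaN`, never silently zero.

`kendalls_w()` measures agreement between the manual and automated
cumulative time budgets as Kendall's coefficient of concordance with
mid-rank ties and the tie-corrected denominator. With only five budget
categories, ties are unlikely but must not corrupt the statistic.
Significance uses the large-sample chi-squared approximation
`chi2 = m (n - 1) W` on `n - 1` degrees of freedom — with two coders
and five items this is the only practical reference distribution, and
`concordance_significance()` exposes the same mapping for checking
published W values directly. The exact permutation distribution is out
of scope.

## Ethogram statistics

Between-period and between-individual comparisons of daily time budgets
use three non-parametric tests, all authored against their textbook
definitions and verified against independent reference implementations
(`stats::wilcox.test`, `stats::chisq.test`, `stats::fligner.test`,
`vegan::kendall.global`) to 1e-8 in the test suite:

* `mann_whitney()` — U from rank sums with mid-rank ties; p by normal
  approximation with tie and continuity corrections. The approximation
  is retained even at eight days per period, matching common software
  defaults; at that sample size its realized two-sided level is a
  slightly conservative ≈ 4 %. An exact small-sample p is available via
  `exact = TRUE` for tie-free data.
* `chi_square_counts()` — Pearson chi-squared on the 2 × k table of
  second counts, no continuity correction, expected counts returned so
  the user can judge validity. The full-distribution 2 × k design is
  the default; per-behavior one-vs-rest 2 × 2 comparisons can be built
  from the same function when per-category p-values are wanted.
* `fligner_killeen()` — rank-based dispersion comparison using normal
  quantile scores of ranked absolute deviations from group medians.

Daily medians (`daily_medians()`) summarize each individual × period ×
category cell before testing, reducing temporal autocorrelation and
unequal daily sampling effort. Seconds coded out of sight are excluded
before budgets are normalized (`time_budget()`): they carry no
behavioral information and would otherwise distort proportions. Raw
p-values are reported by default; `compare_periods(adjust = TRUE)`
applies Benjamini–Hochberg across categories within an individual.

## Heat maps

`sample_points()` takes one blueprint position per 15 s interval start,
skipping (never interpolating) intervals where the animal is invisible.
`heatmap_grid()` bins points into a 64 × 36 grid (30 px cells on the
default 1920 × 1080 blueprint) and smooths with a truncated Gaussian
kernel (σ = 2 cells), then normalizes to unit mass. Histogram plus
smoothing was chosen over kernel density estimation for exact mass
control and speed; edge cells renormalize the truncated kernel so mass
never leaks off the blueprint. `difference_map()` subtracts two
normalized grids, so its cells sum to zero and its maximum marks the
largest gain in spatial use. The recovery property — the difference
map's peak falls within two smoothing bandwidths of a simulated scent
location — is what the package can honestly promise; absolute density
values depend on the arbitrary bandwidth and are only comparable
between maps built with the same grid spec.

## Numerical and testing choices

* All generators run under a private RNG stream (`seed` in the config),
  so results are bit-reproducible and independent of the caller's RNG
  state.
* Golden comparisons against published 3-decimal tables use half-up
  rounding, matching how such tables are printed.
* Test problem sizes — 12,000 s tracks for round-trip checks, 1,000
  replicate studies for the type-I error rate, 100 replicate maps for
  spatial recovery — keep every Monte-Carlo standard error well below
  the tolerance it is checked against while the full suite stays fast.
* Degenerate inputs are explicit: empty tracks classify to empty
  series, all-excluded budgets raise "no observed time", all-tied
  concordance reports `NA` with a warning rather than a spurious W.

## Limitations

The classifier covers terrestrial behaviors only; water-based and
social behaviors need cues the four-point skeleton does not carry. The
lying rule is enclosure-specific (a fixed rectangle on one camera
view). Thresholds are not learned from data; they are transcribed
constants, and the monotonicity property (raising drop thresholds never
increases foraging counts) is the only structure the package asserts
about them. The duplicate-track rule (mean inter-track keypoint
distance under a threshold) is an automated surrogate for what is, in
practice, a manual review step.
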