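---
title: "Performance fields across reference frames: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance fields across reference frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpfields)
```

## The problem

Visual discrimination accuracy at a fixed eccentricity is not uniform
around fixation.  Two robust anisotropies recur across tasks mediated by
contrast sensitivity and spatial resolution: the *horizontal--vertical
anisotropy* (HVA; better performance on the horizontal than the vertical
meridian) and the *vertical meridian asymmetry* (VMA; better performance
directly below than directly above fixation), with intermediate accuracy
at intercardinal locations.  The joint pattern is called a *performance
field*.

In everyday viewing, three candidate coordinate systems are confounded:
retinotopic coordinates (fixed to the retina, so they translate with the
eye and roll with the head about the line of sight), head-centric
coordinates (fixed to the head), and allocentric coordinates (fixed to
the environment).  They can be pulled apart experimentally in two ways:

* **Head roll.** With fixation at the screen center, rolling the head
  about the line of sight rotates retinal (and head-centric) coordinates
  relative to the screen.  If performance fields are egocentric, their
  axes should rotate with the head.
* **Fixation displacement.** With the head upright and fixed, moving the
  fixation dot away from the screen/head center changes every target's
  retinal position while leaving its head-centric position untouched.
  A retinotopic field should follow the dot; a head-centric field should
  stay put.

`vpfields` implements both manipulations end to end: the geometry, a
generative observer whose field can be anchored to any of the three
frames, adaptive threshold setting, the accuracy statistics, and a
bootstrap model comparison that decides which frame explains performance
in the fixation-displacement design.

## Geometry and conventions

All positions live in degrees of visual angle.  Angles follow the
mathematical convention: 0° = East (right), counterclockwise positive,
stored in [0, 360).  The eight canonical compass directions map exactly
to multiples of 45° (`E` = 0, `NE` = 45, ..., `SE` = 315).

**Head-roll sign.**  `apply_head_roll(loc, rho)` rotates a retina-fixed
direction counterclockwise by `rho` on the screen, as seen by the
observer.  The tilted posture modeled throughout the package is
`rho = +45`: it carries retinal East to screen North-East and retinal
South to screen South-East, so the rotated field's horizontal meridian
runs through NE and SW.  Describing a leftward head tilt with a sign is
convention-laden; we fix the convention operationally by this mapping
rather than by a verbal label.

**Displacements.**  With targets on a 6° ring and a fixation dot
displaced 4° along a cardinal axis, the retinal eccentricities of the
eight targets take exactly five values: 2, 4.25, 7.21, 9.27 and 10°
(each row of `table1()` is a permutation of {2, 4.25, 4.25, 7.21, 7.21,
9.27, 9.27, 10}).  `table1()` computes all 32 cells from first
principles and rounds half-up to two decimals, the precision at which
such tables are conventionally printed.

**Direction matching.**  A displaced target's retinal direction rarely
falls exactly on a canonical direction (e.g. the NE target under an East
shift lies at 86.73° retinally).  Two strategies are implemented for
assigning such cells to baseline ring directions:

* `snap_rule = "nearest"` (default): snap to the nearest canonical
  direction; exact midpoints (22.5° from two canonicals) break ties
  counterclockwise.  A retinotopic account should match by retinal
  direction, so this is the default.
* `snap_rule = "label"`: keep the target's original screen label.

The choice is exposed in `build_prediction_maps()` and the pipeline
configuration because the matching rule is a genuine design freedom: the
displacement distances pin down the eccentricity ring, but no physical
constraint dictates the angular assignment.  With the default generative
parameters the two rules give very similar comparisons, because the
snapped direction is always within about 4° of the true retinal
direction for these displacements.

## The generative observer

No raw behavioral data accompany the designs the package emulates, so the
synthetic observer is a first-class, tested module, not a fixture.  Its
accuracy model is deliberately minimal -- a separable product of three
factors feeding a Weibull psychometric function:

$$p(\mathrm{correct}) \;=\; \gamma + (1 - \gamma - \lambda)\,
  \bigl(1 - e^{-(c\,s/\alpha_0)^{\beta}}\bigr),
  \qquad s = m(\theta)\, E(e)\, (1 - d\,[\text{tilted}])$$

with

* **Angular modulation** $m(\theta) = 1 - h\,\lvert\sin\theta\rvert -
  v\,\max(\sin\theta, 0)$: equal to 1 on the horizontal meridian,
  $1 - h$ at the lower vertical, $1 - h - v$ at the upper vertical,
  strictly intermediate at intercardinals.  $h$ is the HVA amplitude,
  $v$ the VMA amplitude applied as an *upper-field penalty* (performance
  below fixation is the vertical-meridian reference, matching the
  empirical S-over-N advantage).
* **Eccentricity gain** $E(e) = (1 + e_0/e_2)/(1 + e/e_2)$, a hyperbolic
  decline normalized to 1 at the reference ring $e_0 = 6°$, with
  half-saturation constant $e_2$ (degrees).  This is the standard
  inverse-linear form used for cortical-magnification-like declines.
* **Oblique decrement** $d$: a fixed fractional sensitivity loss when
  the distractor array is tilted, standing in for the oblique effect.

The target's $(\theta, e)$ are taken in the observer's **anchoring
frame**: fixation-relative with head-rolled axes (retinotopic),
screen/head-centered with rolled axes (head-centric), or screen-centered
with unrolled axes (allocentric).  Those three lines are the entire
difference between the hypotheses; everything downstream is shared.

### Defaults and why

| parameter | default | units | rationale |
|---|---|---|---|
| `chance` | 0.5 | -- | two-alternative tilt discrimination |
| `lapse` | 0.01 | -- | attentive adult observers |
| `hva` | 0.20 | fraction | strong, reliably significant HVA |
| `vma` | 0.07 | fraction | present but weak: the VMA is empirically smaller than the HVA and often non-significant at n = 4; no principled value is derivable, so the default is simply "clearly smaller than `hva`" |
| `e2` | 8 | deg | places the 2--10° test range on a gently saturating decline |
| `alpha0` | 0.05 | Michelson contrast | mid-range threshold for parafoveal Gabors |
| `beta` | 3.5 | -- | canonical Weibull slope for contrast psychometrics |
| `oblique_drop` | 0.05 | fraction | small overall cost of tilted distractors |

These defaults *are* the study conditions for every simulation-based test
in the package; they were fixed once from the qualitative constraints
above and are not tuned per test.

### Gaze noise

Simulated gaze deviations exist purely to exercise the fixation filter:
a half-normal draw (sd 0.1°) truncated at 0.3°, far below the 1°
exclusion criterion, mirroring well-trained fixators for whom exclusions
are rare (under 1% of trials).  The filter itself uses a strict
inequality: a deviation of exactly 1° is kept.

### What the generator does and does not emulate

It reproduces: HVA/VMA field shape with intermediate intercardinals,
eccentricity decline, contrast dependence through a Weibull, frame
anchoring under head roll and fixation displacement, Bernoulli trial
noise, balanced randomized designs, and rare fixation breaks.  It does
*not* emulate: learning or fatigue across blocks, serial dependencies,
response bias, reaction times, attention manipulations, optic distortions
or ocular counter-roll under head tilt (the analysis ignores counter-roll
too, so retinal and head frames share the roll angle about the line of
sight).  Passing tests therefore certify the *machinery* -- geometry,
estimators, resampling, decision rule -- under a clean generative world,
not the biological accuracy of that world.

## Threshold setting

`quest_init()` / `quest_update()` implement QUEST as a discrete-grid
Bayesian staircase: a Gaussian prior over candidate log10 thresholds
(201 points spanning the prior mean ± 3 SD), multiplied after every
trial by the Weibull likelihood of the observed outcome and
renormalized.  The grid form was chosen over the original parabolic
approximation because it is numerically transparent and directly
testable against a brute-force posterior recomputation.

The estimator is the posterior mode (MAP), with grid ties breaking
toward the lower contrast.  The placement rule shifts the mode to the
contrast whose assumed psychometric value equals the criterion (75%
correct by default).  One track is run per condition; interleaved
tracks are out of scope.  In the pipeline, each condition's final
recommendation becomes the fixed contrast of that condition's main
blocks (a fixed contrast can be configured instead).

Recovery behavior at the package's test scale: over 100 simulated
200-trial staircases the median absolute error of the final mode is
about 0.02 log10 units, with no detectable bias.

## Accuracy statistics

Proportions correct are transformed with $2\arcsin\sqrt{p}$ before any
inference, stabilizing variance against the ceiling at 1.  The transform
is a bijection of [0, 1] onto [0, π]; its inverse is provided.

**Meridian contrasts** compare mean transformed accuracy between two
location sets, pairing units across sets.  The sets are defined by axis
angles rotated into the analysis frame, so the same code computes the
upright HVA ({E, W} vs {N, S}) and the tilted-frame HVA ({NE, SW} vs
{NW, SE}).  In the head-tilt pipeline the paired units are observer ×
distractor-orientation (pooling the two distractor conditions as units),
giving 8 pairs from 4 observers and df = 7 -- mirroring the analysis
convention of the designs this package emulates; whether such units are
independent is a property of that convention, mirrored rather than
endorsed.  Tests are two-sided throughout, and no multiple-testing
correction is applied.

**The omnibus ANOVA** is the fully within-subject 2 (posture) × 2
(distractor) × 8 (location) partitioning, each effect tested against its
own effect-by-subject interaction, reported with F, error MS, df, p and
partial η².  No sphericity correction is applied; the output records
this.  Degenerate inputs (no variance anywhere) are reported as F = 0
with an explicit flag rather than NaN.  The implementation is backed by
`stats::aov()` error strata and is verified against an independent
sum-of-squares oracle to 1e-8 in the test suite.

## Bootstrap model comparison

For the fixation-displacement design, performance in each of the 32
shift × location cells is compared with two baseline predictions:

* **retinotopic**: the baseline ring cell at the cell's retinal
  displacement (ring from `table1()`, direction from the snap rule);
* **head-centric**: the unchanged 6° ring cell at the same screen
  location, identical for all four shifts.

`bootstrap_cells()` draws, per observer and cell, `k = 10` outcomes with
replacement per iteration ("with replacement" is read as standard
i.i.d. resampling within every draw) and records the transformed mean,
for `n_iter = 10,000` iterations by default (tests and scaled-down runs
use fewer; the Monte-Carlo error of summary means shrinks as
$n_{iter}^{-1/2}$, which the suite verifies).  Substream seeds are
derived deterministically from one master seed over the *sorted*
observer × cell identities, and each cell's outcome vector is put in a
canonical order before resampling, so neither row order nor cell order
can change any result.

`compare_models()` pairs each observer × cell observed summary (the mean
of its iterates) with its mapped baseline summary: 4 observers × 32
cells = 128 points, paired t with df = 127, plus an ordinary
least-squares regression of observed on predicted values (predictions as
the explanatory variable, since the question is how much observed
variance the model explains).  The **winner is the model with the higher
R²**; a flag records whether the winner's paired difference is also
non-significant at 0.05.

Two cautions, both verified in simulation and inherent to the method
rather than to this implementation: the 128 paired points are not
independent (the head-centric map sends four cells to each baseline
cell), which inflates the paired test's size; and under the generative
defaults the wrong model's *mean* paired difference is near zero because
eccentricity gains above and below the 6° reference largely cancel, so
the paired test has little power against the wrong model.  R² separates
the models sharply in both directions -- in 20-replicate recovery runs
the higher-R² model matches the generating frame essentially always --
which is why the winner rule rests on R².

## Pipelines and problem sizes

`run_exp1()` simulates two sessions per observer (upright, tilted; 8
blocks × 112 trials each; each location 14 times per block; distractor
orientation fixed within a block), thresholds each of the four
conditions with QUEST, filters fixation breaks, aggregates, and emits
the ANOVA plus the four meridian contrasts for each posture in both
analysis frames.  `run_exp2()` simulates the shifted session (4 × 400
trials; 50 per shift × location cell) and the six baseline rings (400
trials each, 2,400 total; ring order counterbalanced across observers is
immaterial for a memoryless observer, so rings are simply generated in
order), bootstraps all cells, and runs the model comparison.  Both
runners derive every random stream from one master seed and write
machine-readable reports plus a manifest (config hash, seeds, versions);
apart from the manifest timestamp, reruns are byte-identical.

The test suite runs the full designs but scales the bootstrap to
`n_iter` between 300 and 1,000 and uses 20 seeded replicates for the
recovery properties; the acceptance script runs one comparison at the
full `n_iter = 10,000` and 10 replicates per frame at 1,000.  These
sizes were chosen so the whole suite completes in about a minute while
keeping every Monte-Carlo margin wide relative to its threshold.

## Known limitations

* The generative model is one convenient parameterization of a
  performance field; alternatives (e.g. cosine-harmonic angular
  profiles) would serve equally and are not implemented.
* The bootstrap comparison inherits the correlated-pairs caveat above;
  a mixed-model or Bayesian treatment is explicitly out of scope.
* Real-data ingestion is limited to the documented CSV trial-table
  dialect; eye-tracker integration is reduced to a gaze-deviation
  column.
* Printed inferential statistics from human observers are not
  reproduction targets: they depend on raw data that are not public.
  The package reproduces the *structure* of those analyses on synthetic
  data whose ground truth is known.
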