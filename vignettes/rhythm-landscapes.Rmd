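---
title: "Rhythm landscapes: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm landscapes: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhythmscape` quantifies the development of vocal rhythm from note-onset
data. This vignette explains the underlying model and the choices made
where the method leaves room for them, so results can be interpreted — and
criticized — with full knowledge of what the defaults do.

```{r setup}
library(rhythmscape)
```

## The measurement model

The atomic observation is a detected note with an onset time and a
duration, grouped into serially numbered recordings on intermittent
recording days (in the motivating use case, 24 h recordings roughly every
4 days from around day 40 post-hatch). Rhythm is treated purely as a
durational phenomenon: the order-1 inter-onset interval
`IOI(i) = onset(i+1) − onset(i)` between adjacent notes of the same
recording is a proxy for one note-to-note transition, and the IOI
*distribution* of a recording day is the day's first-order rhythm
structure. Order-k IOIs (onsets k notes apart) expose higher-order
patterns: a three-note chunk occupies a narrow window of order-2 IOIs the
way a self-repetition occupies a narrow window of order-1 IOIs.

Three conventions matter downstream:

* **Noise filter.** Detected sounds shorter than 15 ms or longer than
  350 ms are treated as detector noise and removed *before* interval
  computation (`filter_notes()`, both bounds inclusive). The filter is
  applied to note durations; the IOI range restriction is separate. This
  is a deliberate reading of an ambiguous convention — the alternative
  (filtering IOIs only) leaves noise notes corrupting both neighbouring
  intervals.
* **Binning.** Daily distributions use 35 half-open bins `[lo, hi)` of
  10 ms over 0–350 ms, with the final bin closed at 350. IOIs above
  350 ms — including those spanning silences between song bouts — fall
  outside the histogram range, so no explicit bout segmentation is needed.
  Intervals never cross recording (file) boundaries.
* **Pooling.** The per-day distribution pools all recordings of a calendar
  recording day. Landscapes (300 × 300 2D histograms) use the serial
  recording ID as the development axis for visualization; all quantitative
  analyses use day post-hatch.

## Band detection

A day's rhythm bands are the local maxima of a Gaussian kernel density
estimate of the raw retained IOI values, evaluated on a 1 ms grid over
0–350 ms. Fitting the KDE to raw values rather than to the 10 ms
histogram avoids double-binning artifacts.

**Bandwidth.** The default bandwidth rule is Sheather–Jones
(`stats::bw.SJ`), with Scott's rule, `bw.nrd` and a fixed millisecond
value as alternatives. Global scale rules such as Scott's are calibrated
for roughly unimodal samples; on a multimodal day (five bands spread over
250 ms) they inflate the bandwidth with the between-band variance and
merge neighbouring bands. In seeded recovery experiments on planted
Gaussian-mixture days (1–6 bands, ≥ 40 ms separation, component sd 10 ms,
n = 2000), Sheather–Jones recovers the exact band count and positions to
±5 ms in > 99% of replicates, while Scott's rule fails in roughly a third
of them — which is why it is not the default despite being the more
common convention.

**Maxima.** A band must be a strict interior local maximum whose
*topographic prominence* (height above the higher of the two key saddles)
is at least `min_prominence = 0.05` of the global density maximum.
Prominence, not height, is what separates a shoulder wiggle from a band:
a small bump riding on a tall peak is tall in absolute density but has
negligible prominence. Plateau maxima are reported at the plateau
midpoint; maxima at the grid endpoints are excluded by default as range
truncation artifacts. Raising `min_prominence` can only remove bands —
a monotonicity that is property-tested.

## Band tracking and emergence classification

Bands of consecutive recording days are linked by greedy nearest-neighbour
matching under `link_threshold = 30` ms (candidate links sorted by
distance, ties by earlier track id; bands sorted by position first, so the
result is invariant to input order). With ~4-day recording gaps, a real
band rarely moves more than ~20 ms between recordings; 30 ms leaves
headroom without bridging distinct bands (≥ 40 ms apart by the detector's
resolution).

An unlinked band on a later day opens a track and produces an *emergence
event*. Its **stem** is the local maximum of the previous recording day's
density nearest to the new band (ties toward the smaller position). The
event is classified as:

* `branching` — the new band differentiates continuously out of the stem:
  on the emergence day the density valley between stem and new band
  retains at least `valley_ratio = 0.5` of the lower of the two peak
  densities, *and* the stem distance is at most `distance_cap = 60` ms;
* `other` — everything else (sudden appearance at a distance, or a deep
  valley showing no continuity).

The continuity judgment in the underlying method is partly visual; the
valley/distance rule is this package's operationalization, and both knobs
are exposed. The 60 ms cap sits between the two empirical classes of stem
distance (tens of ms for branching, ~80 ms for de-novo events), and
raising `valley_ratio` can only reduce branching labels (also
property-tested). Only events before `day_limit = 80` are classified:
with intermittent recording, later emergences cannot be reliably
attributed — a band "appearing" at day 100 may have branched anytime in
the preceding gap.

## Rhythm proficiency

Proficiency is measured as the Jensen–Shannon divergence between each
day's 35-bin distribution `Q` and the final recording day's distribution
`P`: `JS = ½ KL(P‖M) + ½ KL(Q‖M)` with `M = ½(P+Q)`. Logarithms are base
2, so `JS ∈ [0, 1]`; zero-probability bins contribute zero, and `M > 0`
wherever either distribution has mass, so JS is always finite. The
base-2 choice is forced by consistency: a decay amplitude near 1 is only
attainable when the upper bound is 1, not `ln 2`.

The trajectory is summarised by 10-day decade means from day 40. The
reference-day point (identically 0) is excluded from decade means by
default so the terminal decades reflect the sampling floor — with
n ≈ 2000 intervals per day, two draws from the *same* distribution still
differ by JS ≈ 0.005 — rather than the self-comparison artifact.

The decay is fit as `y = a·e^(−b·x)` with `x` the decade midpoint in days
post-hatch, by least squares on the cross-bird decade means (unweighted).
The fit is deterministic: the amplitude is profiled out in closed form,
`b` is scanned on a fixed grid (0–0.3 per day, step 5·10⁻⁴) and refined
by bounded 1-D optimization; the reported `chi2` is the plain sum of
squared residuals.

**Crystallization** is located by paired two-sided t-tests (α = 0.01,
uncorrected, mirroring the way such cohort comparisons are conventionally
reported) of each decade's per-bird values against the terminal decade;
the crystallization decade is the earliest decade from which every later
comparison is non-significant. With five null decades tested at α = 0.01,
a single cohort has a ~5% chance of one false-positive comparison; cohort
replicates in the acceptance analyses absorb this.

## The synthetic data generator

`simulate_development()` draws each recording day's IOIs i.i.d. from a
day-varying Gaussian band mixture — sufficient because every analysis in
the package is distributional; no within-bout sequence structure is
modelled. Each `band_spec()` has a birth day, a linear position drift
(optionally with a second "settle" segment), an exponentially annealing
jitter sd, and a weight that ramps in over ~16 days after birth and can
decay exponentially. IOIs are clipped to [25, 350] ms; durations are
drawn (default N(40, 8²) ms) and clipped into [15 ms, following interval
− 1 ms], so the generated notes survive the standard noise filter and all
silent gaps are non-negative. Recording clock hours are drawn uniformly
from 6:00–19:00 to support within-day window comparisons, and an optional
hourly weight step plants rapid within-day song changes. A fixed seed
makes the emitted note table byte-identical across runs.

`preset_bengalese()` encodes the study conditions the package is validated
under: recordings every 4 days from day 40 to 152 with 2000 notes per day;
a broadband juvenile component (180 ms, sd 55 ms) that fades out over
development while a founder core band (180 ms) anneals from sd 18 to 9 ms;
two branching events off the founder (days 48 and 56, up to 225 ms and
down to 128 ms), one branching event off the lower branch (day 68, to
~70–80 ms), and one de-novo band appearing at day 64 above the established
upper branch. Branching stem distances are drawn near 25 ms
(TN(25, 15²) on [5, 55]) and the de-novo stem distance near 80 ms
(TN(78, 12²) on [68, 100]), mirroring the empirical separation between the
two classes. Positions stop drifting by day 86 and all jitter and weights
freeze at day 90, planting a crystallized stage, so the JS trajectory
decays approximately exponentially (fitted b ≈ 0.04 per day) and
cohort-level crystallization lands in the 90s decade.

Two generator features deserve comment. The broadband background
component is what makes the juvenile-to-adult transition realistic: a
bird's early rhythm is not a narrow band but diffuse timing, and without
this component the mid-development distributions over-concentrate and the
JS trajectory becomes non-monotone. And the preset's branching geometry
keeps every parent band *detectable* before its child emerges — when two
bands branch in quick succession (a chain), the second split resolves
while its parent is itself still merged with the grandparent, and the
measured stem jumps a generation. Real data will contain such chains;
on them, stem distances for rapid sequential branchings are biased
upward.

## What recovery tests do and do not show

The simulator emulates band structure, emergence, annealing and
intermittent sampling. It does **not** emulate: sequential dependence of
intervals within bouts (real IOIs are autocorrelated through song syntax),
bout structure and its long gaps, day-to-day variation in recording
effort, detector artifacts other than the duration range (double
triggers, missed onsets), or acoustic features of any kind. Passing
recovery tests therefore demonstrates that the estimators are correct and
well-calibrated for distributional structure of the planted kind — not
that the pipeline is robust to every pathology of field recordings.
The measured quantities also differ subtly from their planted
counterparts: a branching band is *detectable* only once it is ~35 ms
clear of its stem, so recovered first-appearance distances for the
branching class (~40 ms in the acceptance runs) sit systematically above
the planted branch offsets (~25 ms), while de-novo distances are
recovered nearly unbiased. The same detectability lag applies to real
recordings, where a branch must separate before any detector can see it.

## Numerical and degenerate-input conventions

* Empty daily distributions are flagged (`n = 0`, `probs = NULL`), never
  NaN-filled; trajectory computation skips such days with a warning.
* KDE requires n ≥ 2; a zero-spread sample falls back to a 1 ms bandwidth.
* Negative silent gaps (overlapping detections) are dropped and counted.
* Rows of a note table with unparsable numerics are dropped and counted
  in the load report, not fatal.
* Divergences validate normalization to 1e-9 and reject length
  mismatches; `KL` returns `Inf` on support violations, `JS` never does.
* The exponential fit constrains b ≥ 0 and errors on all-zero input;
  a constant series yields b = 0 exactly.
* Ties: nearest-stem ties resolve toward the smaller position; track-link
  ties toward smaller distance, then the earlier track id.

## Problem sizes

The validation analyses use 2000 notes per simulated recording day
(29 days per bird), 100 replicates for band recovery, 50 single-bird
replicates for classification recovery, 200 replicates for fit recovery,
and 12-bird cohorts (20–40 replicates) for the crystallization analyses.
These sizes keep every distributional estimate well inside its asymptotic
regime while the whole validation suite runs in minutes on one core.
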