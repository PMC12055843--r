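---
title: "Analysing picture-naming gaze data with gazelex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing picture-naming gaze data with gazelex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazelex analyses screen-based eye-tracking recordings from picture-naming
(lexical retrieval) tasks, of the kind used to characterise visual search
in normal pressure hydrocephalus (NPH) against healthy elderly (HE)
controls. This vignette explains the models and conventions behind each
stage, the parameters that matter, and what the synthetic study used in
the test suite does and does not establish.

## The event model

Raw input is a stream of gaze samples — a timestamp plus a screen-pixel
coordinate (origin top-left, y downward), nominally at 28.43 Hz on a
1,920 × 1,080 display. Classification is velocity-threshold (I-VT):

1. Each inter-sample segment gets an angular velocity. A pixel
   displacement of $d$ px subtends
   $\theta = 2\,\mathrm{atan}\!\left(\frac{d \cdot p}{2D}\right)$
   degrees, with $p$ the pixel pitch (default 0.2745 mm, a 23.8-inch
   full-HD panel) and $D$ the viewing distance (default 550 mm); velocity
   is $\theta / \Delta t$. Segments above 30 °/s are saccadic.
2. Maximal runs of samples joined only by sub-threshold segments are
   fixation candidates; a candidate whose span (last minus first sample
   time) reaches 70 ms becomes a fixation, shorter runs are discarded and
   counted. All samples of a fixation are snapped to its first sample's
   coordinate.
3. Saccadic samples are transitional and excluded. Each saccade event is
   reconstructed as the gap between consecutive fixations, carrying the
   two snapped coordinates as endpoints. This is the only reading under
   which saccade durations remain positive once saccadic samples are
   dropped, and it implies the unit gap SC = FC − 1 on any stream the AOI
   filter leaves intact.

A stationary run shorter than 70 ms is neither fixation nor saccade; it
is counted in the discard tally. The velocity clause is applied to
consecutive *samples*: phrasing it between consecutive *fixations* would
be circular, and the per-sample form is the standard online I-VT.

Analysis is restricted to a central area of interest (AOI) of
1,483 × 707 px. Offsets are not part of the published setup, so the AOI
is centred, with half-open integer bounds and floored margins:
x ∈ [218, 1701), y ∈ [186, 893). The AOI test is applied to the snapped
fixation coordinate, not to individual samples, because all metrics are
defined on snapped fixations; saccades are rebuilt between the surviving
fixations.

## The six metrics

Per trial, over AOI-filtered events: FC (fixation count),
FD $= \sum (t_{end} - t_{start})$ in ms, SC (saccade count),
SD $= \sum (s_{end} - s_{start})$ in ms, SST $= \sum \sqrt{\Delta x^2 +
\Delta y^2}$ in pixels, and SAT $= \sum \mathrm{atan}\!\left(
|\Delta y| / |\Delta x|\right)$ in degrees.

SAT deserves a caveat: as defined it sums the *direction angle* of each
saccade relative to horizontal, not a visual-angle amplitude, despite its
name. The absolute (acute) angle is used so contributions cannot cancel;
signed angles could sum to near zero over a trial, which is incompatible
with the magnitudes such studies report (~30° per saccade). A
conventional amplitude — the visual angle subtended by each displacement
— is emitted separately as `SAT_visual_deg` and never substituted.

Group statistics operate on participant-level means (unweighted over
trials within participant × response type), not trial rows: published
group tables in this field report participant rows (n = 14 vs 12). A
participant with no trials of a type has that cell absent, not zero.

## Grid-based spatial statistics

The AOI is partitioned into a 10 × 10 grid of equal half-open cells.
Over a pool of inside fixations:

* **Grid entropy** $H = -\sum p_i \log_2 p_i$ over occupied cells, in
  bits. Base 2 is a deliberate choice: natural-log entropy over 100 cells
  is bounded by ln 100 ≈ 4.61, below values these analyses are expected
  to reach (≈ 5.6), whereas the base-2 bound is log₂ 100 ≈ 6.64.
* **Spatial dispersion**: mean Euclidean distance between consecutive
  fixations, in grid-cell units (x in cell widths, y in cell heights).
  Cell units keep values in the single digits (the AOI diagonal is ≈ 14.1
  cells); raw pixels would be three orders of magnitude larger.
* **Grid occupancy**: occupied cells / 100.
* **Transition density**: unique ordered inter-cell transitions divided
  by all observed inter-cell transitions; within-cell steps count in
  neither. The denominator is the *observed* transition count — against
  the count of possible cell pairs the ratio would be pinned near zero at
  realistic fixation counts, incompatible with reported values ≈ 0.9.
* **Clark–Evans nearest-neighbor index**: observed mean nearest-neighbor
  distance over $0.5\sqrt{A/n}$, the expectation under complete spatial
  randomness in a region of area $A$ (the AOI rectangle). No edge
  correction is applied; at the fixation counts involved the boundary
  bias is well under the differences of interest. Below 1 is clustered,
  above 1 dispersed.

Pooled summaries are per (response type, item, group), fixations pooled
across participants in temporal order; consecutive-pair statistics never
straddle trial boundaries. Whether to compute dispersion before or after
AOI removal of intervening fixations is genuinely open; it is computed on
the inside-fixation sequence.

## Visualization

Heatmaps sum an isotropic Gaussian kernel (default σ = 50 px, no
published bandwidth exists) at each fixation, duration-weighted by
default (count weighting available; the weighting used in published
figures is unstated). Each kernel is normalised to unit mass after edge
clipping, so total mass equals total weighted fixation count exactly and
the field is linear in its inputs. Scanpaths draw duration-scaled,
numbered fixation circles joined by saccade segments. Both renderers
return their numeric artifact (density matrix, ordered polyline) so tests
bind to numbers, not image bytes; the polyline length is identically the
trial's SST.

## Statistics

* **Mann–Whitney U** (groups are small and non-normal): mid-ranks for
  ties, U = min(U₁, U₂), Z from the tie-corrected normal approximation
  without continuity correction, two-sided p — the reporting convention
  of clinical statistics software.
* **Pearson correlation** between naming accuracy and each metric, with
  the usual t-based p.
* **Two-way mixed ANOVA** (group × response type) as the classical
  decomposition with an `Error(participant)` stratum, each F on
  df (1, N − 2); Bonferroni-corrected paired post-hocs of correct vs
  incorrect within each group (family size 2 — the family the design
  implies).
* **Post-hoc power**, one convention per test family: noncentral t with
  ncp $= d\sqrt{n_1 n_2 / (n_1 + n_2)}$ for two-sample comparisons, with
  sample sizes scaled by the Wilcoxon ARE 3/π when the comparison was
  rank-based; Fisher-z for correlations; and observed power for F
  effects with λ = F·df₁. These are the standard conventions of
  G*Power-style post-hoc analysis.

`reference_study()` carries the published participant-level summary
statistics (means, SDs, U, r, F values) of the calibrating NPH study;
`reference_power_report()` recomputes every power claim derivable from
them. The raw recordings behind those tables are not public, which is
precisely why the package ships a generator.

## The synthetic study

`simulate_trial()` is a renewal process alternating fixation plateaus
and saccadic gaps on the regular sampling grid, built so its own event
log is an *exact* classification oracle:

* plateau durations are lognormal (moment-parameterised), truncated
  below at 70 ms, and rounded to whole sample intervals — rounding makes
  the classified span an unbiased estimate of the drawn duration
  (flooring would bias it by half a sample period, ≈ 6% at 300 ms);
* plateau centres follow a fixed-step-length random walk (truncated
  normal step length, direction resampled until the target stays in the
  AOI, so realised step lengths equal drawn ones), ejected outside the
  AOI with a per-cohort probability;
* within-plateau jitter is uniform in a 9 px disc, keeping sample-to-
  sample velocity under half the 30 °/s threshold, so no plateau can
  split;
* gap interiors sweep far off the inter-fixation axis so every gap
  segment exceeds the threshold, so no plateaus can merge; single-sample
  gaps are promoted to two samples when the displacement alone could not
  clear the threshold.

The default cohort presets target the published magnitudes: on correct
trials ≈ 14 (NPH) vs ≈ 10 (HE) inside-AOI fixations of ≈ 279 / 265 ms,
≈ 172 / 186 ms gaps, ≈ 275 / 232 px steps, outside-AOI probabilities
0.15 / 0.10, and incorrect-response rates 0.425 / 0.192 (solved from the
published overall vs per-response-type fixation counts, and consistent
with naming accuracies of ≈ 52% vs ≈ 84%). The count parameter is
divided by (1 − outside-AOI probability) because it governs all
generated plateaus while reported counts cover inside fixations only.

Two honest compromises:

* A single `incorrect_multiplier` scales both the count and duration
  parameters on incorrect trials. Published tables imply the count ratio
  (≈ 2.4) arises almost entirely from more fixations, with per-fixation
  duration nearly constant; a single multiplier applied to both cannot
  reproduce both the FC and FD incorrect/correct ratios at once. The
  defaults (1.68 NPH, 1.60 HE) are the log-least-squares compromise, and
  every directional property (incorrect > correct on all metrics, in
  both cohorts) is preserved.
* Participant-level summary SDs cannot be decomposed into between- and
  within-participant parts from published tables alone; the generator
  splits each variance half/half (a lognormal multiplier on participant
  means plus a shrunken trial-level sd).

What passing tests show, and what they do not: the generator emulates
alternating fixation/saccade structure, cohort and response-type effects
of realistic magnitude, and inside/outside AOI dispersion. It does not
emulate main-sequence saccade dynamics, blinks, pupil data, tracker
dropout, smooth pursuit, or item-level difficulty (correctness is
Bernoulli per trial, so pooled "incorrect" cells contain fewer trials
than in a study that showcases reliably failed items). Tests passing on
synthetic data validate the pipeline's arithmetic and invariants, not
any clinical claim about real NPH gaze behaviour.

## Numerical choices and degenerate inputs

* Fewer than two samples classify to an empty stream, not an error;
  empty streams give all-zero metrics.
* Grid statistics that need ≥ 1 (entropy, occupancy) or ≥ 2 (dispersion,
  transition density, NNI) inside fixations report missing values below
  those counts, never zeros.
* Fixations exactly on a grid cell's maximum edge belong to the last
  cell (relevant only when the AOI filter is bypassed).
* A zero-variance ANOVA (all cells equal) reports F = 0, p = 1 rather
  than NaN.
* Mann–Whitney with all values tied reports Z = 0, p = 1.

## Problem sizes in the test suite

The default simulated study is 14 + 12 participants × 30 trials
(≈ 780 trials, ≈ 170k samples); parameter-recovery checks use a single
1,000-fixation trial; oracle equivalence runs 100 random 200-sample
streams; the ANOVA type-I calibration uses 800 replicates of a
12-participant design. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the suite quick to run.

## Known limitations

* The trial window (stimulus onset to response) must be pre-cut by the
  caller; the published procedure does not state the window end, so the
  package does not guess one.
* SAT is implemented exactly as the field defines it (a summed direction
  angle); users wanting a true amplitude should read `SAT_visual_deg`.
* The Clark–Evans index is uncorrected for edge effects.
* Proprietary tracker smoothing upstream of the recorded samples is
  unknowable; the classifier implements the stated rules only.
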