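---
title: "Quantifying male mating behavior and dual-reporter calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying male mating behavior and dual-reporter calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormmate)
```

`wormmate` turns recordings of *C. elegans* male mating — two-channel
fluorescence stacks, grey-scale spicule videos, annotated behavioral
timelines and centroid tracks — into the quantitative readouts used to study
how dopamine and acetylcholine signaling shape copulatory motor programs.
This vignette is the package's account of the underlying models, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical choices made where the procedure left latitude.

## Ratiometric %ΔF/F0 correction

### The measurement model

A green calcium indicator (G-CaMP) and a calcium-insensitive red fluorophore
(mDsRed) are co-expressed in the cells of interest and imaged simultaneously
at ~30 frames/s. For each frame, the mean pixel intensity (MPI) of a cell
ROI and of a same-channel background ROI are measured, and background is
subtracted. The background-subtracted traces are modeled as

* green: `G(t) = G0 · (1 + transient(t)) · exp(−kg·t) · a(t)`
* red:   `R(t) = (plateau + span · e^(−rate·t)) · a(t)`

where `a(t)` is a per-frame multiplicative artifact shared by both channels
(focusing, gross movement, muscle contraction, arc-lamp flicker), `kg` is
the minimal green bleach rate, and the red channel photobleaches with
one-phase-decay kinetics. Because `a(t)` is shared, it cancels from the
green/red ratio — the property the correction exploits.

### The correction

`fit_reference()` summarizes the red trace either as a flat average line or
as a bounded least-squares one-phase decay `R̂(t) = plateau + span·e^(−rate·t)`
(plateau, span, rate ≥ 0, initialized at `min(red)`, `max − min`, and
1/duration). The per-frame correction value is `c(t) = red(t)/R̂(t)`;
`correct_and_dff()` divides the green trace by `c(t)` (equivalently,
multiplies by its inverse) and computes

```
%ΔF/F0(t) = 100 · (G_corr(t) − G_corr(t1)) / G_corr(t1)
```

with F0 fixed at the **first** frame. `call_events()` then classifies
contiguous runs of %ΔF/F0 above an artifact band (default 20%) as calcium
events, merging runs separated by fewer than `min_gap` frames (default 3)
and discarding events shorter than `min_len` frames (default 2).

### Parameter choices and their rationale

* **Reference mode `auto`** fits the decay and falls back to the mean line
  when the fit fails, the fitted rate is not positive, or the decay does not
  reduce the sum of squared residuals by at least 5% relative to the mean.
  The original workflow chose per recording by eye; the 5% margin is this
  package's operationalization of "bleaching pronounced enough to matter".
* **F0 at the first frame.** The percent change is referenced to the first
  recorded frame. (One figure legend in the source workflow says "last
  frame", in conflict with its own methods text; first frame is implemented.)
* **20% artifact band.** Hyperpolarized-neuron control recordings put
  focusing/motion artifacts within a 0–20% apparent change; the band is a
  configurable default, not re-estimated from data.
* **Decay fitting** uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  non-negativity bounds; unlike Gauss–Newton `nls()`, it converges on
  noiseless (zero-residual) traces, which the test suite exploits to verify
  parameter recovery to 1e-6 relative error.

### What the correction cannot do

The reference fit separates photobleaching from artifacts only when the
artifact has little low-frequency, decay-shaped content. A slow monotone
focus drift is mathematically degenerate with the bleach curve: the fit
absorbs part of it into `R̂`, and the absorbed share reappears in %ΔF/F0 as
a bias. This is a property of the method, not of the implementation. The
synthetic generator's default artifact is therefore frame-scale flicker
(below); users can pass a slowly drifting `artifact_series` to study the
failure mode explicitly.

## Spicule-thrust rhythmicity

During insertion attempts the male thrusts his spicules against the vulval
slit at 7–11 Hz. In a grey-scale recording (~35 frames/s), a rectangular ROI
drawn over the spicule region changes its pixel composition as the spicules
move, so the per-frame **population** standard deviation of pixel intensity
(`sd_trace()`) oscillates at the thrust frequency. The trace is normalized
as percent deviation from the bout **median** — the median rather than the
mean because it resists contamination by the deflection peaks themselves;
the original workflow never states its reference level.

`detect_deflections()` scores one deflection per oscillation whose
peak-to-baseline amplitude exceeds 5% (peak-to-baseline rather than
peak-to-trough, configurable). Two numerical points matter at this sampling
density (3–5 samples per cycle):

* The sampled maximum understates the continuous oscillation amplitude by up
  to ~45%, so the trace is upsampled by cubic-spline interpolation (factor 8)
  before peak picking, and the amplitude criterion is applied to the
  interpolated peaks. Without this, genuine 10% oscillations at 11 Hz are
  intermittently scored below a 5% threshold purely through sampling phase.
* A refractory window (default 30 ms) suppresses double-counting of a single
  peak; it is kept well below the shortest physiological period (~91 ms).

`deflection_set()` carries the inter-thrust intervals; the summary frequency
is `(count − 1)/(last − first)` and the interval SD operationalizes
(ar)rhythmicity: mutants with disrupted D2-like signaling show runs of rapid
shallow thrusts whose interval spread is larger than wild type at equal mean
frequency. `rhythmicity_summary()` tabulates both per bout and pools
intervals for group comparisons.

## Behavioral scoring

### The E_SI score

The efficiency of spicule insertion ranks the spectrum of male performances
during the first 120 s of contact with a paralyzed mate:

```
E_SI = (t_prod / t_total) × (1 / max(t_nonprod, 1 s)) × (1 + bonus)
bonus = 0 without penetration, else (cap − t_pen)/cap
```

`t_prod` is time spent prodding at the vulva, `t_nonprod` is in-contact time
not attempting insertion, `t_total = t_prod + t_nonprod`, all truncated at
the 120 s cap; `t_pen` is the penetration time.

The one genuinely open choice is the penalty denominator when a male prods
immediately on contact: `t_nonprod` is then 0 and the printed formula
divides by zero — yet the formula's own worked example assigns such a male
1.99 = 1 × 1 × (1 + 119/120). Clamping the denominator at 1 s is the minimal
rule that reproduces that example and is what `compute_esi()` implements;
whether the original calculation clamped, added a constant, or simply never
met `t_nonprod < 1 s` in real data cannot be determined from the formula
alone. "Attempting insertion" maps to the `vulva_prodding` label only:
arched-posture prodding away from the vulva counts as non-productive
contact, consistent with the score's purpose of penalizing ectopic attempts.

### Other metrics

* `compute_icl()` — in-contact length as a percentage of body length, a
  posture proxy (lower = more arched); lengths are supplied by the analyst
  from skeletonized outlines, no segmentation is performed here.
* `contact_metrics()` — vulva-contact counts and durations, the mean
  in-contact time between successive insertion attempts, and cumulative /
  average contact across episodes (episodes are maximal runs of in-contact
  intervals uninterrupted by `off` time).
* `centroid_kinematics()` — distance traveled and velocity from centroid
  tracks, for ruling out locomotor confounds.
* `potency_fraction()` — the proportion of males siring cross-progeny, feeding
  the categorical tests.

## Statistics

`fisher_exact()`, `mann_whitney()` and `anova_tukey()` are thin, typed
surfaces over base R's `fisher.test`, `wilcox.test` and `aov`/`TukeyHSD`,
matching the conventions of the graphing software used in this field:
probability-mass two-sided Fisher p-values; exact Mann–Whitney p by
enumeration when the combined sample is ≤ 20 without ties, otherwise the
tie-corrected normal approximation with continuity correction; Tukey's HSD
as the only within-family adjustment. The test suite checks them against
independent hand-written oracles (full hypergeometric enumeration, all-
assignments permutation, hand ANOVA formula) rather than trusting either
implementation alone. A 2×2 table with a zero margin carries no information
and is reported as p = 1 with a flag. A zero-residual-variance ANOVA is
flagged rather than reported.

One calibration fact worth knowing: at 30 animals per arm the exact
two-sided Fisher test rejects a true null at α = 0.05 with probability at
most 0.0274 (exact enumeration, maximized over the binomial success
probability at p = 0.5). The test is substantially more conservative than
its nominal level at these sample sizes, which is the price of exactness on
a coarse discrete support.

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth carrying the statistical structure the analysis assumes.

**Stacks** (`simulate_stack()`): cells are filled discs (shape is irrelevant
to MPI-based analysis); green cell pixels follow the transient model, red
cell pixels the bleach model, both multiplied by the shared artifact, plus a
uniform background and additive Gaussian noise truncated at zero. Defaults
emulate a 10 s vulval-contact recording: 30 frames/s, green baseline 100 AU
over a 10 AU background, red bleach (plateau 90, span 60, rate 0.2 /s —
most of the bleachable pool lost within a bout, the regime in which a decay
reference is warranted at all), pixel noise SD 2 AU (2% of baseline).

* **Transients** are multiplicative on the green baseline with a linear rise
  over the first 20% of the event and an exponential fall (τ = duration/4),
  so the scheduled amplitude is exactly the peak %ΔF/F0 and the score is
  scale-free. Onsets must be positive because frame 0 defines F0.
* **The artifact series** defaults to frame-scale flicker: iid Gaussian
  excursions squashed by `tanh` into roughly [0.9, 1.1]. Two considerations
  fix this choice. First, the apparent %ΔF/F0 change the artifact alone
  induces must stay within the ~0–20% band that hyperpolarized-neuron
  controls establish for real recordings. Second, focus and stage position
  are actively corrected during acquisition, so artifact excursions are
  transient; a slowly drifting artifact is decay-degenerate and defeats any
  red-referenced correction (see above). Slow drift remains available by
  passing `artifact_series` explicitly.

**Timelines** (`simulate_timeline()`): alternating scanning/prodding bouts
with exponential durations (means 10 s and 8 s), truncated at the 120 s cap
or at the first penetration; each prodding bout is ectopic with probability
`p_ectopic` (emitted as non-productive contact and unable to penetrate) and
an on-vulva bout that completes within the window penetrates with
probability `p_penetration_per_bout` (default 0.3). Raising `p_ectopic`
emulates the dopamine-deficient regime of precocious thrusts at random
body locations; the package's directional check verifies that this lowers
median E_SI.

**Thrust traces** (`simulate_thrust_trace()`): per-cycle raised-cosine
deflections of half-width a quarter period on a flat baseline — a 50% duty
cycle, so the bout median (the detector's reference) equals the baseline by
construction — with per-cycle Gaussian timing jitter, cycle dropouts, and
additive noise (default 0.5% of baseline). Configurations violating the
Nyquist condition are rejected.

All generators draw every random quantity from a single seeded stream per
call (`withr::with_seed`); seeds are required arguments and no global state
is touched, so identical configurations are bit-reproducible.

### What the generator does not emulate

No optics: no point-spread function, no magnification dependence (real
recordings mix 10× and 20× objectives), no bleed-through between channels,
no shot-noise scaling with intensity, no cell movement within the frame
(per-frame ROI repositioning is an input, mirroring the manual workflow).
Passing tests therefore demonstrate correctness of the analysis chain under
the stated measurement model — not robustness to segmentation error,
channel cross-talk, or drift-dominated artifact regimes.

## Validation scale and interfaces

The test suite validates parameter recovery at the scale of the emulated
experiments: 20 replicate stacks (64×64 px, 300 frames) for end-to-end
transient recovery within ±5 percentage points; 100 replicate bouts per
frequency at 7, 9 and 11 Hz for thrust-frequency recovery within 0.5 Hz;
5000 simulated null comparisons for exact-test calibration; 100 timelines
per regime for the E_SI direction check. `scripts/acceptance.R` re-runs the
same computations from scratch with a user-supplied seed and writes the
resulting numbers as JSON.

File interfaces are deliberately plain: multi-page TIFF for stacks
(frame-major pages, green before red; 32-bit floats scaled by a documented
factor because TIFF floats live in [0, 1]), and headered CSV for ROI tracks
(0-based, half-open rectangles), traces, timelines and deflections. The
package's functions are its interface; analyses are driven from R scripts
rather than a shell entry point.

## Known limitations

* Rectangular ROIs only; no tracking, no segmentation.
* The reference fit cannot separate decay-shaped artifact drift from
  photobleaching (inherent to single-reference ratiometry).
* Deflection detection assumes the supplied window covers one uninterrupted
  prodding bout (≥ 1 s; typically 6–10 s), as in the manual workflow.
* The E_SI penalty clamp below 1 s of non-productive contact is a modeling
  decision constrained by a single worked example.
* Exact tests on small discrete supports are conservative; reported
  rejection rates under the null sit well below nominal α.
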