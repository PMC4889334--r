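---
title: "Models and methods behind ribotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotrace)
```

ribotrace models single-molecule translation imaging experiments of the
SunTag/PP7 type: an mRNA carries an N-terminal array of epitopes that are
bound by a fluorescent single-chain antibody as soon as they emerge from
the ribosome exit tunnel, so the fluorescence of a translation site reports
how many ribosomes are engaged and how far each has translated.  The
package contains (i) the deterministic intensity model linking ribosome
positions to fluorescence, (ii) an exact stochastic simulator of ribosome
traffic, (iii) the estimators that invert traces back to kinetic
parameters, and (iv) a scenario generator that produces labeled synthetic
datasets at desk scale.  This vignette explains the models, the default
parameters and the numerical choices.

## The intensity model

A reporter is described purely geometrically: an ORF of $L$ codons with
epitope completion positions $e_1 < \dots < e_K$ and an exit-tunnel offset
$\Delta$ (codons translated between peptide-bond formation and antibody
accessibility).  A ribosome at codon $x$ exposes

$$f(x) = \frac{1}{K}\,\#\{i : e_i + \Delta \le x\},$$

and a translation site with ribosomes at $x_1,\dots,x_N$ has noiseless
intensity $I = \sum_j f(x_j)$, in units where one fully synthesized,
fully labeled mature protein equals 1.  All traces and estimators use this
unit, so any conversion from camera counts happens at the I/O boundary.
A continuum mode replaces the staircase $f$ by the linear ramp between
$e_1+\Delta$ and $e_K+\Delta$; it is what the runoff fitter uses.

For a ribosome positioned uniformly on the ORF the expected intensity is
$\bar c = L^{-1}\sum_{x=1}^L f(x)$ (`mean_positional_correction()`), and
ribosome number is estimated as $N = I/\bar c$.  For the default
`kif18b_suntag24` preset ($L = 1467$, 24 epitopes, $\Delta = 35$),
$\bar c \approx 0.752$.

**Geometry defaults.**  The main reporter pairs a 24-epitope array with a
2.5 kb kinesin ORF for a 4.4 kb coding region in total; the epitope array
therefore spans the first $\approx 634$ codons and the default places the
epitopes uniformly, $e_i = \mathrm{round}(26.4\,i)$.  The exact epitope
spacing of the tag array is not part of the geometric record we model
from, so uniform spacing is an explicit, configurable assumption.  The
exit-tunnel offset defaults to $\Delta = 35$ codons, a typical tunnel
occlusion of 30–40 residues; it too is configurable per construct.

**Label stoichiometry.**  The mRNA channel is modeled by counting
fluorophores: hairpins × coat proteins per hairpin (a dimer, 2) ×
fluorophores per coat protein (2) × hairpin occupancy, relative to the
24-fluorophore single-protein standard.  Full occupancy predicts a 4-fold
brighter mRNA spot; 50% occupancy predicts 2-fold, the expected value for
a spot containing a single mRNA.

## The traffic simulator

`simulate_translation()` runs an exact event-driven simulation of a
TASEP-like exclusion process, implemented in C++:

* **Initiation** attempts occur at rate `k_init` while the mRNA is in the
  translating state and no drug blocks initiation.  An attempt that finds
  the first `footprint_codons` occupied is held as a single pending
  complex and enters the moment the region clears.  This makes the
  initiation flux insensitive to the footprint at physiological spacings
  (one ribosome per 200–400 nt), which matches the observation that
  ribosome density, not exclusion, limits loading; with plain thinning
  the occupancy would fall ~7% below the flux-balance prediction at the
  default parameters.
* **Elongation** advances each unblocked ribosome one codon after an
  exponential wait of mean `1/k_elong` (memoryless per-codon clocks — the
  standard treatment when per-codon dwell data are unavailable).  A
  deterministic mode with fixed step times exists for analytic tests.
* **Exclusion**: a step or initiation is blocked if it would bring two
  ribosomes closer than `footprint_codons` (default 10 codons ≈ 30 nt).
* **Pause and damage sites** insert an extra exponential dwell on
  arrival.  A pause site draws from a two-component mixture (default:
  10 s for most ribosomes, 800 s for a 10% minority — the signature of a
  regulatory pause where only a subset of ribosomes stall long).  A
  damage site delays *every* ribosome (default mean 300 s), the
  signature of a chemically damaged nucleotide.
* **Drugs**: harringtonine and hippuristanol block initiation after
  `add_time + entry_delay`; puromycin releases all nascent chains
  instantly and blocks initiation; cycloheximide freezes all movement.
  Default entry delays are 60 s (30 s for puromycin).
* **State switching** is a two-state process acting on initiation only;
  elongating ribosomes always finish, which is why traces show a gradual
  ribosome runoff after a spontaneous shutdown rather than a step drop.

**Shutdown/re-initiation semantics.**  The calibrated cycle rate
(0.29 per mRNA-hour) counts *complete* shutdowns — the signal reaches
zero and later reappears — and the 2.5% non-translating lifetime fraction
with its implied 5.2 min mean dwell are measured between signal
disappearance and reappearance.  A plain telegraph process with a 5.2 min
off state would rarely reach zero signal before re-initiating, because
runoff itself takes ~7 min.  The generator therefore keeps initiation off
after a shutdown until the mRNA has emptied and only then starts the
exponential re-initiation clock (`reinit_requires_empty = TRUE`).  With
this convention the segmentation estimator recovers both calibrated
numbers from simulated data.

**Noise.**  Rendered traces add Gaussian noise with variance
$\sigma_0^2 + \sigma_1^2 I$ (affine in signal, the usual shot +
background decomposition).  Real measurement noise is instrument-specific,
so the defaults $\sigma_0 = 0.2$, $\sigma_1 = 0.1$ were chosen once to
give a single-ribosome plateau (1 unit) a signal-to-noise ratio of about
5, and are exposed in every scenario config.

## Estimators

**Runoff model fit.**  After initiation stops at $t_0$, the ribosome
density recedes from the 5' end at speed $v$.  With the continuum ramp
intensity, the normalized ensemble-mean trace is
$I(t) = G(v(t-t_0))/G(0)$ with $G(u)=\int_u^L f$, a three-stage curve:
flat while the front crosses the epitope-free leader, a quadratic
shoulder across the epitope array, then a linear decline of normalized
slope $-v/(L\bar c)$ until zero.  `fit_runoff_elongation()` normalizes
the cumulative mean trace to its pre-drug level and least-squares fits
$v$ with the two stage boundaries free (Nelder–Mead; boundaries
initialized from the construct geometry).  The cumulative mean is the
default target because individual traces are dominated by single
termination steps; a per-trace mode exists.  Uncertainty comes from a
bootstrap over mRNAs (200 resamples) since no closed-form error is
available for the staged fit.  An ensemble whose mean trace decays less
than 10% is flagged (`success = FALSE`) rather than raising an error.

**Total runoff time.**  The per-mRNA disappearance time minus the drug
entry delay is one full traversal, so $k = L/\overline{(T - 60\,s)}$,
with a delta-method standard error.  The estimate carries a small
(~+5%) upward bias because the last-initiated ribosome starts slightly
inside the ORF; the bias shrinks with initiation rate and is well inside
the method's uncertainty.

**Initiation rate.**  Steady-state flux balance:
$k_\mathrm{init} = N k_\mathrm{elong}/L$, reported per minute.  Ten and
twenty-five ribosomes at 3.5 codons/s give 1.4–3.6 min⁻¹.

**State segmentation.**  Traces are median-filtered (3 frames),
thresholded with hysteresis (off below $0.8\times$, on above $1.2\times$
the threshold) and a 2-frame minimum dwell; boundaries are refined by
linear interpolation of the threshold crossing.  The default threshold
(0.4 units) is two background-noise standard deviations at the default
noise level.  Hysteresis and dwell suppress chatter; interpolation keeps
the off-fraction estimate unbiased to well below a frame.

**Single-ribosome events.**  Episodes above threshold are detected on
the filtered trace, but boundaries are measured on the raw one (the
median filter widens an episode by up to a frame per edge).  The
appearance time is the x-intercept of a linear fit to the rising phase,
including sub-threshold rise frames down to the noise floor — the moment
the first epitope cleared the tunnel; the loss time interpolates the
abrupt terminal drop at half plateau.  The event rate is
$(L - (e_1+\Delta))/(t_\mathrm{loss}-t_\mathrm{appear})$: the visible
distance divided by the visible duration.  Episodes whose plateau is far
from one unit are flagged `overlapping` and excluded from rate summaries
rather than split.

**Stall classification.**  Two mechanisms are distinguished by where the
intensity loss happens inside the decay interval.  A roadblock (one
defective ribosome) halts decay until the stall resolves, then releases a
burst; mRNA damage delays every ribosome, producing a steady, slow
decay.  `classify_stall()` marks frames with above-average loss, merges
them into active segments (gaps ≤ 2 frames), and calls `"burst"` when
the active segments cover < 30% of the interval, are few (≤ 4) and the
largest carries ≥ 30% of the loss; otherwise `"slow_linear"` when ≥ 20%
of the signal remains at the check time (default 15 min), else
`"normal"`.  `is_stalled` uses the retained fraction at the check time
against a 50% threshold.  On simulated ensembles (n = 200) the two
signatures separate with ≥ 95% accuracy.

**Buildup analysis.**  Traces are aligned at first detection.  Once the
pioneer ribosome clears the epitope array, every subsequent initiation
adds one unit in expectation, so the mean curve grows linearly with
slope equal to the initiation flux until terminations begin; the slope
is fit inside that window (computed from the construct geometry).  The
implied initiation rate regresses the mean curve on the exact buildup
model $g(t) = \int_0^t f(k s)\,ds$ shifted by the detection lag, with an
intercept absorbing the pioneer's head start.  Ensemble comparisons use
a bootstrap over mRNAs for the slope difference — a single planned
comparison, so no multiplicity correction.

**Intensity distributions.**  Sites below the translating cutoff
(2 noise SD) are excluded; per bin the mRNA fraction and the
intensity-weighted (ribosome-weighted) fraction are reported.  This is
what reveals initiation heterogeneity: in the repressive-5'-UTR mixture
scenario, ~2% of transcripts carry ~half of all ribosomes.

**Diffusion.**  Time-averaged MSD at lags 1–5 is fit by weighted least
squares to $\mathrm{MSD}(\tau) = 4D\tau + b$ (weights = pair counts; the
intercept absorbs localization error).  Negative slopes truncate to
$D = 0$ with a flag.

## Scenario generator and calibrated defaults

`paper_default_parameters()` tabulates the values the scenarios are
calibrated to: elongation 3.5 codons/s (model fit), 3.1 (runoff time),
3.0 (single ribosomes), 4.9 (codon-optimized); initiation 1.4–3.6 min⁻¹
(0.04 s⁻¹ steady-state default, ~17 ribosomes); shutdown 0.29 hr⁻¹ with
a 2.5% off fraction (off dwell 312 s = 0.025/0.29 hr); 7.5% stalled
fraction (midpoint of 5–10%); diffusion 0.047 and 1.06×10⁻³ μm²/s;
30 s frames.  The repressive-5'-UTR mixture uses weights 80% silent /
18% weak (0.004 s⁻¹) / 2% strong (0.04 s⁻¹); with flux balance this puts
~53% of all ribosomes on the strong 2% — matching the observed
ribosome-weighted share — and the weak rate was fixed by that constraint.
Scenario durations follow the experimental designs: 30–60 min of
steady-state imaging, ~40 min runoffs, 1–2 hr for switching, 2 hr for
single-ribosome observation at `k_init` $= 3\times10^{-4}$ s⁻¹ (rare,
well-separated events).

Equilibrated scenarios burn in for 1.5 traversal times before
observation; drug scenarios keep a 5-minute pre-drug window for
normalization.  Every dataset carries one truth record per mRNA and a
resolved-config manifest, and identical seeds give identical files.

What the generator does *not* emulate: pixel-level detection and
tracking, photobleaching, mRNA decay, lysosomal background, tRNA-level
codon-specific elongation, and cell-to-cell expression variability beyond
per-mRNA parameter mixtures.  Passing tests therefore demonstrate that
the estimators invert the stated model faithfully at realistic noise and
sampling, not that they are robust to every artifact of real microscopy.

## Numerical choices and problem sizes

* Positions are 1-based codons; 0 means "initiating".  Initiation places
  the ribosome at codon 1; termination is the step out of codon $L$, so a
  deterministic traversal takes exactly $L/k$ seconds.
* The runoff fitter uses Nelder–Mead with `reltol` $10^{-10}$ and
  rejects parameter sets with $v \le 0$ or disordered boundaries by
  penalty; it is exact (to $10^{-3}$) on continuum-generated curves.
* Ties between simultaneous deterministic events resolve drug → injection
  → frame, so a frame coinciding with a drug records the post-drug state.
* The test suite and the reproduction script size their simulations to
  run in minutes on one core: 200–300 mRNAs per runoff ensemble, 200
  mRNA-hours for switching and occupancy laws, 300 tracks per diffusion
  condition, ≥ 100 single-ribosome events.  These sizes put Monte-Carlo
  error comfortably inside each stated tolerance.

## Known limitations

* The uniform-epitope-spacing assumption shifts $\bar c$ slightly if the
  real array is compact; both geometry and $\Delta$ are per-construct
  configuration, not constants.
* The total-runoff-time estimator's small upward bias (last-initiation
  gap) is documented above; the model fit does not share it.
* `classify_stall()` is a heuristic segmentation, not a changepoint
  model with guarantees; its thresholds are exposed as arguments and were
  validated on simulated ensembles only.
* Stalled ribosomes persist for the whole simulation (no rescue or decay
  pathway), and re-initiation after drug washout is not modeled.
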