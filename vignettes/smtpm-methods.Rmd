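---
title: "Methods: tethered particle motion analysis of helicase unwinding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tethered particle motion analysis of helicase unwinding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtpm)
```

## The measurement

In a tethered particle motion (TPM) unwinding experiment a partially duplex
DNA fork is anchored to a coverslip through a digoxigenin-labelled oligo and
carries a streptavidin-coated bead on a biotinylated strand. A ring-shaped
replicative helicase loads on the 5' single-stranded overhang and unwinds
the duplex; each opened base pair converts stiff duplex into two flexible
single strands along the surface-to-bead path, so the restricted Brownian
motion (BM) of the bead grows. The substrate is nicked so that completion of
unwinding releases the bead-labelled strand: the bead disappears, which
timestamps the end of the event.

`smtpm` implements the full chain from substrate geometry to cohort
kinetics:

1. **Substrate model** (`oligo()`, `anneal()`, `composition_at()`) —
   bookkeeping of duplex length, 5' overhang, nicks and single-stranded
   content as a function of base pairs unwound. Only lengths and annealing
   registers matter; sequences are optional and, when present on both
   strands of a fully paired partner, are verified as exact reverse
   complements. Annealing coordinates are 1-based inclusive positions on
   the scaffold. A partner may be only partially paired (its unpaired
   remainder is a single-stranded tail); consequently the constraint linking
   the anneal interval to the oligo length is an inequality, not an
   equality. Per base pair unwound the duplex shrinks by 1 bp and the
   single-stranded tether content grows by 2 nt, which conserves
   `2 * duplex + ss` until bead release.

2. **BM amplitude** (`bm_series()`) — per window of 20 consecutive frames
   (0.66 s at 30 Hz) the per-axis mean-squared displacement is the
   within-window variance of the centroid, and the scalar amplitude is
   `BM = sqrt((MSD_x + MSD_y)/2)`, i.e. the per-axis RMS excursion in nm.
   The divide-by-n (population) variance form is used; windows touching
   unrecorded frames are skipped. Window stride is configurable (the event
   pipeline uses non-overlapping windows, stride = 20 frames, which keeps
   adjacent BM values statistically independent for the changepoint logic).

3. **Drift correction** (`correct_drift()`) — subtraction of a 10 s
   centered moving average per axis. The window is ~15 times the BM
   analysis window, so stage drift is removed while the tether fluctuations
   that carry the signal are preserved (the induced amplitude loss is below
   1%).

4. **Symmetry QC** (`qc_symmetry()`) — a single-tether bead fluctuates
   isotropically; the per-axis MSD ratio over 1000 recorded frames must lie
   in the closed interval [0.9, 1.1]. Note a statistical fact documented
   here deliberately: the ratio of two variance estimates from 1000 frames
   has a relative sd of at least `sqrt(4/1000)` = 6.3% (more when frames
   are correlated), so even perfectly isotropic beads pass at most ~87% of
   the time, and ~70% at the package's default correlation time. The filter
   is therefore conservative: it discards some good beads but rejects 2:1
   anisotropic beads essentially always, which is the behaviour that
   matters for population statistics.

5. **Calibration** (`population_bm()`, `bm_calibration()`) — one BM value
   per bead from a single block of 1000 consecutive frames, summarised by
   the mean and sd of the per-bead values (the unbinned equivalent of a
   single-Gaussian histogram fit), for the intact fork and for a
   mimicked-unwound control; the conversion factor is the BM difference
   over the duplex-length difference derived from the substrate model
   (71 bp), giving 0.0718 nm/bp from the published population means.

6. **Onset detection** (`detect_unwind_start()`) — the first derivative of
   the smoothed BM series is compared against the 95% marginal band
   (empirical 2.5/97.5 percentiles, robust to heavy tails) of its baseline;
   an onset is called at the first run of `persistence` consecutive points
   above the upper bound, then refined by a least-squares changepoint fit.

7. **Velocity estimation** (`unwind_fit()`) — two estimators per molecule:
   the least-squares slope of the increasing BM section divided by the
   calibration factor, and the unwindable duplex length divided by the
   dwell time from onset to maximum BM (bead release). Molecules are
   excluded if they do not qualify (no dissociation preceded by a
   significantly increasing BM, one-sided slope test at level 0.05) or if
   they pause before release.

8. **Ensemble kinetics** — ordinary nonparametric bootstrap of the cohort
   mean (`bootstrap_mean()`), Michaelis–Menten ATP dependence
   (`fit_michaelis_menten()`), NADH-coupled ATPase rates
   (`atpase_rate()`, rate = |dA340/dt| × 9820 µM/min, the constant taken
   as given since it embeds the NADH extinction coefficient and path
   length), gel-shift normalisation (`percent_unwound()`), fold changes and
   tether-disappearance time courses (`disappearance_curve()`).

## The synthetic-data generator

No raw recordings are distributed with this kind of experiment, so every
stage is exercised against `simulate_trajectory()`/`simulate_cohort()`,
which generate bead centroid time series with the statistical structure of
the real recordings and full ground truth.

**Motion model.** The per-axis centroid follows a discretised stationary
mean-reverting (Ornstein–Uhlenbeck) Gaussian process with relaxation time
`tau` whose instantaneous per-axis standard deviation is
`sigma0_bead + c * u(t)`, with `u(t)` the base pairs unwound. Because the
scalar BM of an isotropic process equals its per-axis sd, the expected BM
amplitude is affine in `u` with slope `c` *by construction*: the
calibration and velocity estimators can be validated for correctness
independently of any polymer physics. The mean-reverting form is a modelling
choice — TPM data show correlated bead positions but the true
autocorrelation time of a 200 nm bead on this tether is not known; `tau` is
therefore a free parameter (default 0.05 s) and all analysis windows are
long relative to it.

**Study conditions as defaults.** `tpm_config()` defaults encode the
recording conditions the analysis is meant for: 30 Hz imaging over 600 s; a
~20 s dead time after solution exchange (frames emitted with
`recorded = FALSE` so the time grid stays uniform); baseline amplitude
9.90 nm with a bead-to-bead sd of 2.18 nm (the intact-fork population
values); conversion factor 0.0718 nm/bp over a 90 bp unwindable duplex;
unwinding initiating uniformly 100–300 s after the dead time (the baseline
is flat for >100 s before any onset); a 17% chance that a tether unwinds
during the recording; a pause probability of 8% (pauses are reported at
below 10% of traces) of default duration 30 s, inserted at a uniform
30–80% of the duplex; 10% of beads with a 2:1 axis-variance anisotropy
(normalised to preserve the scalar BM, so the symmetry filter — not the BM
level — must catch them); slow stage drift of 0.05 nm/s along a random
direction. A single seed makes every simulation bit-reproducible.

**What is not emulated.** Hydrodynamic and excluded-volume tether physics,
force dependence (the geometry is nearly force-free), motion blur within a
frame exposure, backstepping, camera vignetting and non-Gaussian
localisation errors. Passing tests on these synthetic data therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every instrumental artefact of real recordings.

**Optional imaging layer.** `render_frames()` draws the bead as a 2-D
Gaussian spot with Poisson shot noise on a constant background;
`localize_centroids()` recovers trajectories by thresholding, connected
component labelling and intensity-weighted centroids, following the nearest
spot to the previous position when several are present. This lets the
pipeline be tested from image stacks (multi-page TIFF) as well as from
centroid tables.

## Numerical and design choices

**Scalar BM definition.** Reported BM values in the nm range are naturally
per-axis RMS amplitudes, so `BM = sqrt((MSD_x + MSD_y)/2)` was adopted; the
calibration factor absorbs the convention, and the simulator is
parameterised consistently.

**Finite-window attenuation and its self-calibration.** The 20-frame
windowed variance of a correlated position process underestimates the
instantaneous variance (by `(n-1)/n` minus a correlation term — about 7% in
amplitude at `tau` = 0.05 s). A long block (1000 frames) does not. The
slope estimator would therefore systematically read low relative to the
dwell estimator. `unwind_fit()` corrects this *from the data*: the ratio of
the mean short-window BM to the long-block BM over the same pre-onset
frames estimates the attenuation without knowing `tau`, and the fitted
slope is divided by it (clamped to [0.5, 1.5]; disabled with
`window_debias = FALSE`). After the correction the two estimators agree at
the percent level on simulated cohorts, mirroring the expectation that both
methods measure the same velocity.

**Onset detection internals.** The BM series is smoothed with a 15-window
running mean and differentiated by a central difference with an 8-window
half-gap; the baseline band is seeded from the first 100 s of windows and
iteratively re-restricted to the data before the candidate onset (at least
50 windows are always retained). The persistence requirement is 15
consecutive out-of-band points: out-of-band excursions of a smoothed
derivative cluster over roughly the smoothing span, so shorter requirements
(10–12 points) produce per-trace false-positive rates in the tens of
percent, while 15 points keeps the rate at ~2–3% — below the 5% target —
and still catches the ~13-window ramp of the fastest cohorts, whose traces
end at bead release. The trigger time then carries a filter delay of
several windows, so the reported onset is the breakpoint of a least-squares
changepoint fit around the trigger: a continuous flat-then-ramp hinge by
default, or a discontinuous flat-then-line model when the fitted jump
exceeds four residual standard deviations *and* halves the residual sum of
squares (i.e. the rise is a genuine step, which the continuous hinge cannot
represent). The slope fit then starts half a window after the onset, since
windows straddling the onset mix baseline and ramp frames.

**Dwell endpoint.** The bead disappears immediately after the last recorded
frame, so `t_max` is that frame's time rather than the center of the last
analysis window; using the window center shortens every dwell by a third of
a second, which is material for the fastest (~8.6 s) events.

**Pause flagging.** A pause is a span of at least 15 s between onset and
release whose rolling OLS slope is within a tolerance of zero (default 30%
of the overall event slope) while the BM sits at least 1 nm below the final
level. Paused molecules are flagged and excluded from velocity statistics.

**Michaelis–Menten fit.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), initialised at `Vmax = max(v)`, `Km = median(S)`,
both bounded below at 1e-12. Perfectly saturating data drive `Km` to its
bound with `Vmax` at the mean velocity rather than failing. With exactly
two distinct concentrations the hyperbola is inverted algebraically. The
package does not assert a refit of published condition means against the
published `(Vmax, Km)` because the original fit's weighting is not
documented; the self-consistency of the fitter is established on exact
model data instead.

**Disappearance curve.** The default saturating-exponential model is
`y = y0 + A (1 - exp(-x/t))` with a free amplitude; a variant with the
amplitude tied to `1/t` is available (`model = "verbatim"`) but its
prefactor is dimensionally inconsistent with a percent axis, so the
amplitude form is the default and the one under test.

**Degenerate inputs.** Constant A340 traces give rate 0 without a warning
(a rising trace warns and reports 0); identical per-bead BM values flag the
population as degenerate; a cohort with no losses yields an empty
disappearance curve with the fit skipped; all-identical velocities give a
zero bootstrap sd.

## Problem sizes

The test suite and examples run cohorts of 15 molecules per condition at
the three study velocities (3.58, 7.44, 10.52 bp/s), calibration cohorts of
66 and 57 beads with 1000-frame blocks, 200 stationary traces for the
false-positive rate, and 10^4 bootstrap resamples — sizes chosen to match
the scale of the original experiments (10–18 molecules per cohort) while
keeping Monte-Carlo error small relative to the tolerances under test.

## Known limitations

- The bead-motion model is a single-timescale Gaussian process; real TPM
  records show additional slow modes (tether-surface interactions,
  transient sticking) that the QC filters are meant to remove but that are
  not simulated.
- The calibration's published uncertainty cannot be reproduced by error
  propagation from the published population spreads; the package reports
  the central conversion factor and leaves uncertainty propagation to the
  user's bootstrap.
- Onset detection assumes a single onset per trace; multi-phase events
  other than a single pause are not modelled.
- The symmetry filter's pass rate on good beads is limited by
  variance-ratio statistics (see above); cohort sizes should budget for
  ~30% attrition of genuine single tethers.
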