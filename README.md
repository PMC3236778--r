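# smtpm — single-molecule TPM analysis of helicase DNA unwinding

`smtpm` analyses single-molecule tethered particle motion (smTPM) recordings
of replicative helicase DNA unwinding, for researchers who measure unwinding
kinetics of ring-shaped (DnaB/DnaC-family) helicases in nearly force-free
conditions. A partially duplex fork substrate is anchored to a coverslip and
carries a bead on its distal end; as the helicase converts duplex DNA to
more flexible single strands, the restricted Brownian motion (BM) of the
bead grows until the bead-labelled strand dissociates and the bead
disappears. The package turns bead centroid trajectories into per-molecule
unwinding velocities and cohort-level kinetics, and ships a simulator that
generates such recordings with known ground truth.

## The measurement model

The per-window BM amplitude is computed from the centroid time series as

    BM = sqrt((MSD_x + MSD_y) / 2),   MSD = <x^2> - <x>^2

over 20 consecutive frames (0.66 s at 30 Hz), after drift correction by
subtraction of a 10 s centered moving average. Beads whose MSD_x/MSD_y ratio
falls outside [0.9, 1.1] are discarded (multiple tethers / stuck beads).
The BM amplitude is affine in the number of unwound base pairs `u`:

    BM(t) = BM_0 + c * u(t)

with conversion factor `c` calibrated from the mean BM of the intact fork
substrate (108 bp duplex, 37 nt 5' overhang) and of a mimicked-unwound
control (37 bp duplex, 71 nt single-stranded bead strand):
c = (15.00 − 9.90) nm / 71 bp = 0.0718 nm/bp.

Per molecule, the unwinding onset is the changepoint where the first
derivative of the BM time course leaves its baseline 95% band persistently;
the velocity is estimated twice: from the least-squares slope of the
increasing BM section (`v = slope / c`) and from the dwell time needed to
unwind the 90 bp duplex (`v = 90 / (t_max − t_start)`). Molecules that pause
before release, or that detach without an increasing BM phase, are excluded.
Cohort statistics use the ordinary nonparametric bootstrap of the mean;
the ATP dependence is fitted with Michaelis–Menten kinetics
`v = Vmax * S / (Km + S)`; ensemble assays (NADH-coupled ATPase rates,
gel-shift %unwound normalisation, tether-disappearance time courses) are
included.

## Worked example

```r
library(smtpm)

fork_ac90()
#> <substrate_spec> scaffold A (145 nt) + 2 partner(s)
#>   duplex: 108 bp | 5' overhang: 37 nt | nicks: 1 | single-stranded: 37 nt | unwindable: 90 bp

# BM-to-base-pair calibration from the two substrate populations
bm_calibration(9.90, 15.00, fork_ac90()$duplex_bp - mimic_unwound()$duplex_bp)
#> <bm_calibration> c = (15 - 9.9) nm / 71 bp = 0.0718 nm/bp

# one synthetic unwinding recording, analysed end to end
cfg <- tpm_config(v_bp_s = 3.58, p_unwind = 1, seed = 42)
tr  <- simulate_trajectory(cfg, unwind = TRUE)
fit <- unwind_fit(bm_series(correct_drift(tr), stride = 20))
summary(fit)
#> Single-molecule unwinding fit for bead-1
#>   qualifies:         TRUE
#>   onset detected:    TRUE
#>   t_start:           249.65 s
#>   t_max:             273.47 s
#>   baseline BM:       8.004 nm
#>   BM slope:          0.2919 nm/s
#>   v (slope method):  4.368 bp/s
#>   v (dwell method):  3.779 bp/s
#>   paused:            FALSE
#>   calibration:       0.0718 nm/bp over 90 bp

# a cohort of 15 molecules and the bootstrap of its mean velocity
co <- simulate_cohort(tpm_config(v_bp_s = 3.58, p_unwind = 1, seed = 7), 15)
v  <- cohort_velocities(unwind_events(co))
bootstrap_mean(v, resamples = 100, seed = 1)
#> <bootstrap_mean> 100 resamples of n = 15: mean 4.122 +/- 0.198 bp/s (sample 4.134 +/- 0.748)
```

The per-molecule summary reads: this bead's BM began rising at ~250 s and
the bead disappeared at ~273 s; the slope of the rise converts to
4.37 bp/s and the dwell time over the 90 bp duplex to 3.78 bp/s (the two
estimators agree within the single-molecule scatter; this trace was
simulated at 3.58 bp/s). The bootstrap line gives the cohort mean velocity
with its resampling spread.

A full pipeline run (simulation → BM processing → event detection → cohort
kinetics) is driven by one configuration:

```r
run_pipeline(list(seed = 1, outdir = "out",
  simulate = list(n_per_cohort = 15,
                  cohorts = list(list(label = "wt",  v_bp_s = 3.58, p_unwind = 1),
                                 list(label = "mut", v_bp_s = 7.44, p_unwind = 1)))))
```

which writes trajectory/BM/event tables, a kinetics report
(condition, n, mean ± sd, bootstrap mean ± sd, fold change) and a manifest
with the seed and file checksums.

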