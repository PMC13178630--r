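# optoret

Phase-based optoretinography (ORG) analysis for adaptive-optics OCT
recordings of cone photoreceptors, with a full synthetic-data generator
and test–retest repeatability statistics.

## The problem

Phase-based ORG measures the light-evoked elongation of the cone outer
segment from the optical phase difference between its two bounding
reflections (the inner–outer segment junction, ISOS, and the cone outer
segment tip, COST). The elongation is a few hundred nanometers — far
below the system's axial resolution, but readily resolved in phase. The
usefulness of the technique for detecting experimental or disease-related
change hinges on how repeatable the derived response parameters are,
both for single cones and for responses pooled over a field of view.

`optoret` implements, for users of cellular-resolution ORG systems and
for method developers without access to raw in vivo data:

* **Phase extraction.** The conjugate-product estimator
  `Δφ(t) = ∠((1/m) Σᵢ Aᵢ Bᵢ*)` over the m brightest A-scans of each cone
  (piston phase from axial eye motion cancels exactly), circular-mean
  baseline referencing, temporal unwrapping with masked-gap handling, and
  scaling `ΔOPL = Δφ·λ/(4π)` to nm.
* **Response-model fitting.** The overdamped-oscillator curve
  `ΔOPL_fit(t) = A₁(e^(−τ_b t) − e^(−τ_a t))` with `τ_a > τ_b > 0` (rates
  in s⁻¹), fit by box-constrained multi-start Levenberg–Marquardt;
  RMS-error filtering (30 nm default, 20/40 nm sensitivity); the three
  figures of merit: ΔOPL_max (mean of the five highest samples),
  ΔOPL_fitting,max (closed-form fitted peak) and τ_a.
* **Repeatability statistics.** Per-cone CoV with RMS and mean
  aggregation, ICC(2,1) with McGraw–Wong F-based confidence intervals,
  and pooled per-trial means/dispersions with their CoVs.
* **Synthetic data.** Complex two-layer cone signals with parameter
  heterogeneity, an S-cone-like weak subpopulation, SNR-dependent phase
  noise, per-volume piston, baseline drift and eye-motion dropout —
  every downstream stage is testable without any recording.

## Worked example

```r
library(optoret)

pop <- org_pop_config(n_cones = 100)          # in vivo-scale cohort
ds  <- simulate_dataset(pop, org_acq_config(), n_trials = 3, seed = 7)
ex  <- extract_traces(ds)                     # complex signals -> dOPL(t)
ft  <- fit_cohort(ex$traces)                  # model fits + ORG parameters
fl  <- filter_by_rms(ft, threshold_nm = 30)
rep <- repeatability_report(fl$retained)
print(rep)
```

```
ORG test-retest repeatability report
  dopl_max       CoV(rms)  6.41%  CoV(mean)  5.65%  ICC 0.959 [0.944, 0.971]  pooled CoV(means)  0.93%  CoV(SDs)  1.83%  (n=97 cones)
  dopl_fit_max   CoV(rms)  6.42%  CoV(mean)  5.66%  ICC 0.959 [0.943, 0.971]  pooled CoV(means)  0.96%  CoV(SDs)  1.81%  (n=97 cones)
  tau_a          CoV(rms) 14.21%  CoV(mean) 10.00%  ICC 0.724 [0.640, 0.796]  pooled CoV(means)  1.92%  CoV(SDs)  7.90%  (n=97 cones)
```

Reading the report: repeated measurements of the same cone scatter by
~6% in amplitude (ΔOPL_max, ΔOPL_fitting,max) but ~14% in elongation
rate (τ_a) — the rate is the noise-sensitive parameter. Pooling the ~100
cones of the field of view before comparing trials collapses the
variation to ~1–2% (`pooled CoV(means)`), and the inter-cone dispersion
itself is stable across trials (`CoV(SDs)`), indicating that the spread
of responses across the mosaic is physiological diversity rather than
measurement noise.

`run_org_pipeline(out_dir, ...)` runs the same chain end to end and
persists traces, fit tables, an exclusion log and a JSON report (with
seed and configuration embedded); `inst/scripts/org-pipeline.R` wraps it
for the shell. A no-stimulus control (`stimulus_on = FALSE`) reproduces
the ~2.5 nm RMS noise floor.

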