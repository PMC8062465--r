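# birn

Quantification of nanoparticle internalisation with binary ratiometric
nanoreporters (BiRN).

## The problem

Biodistribution assays tell you how much nanomedicine a tumour
accumulated (%ID/g), but not how much of it cells actually took up —
and intracellular exposure, not bulk accumulation, is what drives the
response to endosomally activated nanotherapeutics. A BiRN probe solves
this optically: it carries two fluorescence modules on one pH-sensitive
micelle. The *OFF-ON* module is quenched while the micelle is intact
(blood pH 7.4, tumour interstitium pH ~6.6–6.9) and switches on more
than 100-fold when the micelle dissociates below its transition pH
(~6.3), which happens within minutes of endocytosis in the early
endosome (pH ~6.0). The *always-ON* module reports total probe amount.
Their intensity ratio (O/A) is therefore a near-binary flag for
"inside a cell".

This package implements the full analysis around that readout, for
imaging scientists and nanomedicine groups:

- **Probe optics** — a two-state model per module,
  `F(pH) = c [f_min + (f_max − f_min) θ(pH)]` with
  `θ(pH) = 1 / (1 + 10^{n_H (pH − pH_t)})` and
  `n_H = log10(81) / ΔpH_10–90%`; titration fitting recovers the
  characterization triple (pH_t, ΔpH_10–90%, R_F = F_max/F_min).
- **Calibration** — the mixture standards
  `Ratio(f) = [(1−f) F_O(7.4) + f F_O(5.4)] / [(1−f) F_A(7.4) + f F_A(5.4)]`
  give a concentration-independent line of O/A against turn-ON
  (endocytosis) percentage; curves are gated at r ≥ 0.95 and inverted
  to estimate the endocytosed fraction.
- **Ratio imaging** — background subtraction, validity gating,
  binarization at the normalized midpoint, puncta counting, ROI-level
  endocytosis percentages and tumour-to-normal contrast.
- **Kinetics** — mono-exponential internalization
  (`plateau (1 − e^{−kt})`, half-time ln 2 / k), first-order drug
  release, four-parameter logistic dose-response (IC50) and potency
  shifts.
- **Dosimetry & stratification** — fluorometry standard curves to
  %ID/g, intracellular dose = accumulation × endocytosis fraction,
  median-split or tercile stratification, exposure–response correlation
  and Welch group comparison.
- **Synthetic data** — seeded generators for titrations, calibration
  plates, dual-channel tissue scenes (compartmental pH, Gaussian PSF,
  Poisson + read noise, ground-truth labels), pulse-chase courses and
  subject cohorts, so the whole pipeline runs and is testable with no
  instrument.

## Worked example

```r
library(birn)

probe <- birn_probe()   # pH_t 6.28, ΔpH 0.21, R_F 111, flat always-ON
round(oa_response(probe, c(7.4, 6.6, 6.28, 6.0, 5.4)), 4)
#> [1] 0.0000 0.0012 0.5000 0.9972 1.0000
```

The normalized O/A response is ~0 at interstitial pH 6.6 and ~1 at
endosomal pH 6.0 — the binary contract the probe is built on.

```r
# characterize the probe from a (here simulated) titration
tit <- gen_titration(probe, ph = seq(5.0, 7.4, 0.1), noise = 0.03,
                     replicates = 3, seed = 11)
fit_titration(tit, "off_on")
#> <birn_titration_fit> channel off_on (off_on), n = 75
#>   pH_t = 6.279, width(10-90%) = 0.215, R_F = 113.8, R^2 = 0.9974

# calibration plate -> O/A vs turn-ON line
curve <- build_calibration(gen_calibration_plate(probe, noise = 0.03,
                                                 seed = 11))
curve
#> <birn_calibration> tissue tumour: ratio = 7.6425 + 983.8788 * f_on,
#>   r = 0.9986 (n = 24)

# quantify a tissue image (true internalized fraction 0.155)
img <- gen_tissue_image(tissue_scene_config(f_target = 0.155), probe,
                        seed = 11)
roi <- matrix(TRUE, 96, 96)
region_endocytosis(img, roi, curve, background = 0, min_denominator = 1)
#>   f_hat ratio n_pixels out_of_range
#> 1 0.162  167.     9216 FALSE
```

The ROI-level estimate (16.2%) recovers the simulated truth within the
noise of a single scene. Combined with a measured accumulation of
1.74 %ID/g, `internalized_dose(1.74, 0.162)` gives 0.28 %ID/g of
intracellular exposure (the probe's own study conditions yield
0.27 %ID/g at an endocytosis fraction of 15.5%).

```r
# internalization kinetics and cohort stratification
fit_internalization(gen_pulse_chase(t_half = 11.89,
                                    timepoints = seq(0, 60, 5),
                                    noise = 0.05, seed = 11))
#> <birn_kinetics_fit> internalization: t_half = 11.899 min
#>   (k = 0.05825 /min), plateau = 1.000, R^2 = 0.9871

cohort <- stratify(gen_cohort(n_subjects = 24, seed = 11))
compare_groups(cohort)           # high vs low intracellular dose
#>   difference 15.8, t = 3.65, p = 0.0018
tidy(correlate(cohort$internalized_pct_id_g, cohort$outcome))
#>   r = 0.819, p = 9.7e-07
```

High-internalization subjects respond better, and intracellular dose
correlates with outcome — the stratification logic the reporter
enables.

Every fitted object has `tidy()`, `glance()` and `autoplot()` methods;
file interfaces cover CSV tables (percent on disk, fractions in
memory), probe YAML, calibration JSON and dual-channel TIFF.

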