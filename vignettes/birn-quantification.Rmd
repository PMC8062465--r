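---
title: "Quantifying nanoparticle internalisation with a binary ratiometric nanoreporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoparticle internalisation with a binary ratiometric nanoreporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birn)
```

## The measurement problem

Bulk biodistribution (fluorometry, mass spectrometry, radioactivity)
reports how much nanomedicine a tumour holds, in percent injected dose
per gram (%ID/g), but cannot tell probe in the vasculature or
interstitium apart from probe that cells have endocytosed. A binary
ratiometric nanoreporter (BiRN) makes that distinction optically. It is
a pH-sensitive micelle carrying two fluorescence modules: an OFF-ON
module, quenched while the micelle is assembled and >100-fold brighter
once the micelle dissociates below its transition pH, and an always-ON
module whose brightness is pH-independent and which serves as an
internal standard for the amount of probe. The transition pH (~6.3)
sits between tumour interstitial pH (6.6–6.9) and early-endosomal pH
(~6.0), so the OFF-ON over always-ON intensity ratio (O/A) behaves as
a near-binary flag for internalisation.

This vignette describes the models the package implements, the
conventions and tunable parameters, what the synthetic-data generators
emulate, and the package's known limitations.

## The two-state optical model

Each module is modelled phenomenologically as a two-state (micelle vs
unimer) system:

$$F(\mathrm{pH}) = c\,\big[f_\min + (f_\max - f_\min)\,
\theta(\mathrm{pH})\big], \qquad
\theta(\mathrm{pH}) = \frac{1}{1 + 10^{\,n_H(\mathrm{pH} - \mathrm{pH}_t)}}$$

with $c$ the probe concentration. No mechanistic equation for the
cooperative micelle transition is asserted; any sigmoid family
reproducing the characterization triple — transition pH
$\mathrm{pH}_t$, 10–90% width $\Delta\mathrm{pH}_{10\text{–}90\%}$,
and activation ratio $R_F = f_\max/f_\min$ — would serve, and the
base-10 logistic is the standard choice for ultra-pH-sensitive
micelles. We parameterize steepness directly by the width, through the
exact identity $n_H \cdot \Delta\mathrm{pH}_{10\text{–}90\%} =
\log_{10} 81$, because the width is what titrations report.

The default probe (`birn_probe()`) carries the characterized
near-infra-red parameter set: $\mathrm{pH}_t = 6.28$, width 0.21 pH
units, $R_F = 111$, with a 9:1 OFF-ON to always-ON molar ratio. The
always-ON module defaults to exactly flat ($R_F = 1$); a measured
flatness anywhere in the accepted 0.9–1.1 band can be supplied instead,
at the cost of a (tiny) curvature in the calibration line.

The normalized O/A response anchors at the two reference buffers used
to prepare standards — pH 7.4 (micelle state, response 0) and pH 5.4
(unimer state, response 1):

$$\mathrm{OA}(\mathrm{pH}) = \frac{\mathrm{ratio}(\mathrm{pH}) -
\mathrm{ratio}(7.4)}{\mathrm{ratio}(5.4) - \mathrm{ratio}(7.4)}.$$

Anchoring at buffer endpoints rather than fitted asymptotes is a
deliberate convention: the endpoints are physical samples every
experiment includes, whereas asymptotes depend on the fitted family.
With the default probe the response is 0.0012 at pH 6.6 and 0.9972 at
pH 6.0 — numerically binary over the biologically relevant range.

```{r oa}
probe <- birn_probe()
round(oa_response(probe, c(7.4, 6.78, 6.6, 6.28, 6.0, 5.4)), 4)
```

### Titration fitting

`fit_titration()` fits the four-parameter model by nonlinear least
squares jointly over all replicate points, unweighted (the noise model
of a plate reader is unknown; unweighted is the neutral default).
Starting values are taken from the data (half-range crossing for
$\mathrm{pH}_t$, observed extremes for the asymptotes, width 0.2);
parameter tolerance is 1e-10 with at most 10^4 evaluations. Two
degeneracy gates protect the fit: flat data (per-pH mean max/min
< 1.05) are rejected for an OFF-ON channel and summarized as a
flatness verdict for an always-ON channel; and both plateaus must be
represented beyond the extreme grid points (interior points below 25%
and above 75% of the intensity range), otherwise the asymptotes — and
hence $R_F$ — are extrapolation.

## The calibration curve and its inversion

Standards mix probe at the two reference pH values so that a fraction
`f_on` is in the unimer (ON) state:

$$\mathrm{Ratio}(f) = \frac{(1-f)\,F_O(7.4) + f\,F_O(5.4)}
{(1-f)\,F_A(7.4) + f\,F_A(5.4)}.$$

When the always-ON module is pH-flat the denominator is constant and
the ratio is exactly linear in $f$; because numerator and denominator
both scale with concentration, the line is concentration-independent —
the property that lets one curve quantify tissues with unknown local
probe concentrations. `build_calibration()` fits ordinary least
squares on per-replicate wells (no pre-averaging; per-level means are
reported as diagnostics), keeps the intercept free (no constraint
through the f = 0 standard is asserted), and enforces the acceptance
gate r ≥ 0.95 — a curve below the gate raises a validation error
carrying the fitted values. Tissue identity is part of the curve:
inversion against a mismatched tissue requires `force = TRUE`, because
homogenate optics differ between organs and each tissue gets its own
standards. Whether quantification should use per-animal or shared
curves is not determined by the assay; the package default is one
shared curve per tissue.

`invert_calibration()` maps an observed ratio to
$\hat f = (\mathrm{ratio} - \mathrm{intercept})/\mathrm{slope}$,
clipped to [0, 1] with an `out_of_range` flag rather than silent
clamping. Fractions live in [0, 1] everywhere in memory; file
interfaces speak percent, which avoids hundred-fold unit slips.

## Ratio imaging conventions

`ratio_image()` background-subtracts both channels, clamps negative
numerators to zero, and divides only where the subtracted always-ON
denominator reaches `min_denominator` — a ratio where no probe is
present is noise amplification, not signal. For read-noise-limited
images the classic gate is three times the background standard
deviation; for photon-counting images `suggest_min_denominator()`
solves $a = k\sqrt{a + \sigma_{\mathrm{read}}^2}$ so the gate also
covers the denominator's own shot noise (12 counts at
$\sigma_{\mathrm{read}} = 2$, $k = 3$). Wet-lab ImageJ recipes for
ratio images (background handling, LUT thresholds) vary and are rarely
reported in full; this gate plus the midpoint threshold below is this
package's declared convention.

`binarize_ratio()` normalizes the ratio between the calibration
endpoints (f = 0 and f = 1; probe reference values when no curve is
supplied) and thresholds at 0.5 of that scale. Because the pH response
is near-binary, the midpoint is maximally separating; the threshold is
exposed for sensitivity analyses. The output contains only 0 and 1.

`count_puncta()` labels connected components (8-connectivity by
default, 4 available) with deterministic row-major numbering, filters
by minimum area (default 4 px), and reports 0-based (row, col)
centroids. `region_endocytosis()` uses the region-mean convention —
the ROI ratio is mean(O)/mean(A), not the mean of per-pixel ratios,
which is noise-biased — and inverts it through the calibration curve.
Rasters are row-major matrices, coordinates 0-based; multiplying both
channels by any positive gain leaves ratio, mask and region estimates
unchanged once background is removed.

## Kinetics and dose-response

Internalization pulse-chase data are fitted with the minimal
saturating model consistent with a single reported half-time,
$v(t) = \mathrm{plateau}\,(1 - e^{-kt})$, with
$t_{1/2} = \ln 2 / k$. Reported half-times in the field may come from
such a fit or from an empirical 50% crossing, so both readouts
are returned (`t_half` and `t_half_empirical`); the fit is the
default. The plateau and rate are jointly identifiable only when
sampling spans at least two half-times; shorter spans warn
(`birn_warning_identifiability`), and curvature-free data warn of
degeneracy rather than failing silently. Internalization is recorded
in minutes and release in hours, and the unit travels with the
`time_course` object so the two cannot be mixed.

Drug release is summarized by a first-order model,
$1 - 2^{-t/t_{1/2}}$: with a 4.52 h half-time, 97.5% of drug is
released by 24 h, and the survival fraction halves exactly every
half-time.

Dose-response curves are four-parameter logistics in log10
concentration with top bounded at 1.05 and bottom at −0.05; by
construction the fitted viability at the IC50 is the midpoint of top
and bottom. `potency_decrease()` expresses an IC50 shift as
$100\,(1 - \mathrm{IC50}_{\mathrm{ref}}/\mathrm{IC50}_{\mathrm{test}})$
— blocking endocytosis (IC50 1.25 µM → 12.87 µM) is a 90.3% potency
loss, the link between internalisation and efficacy at the cellular
level.

## Dosimetry and stratification

Fluorometry standard curves (intensity vs spiked concentration,
r ≥ 0.95) convert homogenate readings to concentration;
$\%\mathrm{ID/g} = 100 \cdot c \cdot V_{\mathrm{homogenate}} /
(\mathrm{dose} \cdot m_{\mathrm{tissue}})$. Intracellular exposure is
operationalized as accumulation × endocytosis fraction, in %ID/g; the
conservation invariant internalized ≤ accumulated is checked on every
cohort load. (On the imaging path, the OFF-ON channel ROI intensity is
an accepted surrogate column; the product is canonical.)

Stratification is deterministic: median split sends ties at the median
to the low group (low group size ⌈n/2⌉), terciles split by rank with
remainders to the lower groups, and residual ties break by subject
order. Exposure–response uses simple linear regression with Pearson r
and a two-sided p for slope ≠ 0; group outcomes are compared by
Welch's t-test, two-sided, with no multiple-testing correction — the
analysis tests one predefined contrast; adjust downstream if several
outcomes are screened. Outcomes are tumour-inhibition percent
internally (higher = better); relative tumour volume must be converted
explicitly.

## What the synthetic generators emulate

Every generator is a pure function of its arguments and a single
integer seed, split internally into named substreams (geometry,
placement, pH, per-channel noise) so adding one noise source never
shifts another's draws.

- **Titrations** follow the wet-lab protocol by default (pH 5.4–7.2 in
  0.2 steps, 100 µg/mL) with 5% multiplicative Gaussian noise;
  recovery studies in the tests use a denser grid (5.0–7.4, step 0.1,
  3 replicates, 3% noise) to pin the asymptotes.
- **Calibration plates** use the standard turn-ON grid (0, 5, 10, 20,
  30, 40, 50, 100%) at one or more concentrations with independent
  per-channel noise.
- **Tissue scenes** place probe mass in three compartments: vessels
  (blood pH 7.4), extracellular space (pH ~ N(6.78, 0.20) truncated
  above the probe's transition pH — the validity condition of the
  whole readout, asserted, not merely sampled), and endosomal puncta.
  Endosomal pH is drawn around 6.0 (sd 0.2) truncated at the probe's
  99%-ON pH (~6.06 for the default probe): the generator models the
  reporter's binary premise that internalized probe has fully
  switched; draws lingering near the transition would represent
  probe in compartments the reporter does not claim to count, and
  would make the "fully internalized region reads 1" limit false by
  construction. Rendering is optical model → Gaussian PSF (σ = 1 px)
  → Poisson shot noise → Gaussian read noise (sd 2 counts), with the
  exposure scaled so probe-bearing pixels average 200 always-ON
  counts. Ground-truth compartment labels and the realized
  internalized mass fraction accompany every scene.
- **Pulse-chase** courses are mono-exponential with 5% multiplicative
  noise, clamped to [0, 1].
- **Cohorts** draw accumulation log-normal (meanlog log 1.2, sdlog
  0.4) clipped to the observed 0.50–2.56 %ID/g range, and endocytosis
  fraction Beta(2, 2) scaled to the observed 10.7–28.2% range,
  independently — accumulation and internalization efficiency are
  decoupled, which is exactly why bulk accumulation under-predicts
  response. Outcome follows
  $a + b\,\log(\mathrm{dose}) + \mathcal N(0, \sigma)$ with defaults
  (80, 25, 7.5) chosen so a 24-subject cohort shows an
  exposure–outcome correlation of ~0.8 in the median seed — a
  realistic effect size, not a reproduction of any particular cohort.

What the generators do **not** model: depth-dependent attenuation and
scattering (in vivo images are flat-fielded by assumption), channel
misregistration, autofluorescence structure, vascular network
morphology, multi-compartment endosome maturation, and pharmacokinetic
time courses. Passing tests therefore demonstrate that the estimators
are correct and calibrated under the stated optical and statistical
model — not that they are robust to every artefact of intravital
microscopy.

## Numerical choices and degenerate inputs

- Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with parameter
  tolerance 1e-10; the 4PL fit retries over a small ladder of starting
  midpoints and falls back to the bounded port algorithm, because an
  exactly-interpolating solution can fail the optimizer's internal
  rank check.
- Problem sizes in the tests and acceptance script are desk-scale by
  design: 100-seed ensembles for recovery medians, 96×96 scenes for
  imaging recovery, 24-subject cohorts — large enough for stable
  medians, small enough to run anywhere.
- Degenerate inputs fail loudly with classed conditions
  (`birn_error_parameter`, `_precondition`, `_degenerate`,
  `_validation`): flat titrations, non-spanning designs, all-invalid
  ratio images, zero-variance correlations, all-equal stratification
  keys, calibration below the r gate.
- Ratios at zero denominators are never formed; negative
  background-subtracted numerators clamp to zero; 16-bit image output
  clips at the detector ceiling rather than wrapping.

## Limitations

The package quantifies internalisation as the probe defines it: probe
below its transition pH. Probe recycled back to the surface, in late
compartments with still-lower pH, or extracellular probe in unusually
acidic niches would all be misread to the extent the binary premise
fails — the extracellular-pH-above-transition condition should be
verified (e.g. by microelectrode) for each tumour model before trusting
absolute percentages. Image-based estimates use the region-mean
convention and carry no cell-level segmentation; puncta counts are a
proxy for endocytic events, not a vesicle census. The exposure–response
stage is deliberately simple (linear regression, Welch tests on a
predefined split) and does not replace longitudinal tumour-growth
modelling.
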