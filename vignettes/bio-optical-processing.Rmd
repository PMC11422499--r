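---
title: "Bio-optical processing of phytoplankton culture measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bio-optical processing of phytoplankton culture measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoptics)
library(dplyr)
```

## What this package computes

phytoptics turns raw flow-through optical instrument streams and
filter-pad spectrophotometer scans from phytoplankton cultures into the
products that make up an optical "fingerprint" of a strain: corrected
hyperspectral absorption and attenuation, particulate backscattering by
two independent routes, particle size distributions, the
phytoplankton/detrital absorption partition, and pigment ratios with
propagated uncertainty. Because the raw streams of such experiments are
rarely archived, a first-class synthetic-data module renders matched
pure-water, unfiltered and 0.2-µm-filtered instrument records from a
known ground truth, so that every processing stage can be validated by
parameter recovery rather than by eye.

## Hyperspectral absorption and attenuation

A reflecting-tube absorption/attenuation meter reports a measured
absorption $a_m(\lambda)$ and beam attenuation $c_m(\lambda)$ over
400–730 nm. Processing follows five stages, in this order:

1. **Pure-water baseline.** The median spectrum of the same-day
   ultrapure-water record is subtracted from every time step of the
   sample records. The median, rather than the mean, is the only time
   reduction used anywhere in the package: it is invariant to any strict
   minority of records being contaminated by bubble spikes, which is
   exactly the failure mode of flow-through plumbing.
2. **Temperature/salinity correction.** Pure water absorbs measurably
   differently as temperature and salinity change, notably near the
   740 nm water band. With per-wavelength coefficients $\Psi_T$,
   $\Psi_{Sa}$, $\Psi_{Sc}$ the correction is
   $a_t = a_m - (T_m - T_r)\Psi_T + S_m \Psi_{Sa}$ (attenuation
   analogous). Coefficient tables published for these instruments exist
   with both sign conventions for the salinity term, so the convention
   is an explicit argument (`sign_convention`), defaulting to the form
   above; with the shipped synthetic table's negative $\Psi_{Sa}$ the
   net effect is a subtraction. The correction is affine in the
   measurement, so it commutes with the median reduction; we correct the
   full time series and reduce last, which also keeps the option of
   time-resolved QC open.
3. **Median reduction** per wavelength; an optional rolling-median/MAD
   despiker (`despike_timeseries()`) is available but off by default —
   the plain median already realises the robustness the protocol asks
   for.
4. **Residual-scatter correction** of the absorption tube. The tube
   fails to collect a fraction of scattered light, inflating $a$.
   Assuming negligible true absorption at a red reference wavelength
   ($\lambda_{ref} = 715$ nm by default) and an error proportional to
   scattering $c_t - a_t$,
   $$a_{sc}(\lambda) = a_t(\lambda) -
     \frac{a_t(\lambda_{ref})}{c_t(\lambda_{ref}) - a_t(\lambda_{ref})}
     \,\bigl(c_t(\lambda) - a_t(\lambda)\bigr),$$
   which forces $a_{sc}(\lambda_{ref}) = 0$ exactly. A variant that
   omits the leading $a_t(\lambda)$ term circulates in print; it does
   not null the reference wavelength and is provided only behind
   `method = "as_printed"` for auditability. The correction is applied
   to the unfiltered stream only: a 0.2-µm-filtered stream scatters
   essentially nothing, so the proportionality factor there is a ratio
   of noise to noise, and the filtered absorption is used directly as
   the dissolved fraction $a_g$.
5. **Partition and regridding.** $a_p = a_{sc} - a_g$,
   $c_p = c_t - c_g$, $b_p = c_p - a_p$, followed by shape-preserving
   piecewise-cubic-Hermite (PCHIP) interpolation of all products onto a
   uniform 400–730 nm, 2.5 nm grid. Negative product values are
   *retained* and flagged in the QC table: clamping them would silently
   break the conservation identities $a_p + a_g = a_{sc}$ and
   $c_p + c_g = c_t$ that hold by construction.

PCHIP was chosen over a natural cubic spline because it cannot
overshoot between nodes (no spurious negative absorption between
samples); the price is that it flattens genuine extrema slightly —
about $3\times10^{-3}$ of peak amplitude for a 15 nm-wide Gaussian band
sampled every 5 nm. The tests bound this against an independent
monotone-Hermite implementation rather than pretending the error is
zero. No extrapolation is ever performed beyond measured wavelengths.

The reference temperature $T_r$ is a property of the coefficient table
(carried in its `# t_r:` header), not of the run. The coefficient table
shipped with the package is **synthetic** — smooth, plausibly shaped,
clearly labelled — because real coefficient tables are instrument
deliverables; users must supply their own for real data.

## Backscattering

Raw counts from a scattering sensor become a volume scattering function
via the factory calibration, $\beta_t = SF(\theta,\lambda)\,(V - DO)$,
are compensated for absorption along the source–detector path,
$\beta = \beta_t\,e^{L\,a(\lambda)}$ with $L$ the per-channel optical
path length in metres, and the dissolved VSF measured on the filtered
loop is subtracted channel-by-channel in place of a computational
pure-seawater correction. Two routes then give the particulate
backscattering coefficient $b_{bp}$:

* **Single-angle (chi) route** (nine-wavelength sensor at 124°,
  six-wavelength sensor at 141°):
  $b_{bp}(\lambda) = 2\pi\,\chi\,\beta_p(\theta,\lambda)$. The factor
  $\chi$ depends on the sensor angle and the particle phase function
  and has **no default** in this package: supplying it is a deliberate
  user obligation, and the synthetic tests derive it from the
  generator's own phase function by quadrature rather than inventing a
  literature constant.
* **Three-angle integration route** (104°/130°/151°): the weighted
  integrand $w(\theta) = 2\pi \sin\theta\,\beta_p(\theta)$ is formed at
  the three angles (in radians), the exact endpoint $w(\pi) = 0$ is
  appended, the unique cubic through the four points is constructed,
  and its antiderivative is evaluated analytically from $\pi/2$ to
  $\pi$. This is interpolation, not regression: permuting the angles
  changes nothing, and the result is exact whenever $w$ is itself a
  cubic vanishing at $\pi$. The stretch from 90° to 104° is covered
  only by polynomial extrapolation — that is a property of the
  procedure, documented rather than patched. For smooth backward phase
  functions of the kind the generator produces, the cubic's error
  against dense quadrature is well under 2%, the tolerance used in the
  tests.

The along-path absorption factor uses the scatter-corrected total
absorption for unfiltered runs and the dissolved absorption for
filtered runs — each stream is corrected with the absorption of the
water actually in the path.

## Particle size distributions

The laser-diffraction sizer reports particle volume concentration (PVC,
µL L⁻¹) in 32 logarithmically spaced bins spanning 2.5–500 µm
(constant edge ratio $200^{1/32} \approx 1.1801$). The representative
diameter of a bin is the geometric mean of its edges — the natural
centre on a log grid, and configurable (`d_choice`) for sensitivity
analysis since lower-edge and midpoint conventions also circulate.
Number and area distributions follow as
$N(D) = PVC / \bigl(\tfrac{4}{3}\pi (d/2)^3\bigr)$ (with the internal
unit conversion 1 µL L⁻¹ = 10⁶ µm³ mL⁻¹, so $N$ is per mL) and
$A(D) = N(D)\,\tfrac{\pi}{4}(d \times 10^{-6})^2$ in m² mL⁻¹. The
volume→number→volume round trip is algebraically exact and asserted to
$10^{-10}$ relative. Time series are median-reduced *before*
conversion: conversion is linear in PVC within a bin, so the ordering
only matters across bins, and the median of the raw instrument
quantity is the better-defined statistic.

## Filter-pad absorption

Particles on a glass-fiber filter sit in a scattering matrix that
amplifies the optical path, so measured filter-pad optical density
overstates suspension optical density. After blank subtraction
(negative blank-corrected values are clamped to zero — the non-integer
power below is undefined for negatives, and such values are pure noise
around zero loading), the empirical transform
$$OD_s = 0.323\,(OD_{fp})^{2.0867}$$
converts to suspension-equivalent OD, and the geometry
$a = \ln(10)\,OD_s/(V/A)$ gives the absorption coefficient, with $V$
the filtration volume and $A$ the spot area computed from the
caliper-measured diameter (a required metadata field).
Depigmented pads processed the same way give detrital absorption
$a_d$, and phytoplankton absorption follows as $a_{ph} = a_p - a_d$.
Replicates are aggregated as mean ± sample standard deviation.

When depigmentation is incomplete (residual pigment peaks), a smooth
model replaces the measured $a_d$. Three families are fitted over two
windows (380–530 and 380–600 nm): a simple exponential in
$\lambda - 400$, a power law in $\lambda/400$, and an exponential plus
a constant offset $k$ *fixed* at the 700–850 nm tail mean (not a free
parameter). The primary estimator is linear least squares on the
log-transformed (offset-subtracted) values, which needs no starting
value; optional Levenberg–Marquardt refinement on the original scale is
seeded at the conventional slopes 0.012 and 0.014 nm⁻¹, and the tests
confirm the two estimators agree on clean data. Selection among the
six candidates could follow "highest correlation" or "lowest RMSE",
which can disagree; the rule here is **lowest RMSE first, ties broken
by higher $r$**, both computed over the candidate's own fit window.
Both windows' slopes are reported (and their per-model mean), since
either may be the quantity of interest downstream. A candidate whose
log-transform window contains nonpositive values is dropped rather
than patched; it is an error only if every candidate drops.

## Discrete products

The packaged pigment reference table records name, abbreviation,
retention time and absorption maxima (with shoulder flags) for the
HPLC-resolved pigments; lookups are case-insensitive and an ambiguous
abbreviation returns all matches. Ratios of batch means (pigment:chl,
POC:chl) carry a propagated standard deviation
$$\sigma_R \cong \frac{\mu_X}{\mu_Y}\sqrt{CV_X^2 + CV_Y^2
  + 3 CV_Y^2 CV_X^2 + 8 CV_Y^4},$$
whose higher-order terms matter because a ratio of noisy quantities is
biased and heavy-tailed; a Monte-Carlo oracle in the tests confirms the
approximation to within 5% for CVs up to 0.15. Total chlorophyll a for
normalisation is monovinyl + divinyl chlorophyll a; chlorophyllide a is
excluded by default but can be included. Biovolumes follow the
microscopy conventions: diatoms as cylinders with the unmeasured
dimension set equal to the measured one according to viewing
orientation (girdle: height = diameter; valve: diameter = height),
other cells as prolate-spheroid ovoids $(\pi/6)\,a b^2$ or spheres
$(\pi/6) d^3$ when the axes coincide. Taxon summaries use the $n-1$
standard deviation and treat each input record as one observation —
whether records are strains or replicates is the caller's modelling
decision, not the summariser's.

## The synthetic-data generator

The generator emulates the statistical structure the pipelines assume,
not radiative transfer:

* $a_{ph}$: sum of Gaussian pigment bands (blue peak near 440 nm,
  carotenoid shoulders, red peak at 676 nm);
* $a_d$, $a_g$: spectral exponentials (slopes 0.011–0.0165 nm⁻¹
  across scenarios);
* $c_p$: power law with exponent $\gamma$;
* backward phase function: exponential decay in angle plus an isotropic
  floor, normalised so its backward-hemisphere integral is exactly 1 —
  simple enough for closed quadrature, curved enough that the cubic VSF
  integration is measurably inexact (so its tolerance means something);
* PSD: log-normal volume distribution (scenario median 12–16 µm);
* noise: per-instrument additive Gaussian noise (the AC-S level,
  0.001 m⁻¹ per time step, sits inside the ±0.003 m⁻¹ stability band
  quoted for such instruments) plus multiplicative "bubble" bursts on
  ≤5% of time steps, which the median reduction must and does reject;
* discrete analytes (chl a, POC) with stated CVs; hydrography fixed at
  21.5 °C and salinity 32, against a coefficient-table reference of
  19 °C.

Scenario presets (`exponential`, `stationary`, and their 50:50
`mixture`, which is linear in the additive components by construction)
are YAML data files, not code. One seed drives all randomness; the same
seed reproduces a rendered run byte-for-byte, and noise amplitudes
scale linearly with `noise_scale`, which the tests exploit to verify
that recovery error is proportional to injected noise.

**The null-at-715 nm convention.** The proportional scatter correction
can only determine absorption *relative to its reference-wavelength
value*; whatever true absorption exists at 715 nm is unrecoverable by
construction. The generator therefore defines its flow-through
absorption truths with each component's 715 nm value subtracted, which
makes the zero-noise render→process round trip exact to machine
precision — the honest statement of what the pipeline can recover. The
filter-pad renderer uses the physical (non-nulled) spectra, since an
integrating-sphere spectrophotometer has no such identifiability limit.
`truth_a_ph()` and friends expose both via `null_715`.

What the generator does **not** emulate — and hence what passing
recovery tests do not certify about real data: wavelength-dependent
phase-function shape, Mie structure in the PSD–optics coupling,
temperature-dependent pure-water optics, instrument drift within a
run, or correlated (non-Gaussian) noise. The generator validates the
*processing algebra*; it cannot validate instrument physics.

## Numerical choices and degenerate inputs

* Medians with an even record count are the mean of the two central
  order statistics (the base-R convention, asserted against a
  full-sort oracle).
* The scatter correction errors out when
  $c_t(\lambda_{ref}) \le a_t(\lambda_{ref})$ (nonpositive
  proportionality denominator) instead of producing a sign-flipped
  correction.
* VSF integration requires exactly three distinct angles strictly
  inside (90°, 180°); duplicates and out-of-range angles are errors.
* Counts below the dark offset yield negative $\beta$, retained and
  flagged (`qc_negative`) — clamping would bias the dissolved
  subtraction.
* The cubic through the four VSF points is solved from the Vandermonde
  system directly; with four points spanning ~1.3 radians this is
  perfectly conditioned.
* All quadratures used as oracles run at `rel.tol` $10^{-10}$ or
  tighter; the analytic antiderivative, not quadrature, is used for
  the production integral.

## Problem sizes

Rendered runs use 150 time steps per stream, 67 instrument wavelengths
(400–730 nm at 5 nm) for the flow-through meter, 2 nm filter-pad scans
over 290–850 nm with 3 replicates, and 32 size bins — small enough
that the full test suite, including every render→process round trip,
runs in well under a minute, and large enough that medians, fits and
quadratures behave as they would at full scale.

## Known limitations

* The filtered absorption stream is taken as $a_g$ without its own
  scatter correction (see above); for waters with significant
  sub-0.2-µm scattering this is an approximation.
* $\chi$ must be supplied; the package will not guess it.
* The three-angle route extrapolates over 90°–104°; phase functions
  that turn sharply near 90° will be integrated with larger error than
  the smooth-phase tolerance suggests.
* Detrital model selection by RMSE is scale-dependent; spectra should
  be in m⁻¹ before fitting.
* The workbook exporter's spreadsheet backend shells out to a Python
  interpreter with openpyxl; the TSV backend is the portable default.
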