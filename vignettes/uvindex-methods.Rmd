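---
title: "Methods: UVI estimation from single-wavelength irradiance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UVI estimation from single-wavelength irradiance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvindex)
```

## The quantities

The UV Index is a weighted integral of the solar spectral irradiance
$I(\lambda)$ (mW m$^{-2}$ nm$^{-1}$):

$$\mathrm{UVI} = \frac{1}{25\,\mathrm{mW\,m^{-2}}} \int_{250}^{400}
w(\lambda)\, I(\lambda)\, d\lambda,$$

with $w(\lambda)$ the ISO/CIE 17166:2019 erythema action spectrum:
$w = 1$ for $250 \le \lambda \le 298$ nm,
$10^{0.094(298-\lambda)}$ for $298 < \lambda \le 328$,
$10^{0.015(140-\lambda)}$ for $328 < \lambda \le 400$, zero outside.
Both branch changes are continuous (each pair of formulas agrees to machine
precision at 298 and 328 nm; this is tested).

A radiometer with spectral sensitivity $s(\lambda)$ reads
$M = \int s(\lambda) I(\lambda) d\lambda$, is calibrated linearly
($U_m = C_0 + C_1 M$, ordinary least squares against the true UVI), and is
judged by the signed percent error $\epsilon = 100\,(C(M)/U - 1)$ and by the
accuracy ECDF $A(t) = 100 \cdot \Pr(|\epsilon| \le t)$.

### Numerical choices

* **Quadrature.** Trapezoid rule on the spectrum's native grid. Brewer data
  come in 0.5 nm channels, where the trapezoid rule is accurate to well under
  0.1 % for these smooth weights (tested by grid refinement, and against an
  independent quadrature implementation).
* **Integration range.** The spectrum's own grid intersected with
  250–400 nm; no extrapolation beyond the measured range. A Brewer-style
  286–363 nm spectrum therefore misses the UV-A tail, worth roughly 1–3 % of
  the UVI for solar spectra; `compute_uvi()` flags this with a `truncated`
  attribute rather than correcting for it, because any correction would
  presume the spectral shape that the analysis is trying to measure.
* **Negative irradiance.** Brewer channels near 286 nm are noise-dominated
  and can be negative. `spectrum()` clips negatives to zero and reports the
  count; a strict mode rejects them. They are never silently kept.
* **Band-shaped sensitivities.** On a discrete grid an ideal boxcar would
  acquire interpolation ramps at its edges and integrate to more than its
  nominal width. `builtin_sensitivity()` therefore puts half weight on a
  channel that sits exactly on a band edge, making the trapezoid equivalent
  width equal the nominal width (a 310 ± 0.5 nm boxcar over a flat
  25 mW m$^{-2}$ nm$^{-1}$ spectrum reads exactly 25 mW m$^{-2}$).
* **Error metrics.** "Median error" is the median of $|\epsilon|$: after
  least-squares calibration the median *signed* error is near zero for every
  detector and would carry no information. Accuracy counts $|\epsilon| \le t$
  (a detector 50 % low is not "within 10 %"). Median ties use the standard
  lower-median convention; the scan's argmin breaks ties toward the lowest
  wavelength.

## The single-layer atmospheric model

Surface irradiance is modelled as the extraterrestrial (AM0) spectrum
attenuated by one effective layer with three adjustable parameters:

$$I_m(\lambda) = \exp\!\left[-A + B(\lambda - 320)
  - \frac{z\,\sigma(\lambda)}{\cos\varphi}\right] I_{solar}(\lambda)$$

* $A \ge 0$: gray (wavelength-independent) loss from clouds and aerosols;
* $B$ (nm$^{-1}$): a gross spectral tilt capturing the wavelength dependence
  of scattering;
* $z \ge 0$: ozone column (molecules cm$^{-2}$; user-facing functions use
  Dobson Units, 1 DU = 0.001 cm of ozone at STP $= 2.6885\times 10^{16}$
  molecules cm$^{-2}$, i.e. DU $= 3.720\times10^{-17} z$ — derived from
  $N_A$ and the 22.4 L molar volume and implemented from those first
  principles);
* $\sigma(\lambda)$: ozone absorption cross-section (cm$^2$/molecule);
* $1/\cos\varphi$: slant-path adjustment at solar zenith angle $\varphi$,
  valid for $\varphi < 90°$. The slant factor multiplies only the ozone
  term (the ozone layer is the thin high layer; gray cloud loss is treated
  as an effective local attenuation).

The zenith angle is treated as known metadata, never fitted: only
$(A, B, z)$ are free.

### Fitting

`fit_huber()` minimises residuals in **linear irradiance space** with
Levenberg–Marquardt (`minpack.lm::nls.lm`), bounded below at $A, z \ge 0$.
Taking logs makes the model exactly linear in $(A, B, z)$, so
`loglinear_fit()` — OLS of $\log(I/I_{solar})$ on
$\{-1, \lambda - 320, -\sigma/\cos\varphi\}$ — recovers noiseless spectra
exactly and serves both as the initializer and as an independent oracle for
the nonlinear route (the two agree to $<10^{-6}$ relative on noiseless
input; tested). Linear-space residuals were chosen for the production fit
because multiplicative noise plus an additive floor makes log-residuals
explode in the noise-dominated short-wavelength channels; for the same
reason both fitters drop channels at or below `min_irradiance`
(default 0.1 mW m$^{-2}$ nm$^{-1}$, ten times the default additive noise
floor). Convergence uses the standard `nls.lm` criteria (information codes
1–4); non-convergence is flagged on the returned object, never silent.
With the default 2 % noise, the median ozone-column recovery error is below
5 DU (tested over 200 replicates).

## The synthetic ensemble

`generate_ensemble()` emulates a long-term Brewer spectrometer record with
no external data:

| quantity | default | rationale |
|---|---|---|
| grid | 286–363 nm, 0.5 nm | Brewer channel layout |
| $z$ | Uniform(250, 500) DU | the naturally occurring ozone range |
| $A$ | Uniform(0, 3) | clear sky to heavy overcast ($e^{-3} \approx 5\%$ transmission) |
| $B$ | Uniform(−0.005, 0.005) nm$^{-1}$ | mild spectral tilt of either sign |
| $\varphi$ | Uniform(0°, 70°) | overhead sun to low sun |
| noise | 2 % log-normal × channel + 0.01 mW m$^{-2}$ nm$^{-1}$ additive, clipped at 0 | percent-level Brewer-class precision with a small dark floor |

Uniform distributions are used because only the ozone range is well
established; the fitted $(A, B)$ distribution of real records is not
published, so the bounds were chosen once to span the physically sensible
range and are config-overridable. Generation is fully seeded: a fixed seed
reproduces the ensemble byte-for-byte (parameters from the seed, noise from
seed + 1). Both the noise-free "true" UVI and the UVI of the noisy spectrum
are retained so recovery can be tested.

The test suite and the acceptance script use ensembles of 300–2000 spectra;
2000 spectra resolve the scan optimum to one 0.5 nm channel and the
calibration slope to well under a percent of its Monte-Carlo spread.

### Built-in reference curves, and their frozen constants

Two references feed the model. Both are smooth parametric stand-ins whose
constants were fixed once against published magnitudes and then frozen:

* **Solar AM0**: a 5778 K blackbody shape (the solar effective temperature)
  scaled to 689 mW m$^{-2}$ nm$^{-1}$ at 310 nm, the published AM0
  magnitude there. Positive everywhere, rising from 300 to 400 nm.
* **Ozone cross-section**: $\sigma(\lambda) = 8.0\times10^{-20}
  \exp[-(\lambda - 310)/6.3]$ cm$^2$/molecule. The anchor is the 273 K
  literature value at 310 nm; the 6.3 nm decay scale matches the published
  decade rate between 310 and 320 nm, the channels that bracket the scan
  optimum and carry the decisive ozone signal. Over 300–320 nm the
  approximation stays within about 20 % of measured values; it is
  deliberately weighted toward fidelity at 310–320 nm rather than a global
  fit, because the true decay is not exactly exponential.

Measured tables (two-column text, e.g. with a 21-line preamble skipped via
`read_spectrum_table(skip = 21)`) override the built-ins through
`reference_curves()`.

### What the smooth curves can and cannot reproduce

Everything *structural* about the single-wavelength result survives the
smooth approximation, and is asserted in the tests:

* the per-wavelength error curve has a sharp, narrow minimum at
  309.5–310.5 nm across seeds and across the literature-plausible range of
  the frozen constants, with errors an order of magnitude worse at 300 nm
  (ozone-dominated) and 350 nm (UV-A-dominated);
* the UVI-normalized spectra collapse at the same wavelength;
* UVI/$I_{310}$ is *exactly* invariant in $A$ (the gray factor cancels),
  which is why the rule survives arbitrary cloud and aerosol attenuation;
* UVI decreases monotonically in ozone and zenith angle; at ozone-hole
  columns the fixed-constant rule switches to underestimating the UVI
  (`crossover_ozone()` reports the switch point as a function of tilt and
  zenith angle rather than asserting a single number).

The *absolute channel constant* does not survive it. With the built-in
curves the ensemble yields a UVI-vs-$I_{310}$ slope of about 54 UVI per
(W m$^{-2}$ nm$^{-1}$) and a median ratio of about 51, versus the published
value near 77 measured on real spectra. A sensitivity sweep over the frozen
constants (cross-section scale and decay, solar temperature) moves this
constant only between roughly 47 and 61 while the optimum stays at
310 ± 1 nm: no literature-consistent smooth curve reaches 77. The
difference sits in spectral fine structure at the 0.5 nm channel scale —
solar Fraunhofer line blanketing and Huggins-band cross-section
oscillations — which modulates the flux of the specific 310.0 nm channel by
tens of percent. A per-channel multiplicative factor leaves every
correlation, error and invariance property unchanged (which is why the
optimum's location is trustworthy here) but scales the slope and ratio at
that channel (which is why their absolute values are not). Users who need
the absolute constant should load the measured AM0 spectrum and
cross-section tables; the analysis then runs unchanged.

For the same reason, the detector-comparison table reproduces the published
*pattern* — the erythema-matched detector exact by construction, a
310 ± 0.5 nm boxcar accurate to within 10 % for roughly two-thirds of
spectra, broad-band designs failing — while its signal column reports the
literal ratio median($M_d$)/median($M_{eas}$), about 0.8 for the boxcar
here; the published table's 0.3 uses a normalization that cannot be
reconstructed from its description.

## The parameter-space accuracy map

`engineering_accuracy_map()` evaluates $e = |77\,I_{310}/\mathrm{UVI} - 1|$
(with $I_{310}$ in W m$^{-2}$ nm$^{-1}$, linearly interpolated to exactly
310.0 nm) over a box of $(A, B, z)$ values sampled uniformly two standard
deviations around fitted central conditions, per `sample_box()`. The UVI in
the map uses the full 250–400 nm model range: the map characterises the
physical approximation, not an instrument bandpass. The box is sampled
uniformly because no distribution is established for these parameters; a
grid can be passed instead via a user-constructed `points` data frame.

## Limitations

* The model is a single effective layer: no explicit Rayleigh term,
  multiple scattering, temperature-dependent cross-sections or aerosol
  microphysics. $B$ absorbs these grossly.
* The built-in reference curves are smooth surrogates (see above): results
  that depend on channel-scale fine structure — the absolute 310 nm
  constant in particular — require measured tables.
* Passing tests on synthetic ensembles shows the pipeline and the model's
  internal consistency; it does not validate the model against real skies,
  since the ensembles are generated by the same forward model being fitted.
* Calibration is linear and single-channel by design; multi-channel or
  nonlinear estimators are out of scope.
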