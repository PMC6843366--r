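---
title: "Quantifying drug-cyclodextrin inclusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-cyclodextrin inclusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclofit)
```

Cyclodextrins solubilize poorly water-soluble drugs by including them in
their hydrophobic cavity.  Establishing that an inclusion complex forms,
its stoichiometry, and how tightly it binds requires several independent
experiments whose raw outputs are spectra and concentration tables.  This
vignette describes the models `cyclofit` implements for each of them, the
choices made where the methodology is genuinely open, and what the
package's synthetic-data generators do and do not emulate.

## Phase solubility

A phase-solubility experiment equilibrates excess solid guest against
increasing host concentrations.  For a soluble 1:1 complex the dissolved
guest follows the Higuchi-Connors A~L~ line

$$S(c) = S_0 + \frac{K_c S_0}{1 + K_c S_0}\, c,$$

so the slope lies in $(0, 1)$ and the association constant is recovered
as $K_c = \mathrm{slope} / \{S_0 (1 - \mathrm{slope})\}$.
`fit_phase_solubility()` fits the line by ordinary least squares and
classifies the diagram as A~L~ only when $r^2$ reaches the linearity
threshold (default 0.99, the conventional acceptance for A-type diagrams)
and the slope is in $(0,1)$; anything else is reported as `nonlinear`
with no constant.  Two choices deserve note:

* **Source of $S_0$.**  The measured intrinsic solubility, when the user
  supplies it, takes precedence over the fitted intercept: the intercept
  inherits all the leverage of the design, while $S_0$ is typically
  measured directly in the same study.
* **Uncertainty.**  The standard error of $K_c$ is propagated from the
  slope SE by the delta method,
  $\partial K_c/\partial \mathrm{slope} = 1/\{S_0(1-\mathrm{slope})^2\}$.

`gibbs_from_kc()` converts any association constant to a binding free
energy, $\Delta G = -RT\ln K_c$, with $R = 8.31446$ J mol^-1^ K^-1^ and
1 kcal = 4184 J.

## Speciation and global titration fitting

A UV-Vis titration holds the guest total fixed while the host steps
through a concentration ladder.  Each candidate stoichiometry is a set of
complexes $\mathrm{H}_h\mathrm{G}_g$ with cumulative formation constants
$\beta_{hg}$ (parameterized as $\log_{10}\beta$, the convention of global
fitting programs, which keeps the constants positive and the scale
sane).  `solve_speciation()` solves the two mass balances

$$H_\mathrm{tot} = [\mathrm{H}] + \sum_s h_s \beta_s [\mathrm{H}]^{h_s}[\mathrm{G}]^{g_s},
\qquad
G_\mathrm{tot} = [\mathrm{G}] + \sum_s g_s \beta_s [\mathrm{H}]^{h_s}[\mathrm{G}]^{g_s}$$

by a damped Newton iteration in $(\ln[\mathrm{H}], \ln[\mathrm{G}])$ —
positivity is automatic in log space, steps are capped at 5 log units and
halved until the residual decreases.  After first reaching the requested
tolerance the solver takes two more Newton steps: convergence is
quadratic, so this polish lands at machine precision, which matters
because bound fractions near 0 or 1 amplify any slack in the free
concentrations.  Zero totals are handled as exact boundary cases (the
remaining one-dimensional problem is monotone and solved by
root-bracketing).

`fit_titration()` implements variable projection.  The outer problem is a
bounded multistart search over $\log_{10}\beta$ (default 7 starts drawn
from $[1, 6]$, deterministic in the seed; the outer surface can be
multimodal).  For each trial the speciation is solved at every titration
point and the molar absorptivities follow per wavelength from
*non-negative* linear least squares — absorptivities are physical
quantities, and the constraint also stabilizes the projection.  With at
most a few absorbing species the non-negative solve is done exactly by
support-subset enumeration (the NNLS optimum is the minimum-RSS feasible
subset solution), vectorized across wavelengths.  Standard errors of
$\log\beta$ come from the curvature of the projected objective; when the
curvature is numerically flat the fit is flagged `degenerate` and no SE
is reported.

### Residual trends and model selection

Which stoichiometry the data support is decided from the residuals, not
from the raw fit quality alone.  `residual_trend_test()` runs a
one-sided Wald-Wolfowitz runs test on the residual signs at each
wavelength, ordered by titration point (zero residuals count as
positive).  Two aggregations feed the verdict:

* the fraction of wavelengths rejecting randomness at level $\alpha$
  (systematic when it exceeds $\alpha$, i.e. more often than chance), and
* a Stouffer combination $\sum_\lambda z_\lambda / \sqrt{n_\lambda}$ of
  the per-wavelength runs z-scores, which is standard normal under the
  null because the noise is independent across wavelengths.

The second signal exists because a titration has very few points per
wavelength: with seven or eight points an individual runs test only ever
rejects for a perfect block pattern, yet a shared misfit shape depresses
*every* wavelength's z a little.  Combining them restores power against
exactly that alternative.  Even so, sign-based statistics remain weak
against misfits whose residual curves cross the data several times; the
accompanying AICc ranking in `select_model()` is what reliably demotes
such models (their residual variance is far above the noise floor).
`select_model()` therefore ranks candidates first by the absence of a
systematic trend and then by AICc computed on Gaussian residuals, with
every fitted parameter counted — including the per-wavelength
absorptivities, so a second species pays for a full extra spectrum, not
just one more constant.

## O-H band deconvolution

The hydroxyl stretching envelope of a cyclodextrin complex
(3800-3000 cm^-1^) is decomposed into six Voigt sub-bands, the canonical
assignment for hydroxypropylated cyclodextrin systems: intracavity water
(~3525 cm^-1^), primary OH (~3439 cm^-1^), interstitial water (~3360 and
~3084 cm^-1^), guest OH (~3277 cm^-1^), and secondary OH (~3191 cm^-1^).
The workflow is:

1. **C-H subtraction** (`subtract_overlap()`): the overlapping C-H
   stretching doublet (~2922/2848 cm^-1^) is modeled as two Voigt peaks
   plus a straight baseline inside 3000-2700 cm^-1^ and its modeled
   profile — tails included — is subtracted from the whole trace.  No
   standard recipe exists for this step; a peak-model subtraction is used
   because it removes the doublet's tails from the O-H window, which
   simple windowed baselining cannot.  A window with no signal (maximum
   excursion under three noise MADs) is left untouched.
2. **Seeding** (`second_derivative_minima()`): a Savitzky-Golay second
   derivative (order-3 polynomial) marks sub-band centers as its local
   minima beyond a prominence threshold.
3. **Fitting** (`fit_bands()`): least squares over all Voigt parameters
   plus a straight baseline, by Levenberg-Marquardt with analytic
   Jacobians.  Centers are boxed to the seeds ± 40 cm^-1^ so the physical
   assignment cannot migrate; areas and widths are free but positive.
   The fit restarts from deterministically perturbed widths until the
   $R^2$ gain drops below 10^-6^ (best round kept, so $R^2$ never
   decreases).

The Voigt profile is evaluated exactly, as the real part of the Faddeeva
function $w(z)$ with $z = (x - x_0 + i\gamma)/(\sigma\sqrt2)$, using
Weideman's rational approximation with 32 poles (close to machine
precision on the upper half-plane).  The single "linewidth" of
spectroscopy software is split into its Gaussian $\sigma$ and Lorentzian
$\gamma$, both free — a one-width Voigt is underdetermined.

**Width caps and identifiability.**  When several sub-bands overlap
within one envelope, a component much wider than the inter-band spacing
can siphon area from its neighbours through its tails while changing the
envelope almost nothing — the fit is then degenerate along an area-trading
direction and noise decides the split.  `deconvolve_oh()` therefore caps
$\sigma$ at half and $\gamma$ at a fifth of the median gap between the
seeded centers (~86 cm^-1^ for the canonical scheme).  `fit_bands()`
itself imposes only positivity, so single-peak and well-separated fits
are unconstrained.

## Two-state van 't Hoff thermodynamics

The six sub-bands split into a weakly hydrogen-bonded class (the two
highest-wavenumber components, populations $I_1 + I_2$) and a
hydrogen-bonded class ($I_3 + \dots + I_6$).  `population_ratio()` forms
$R = (I_1+I_2)/(I_3+I_4+I_5+I_6)$ and `vant_hoff_fit()` regresses
$\ln R$ on $1/T$.  Because the weakly bonded population grows with
temperature, the slope against $1/T$ is negative; the hydrogen-bond
rupture enthalpy is reported as the positive magnitude
$\Delta H_\mathrm{HB} = |\mathrm{slope}| \cdot R$, with
$\Delta S_\mathrm{HB}$ from the intercept with its fitted sign.  This
magnitude convention sidesteps a sign ambiguity in how the linearized
relation is usually quoted while reproducing the conventional positive
rupture enthalpy.

A genuine two-state exchange also implies an isosbestic point: every
spectrum in the temperature series is a mixture of two fixed basis
spectra, so all of them cross where the bases cross.
`find_isosbestic()` area-normalizes the members (the normalization that
accounts for the effective number of absorbers), upsamples tenfold by
linear interpolation — interpolation commutes with mixing, so a genuine
crossing survives exactly between grid samples — and returns the axis
point minimizing the across-temperature SD of intensity.  Only points
carrying at least 10% of the maximum mean intensity are candidates
(baseline regions have trivially small SD), and the crossing is flagged
`present` when the minimum SD falls below 5% of the median SD.

## DOSY bound fractions

Under fast exchange a guest shows one diffusion coefficient, the
population average of its free and bound values, so
$f = (D_\mathrm{free} - D_\mathrm{obs})/(D_\mathrm{free} -
D_\mathrm{complex})$ (`bound_fraction()`), with the fully bound guest
approximated by the host/complex diffusion.  `kc_from_diffusion()`
inverts the 1:1 mass-action law from $f$ and the totals; it is an
extension beyond what diffusion data are usually asked to deliver and is
labelled as such — its value depends sensitively on the assumed
$D_\mathrm{complex}$.

## Assay arithmetic

`viability_percent()`, `ldh_release_percent()`,
`cumulative_permeation()`, `mucosal_accumulation_percent()` and
`fit_calibration()` implement the deterministic conversions used around
the binding work: MTT viability as treated/control, LDH leakage as
percent of total, Franz-cell cumulative amounts with the
sampling-with-replacement correction
$Q_n = C_n V_\mathrm{receptor} + \sum_{i<n} C_i V_\mathrm{sample}$
(the withdrawn aliquot volume is a parameter — protocols rarely print
it), tissue accumulation corrected by the validated extraction recovery
(97% w/w by default), and calibration limits at the pharmacopoeial
signal-to-noise thresholds LOD $= 3\sigma_N/\mathrm{slope}$,
LOQ $= 10\sigma_N/\mathrm{slope}$.

## What the generators emulate — and what they do not

Every analysis stage has a matched generator so the chain is testable
without instrument data; each is a deterministic function of its
parameters and seed.

* `gen_phase_solubility()`: the A~L~ line at $K_c = 6031$ M^-1^ and
  $S_0 = 2\times10^{-5}$ M on a 0-9 mM host grid, multiplicative
  Gaussian noise (2% CV default) — solubility assays are
  heteroscedastic.
* `gen_titration()`: speciation plus Beer-Lambert at guest total
  $4.43\times10^{-5}$ M over host totals 0 and
  $4.43\times10^{-5}$-$2.21\times10^{-3}$ M, additive absorbance noise
  (detector-limited), Gaussian-bump absorptivities at 270 nm (free
  guest) and 282 nm (complex) with $\varepsilon_{\max}$ of
  1.5-1.85 $\times 10^4$ M^-1^cm^-1^ — the scale of a quinone
  chromophore, giving peak absorbances near 0.7.
* `gen_oh_series()`: six Voigt sub-bands at the canonical centers whose
  class populations follow the van 't Hoff law
  ($\Delta H_\mathrm{HB} = 10596$ J/mol,
  $\Delta S_\mathrm{HB} = 35.9$ J mol^-1^K^-1^ by default — the entropy
  is chosen so $R$ crosses 1 mid-range over 250-340 K), total area 1 at
  every temperature, multiplicative point noise.  Sub-band widths
  ($\sigma \approx 28$-30, $\gamma = 8$ cm^-1^) are at the narrow end of
  what hydrogen-bonded O-H envelopes show, chosen so the six
  second-derivative minima remain individually resolvable — the regime
  the seeding step assumes.
* `gen_diffusion()`: speciation-derived bound fraction mapped to the
  fast-exchange average, on the 10^-10^ m^2^/s scale of small molecules
  in water.

The generators deliberately omit several features of real data:
scattering and drifting baselines, ATR penetration-depth dispersion,
water-vapor lines, wavelength-dependent (heteroscedastic) detector
noise, chemical-shift temperature drifts, and any inter-replicate
variability beyond the stated noise models.  Passing the recovery suites
therefore demonstrates that the estimators are correct and
well-conditioned under their own assumptions — not that they are robust
to instrument artifacts, which should be corrected before fitting.

## Problem sizes and numerical defaults

The recovery studies the package's tests and acceptance script run are
sized for a desk machine: 100 phase-solubility replicates, 25 titration
replicates (each a 7-start multistart over up to two constants on an
8-point × 101-wavelength matrix), and 50 temperature series of 10
spectra, each deconvoluted into six Voigts on a 201-point grid.
Tolerances: speciation converges to 10^-12^ relative (then polished);
band-fit rounds stop at an $R^2$ gain of 10^-6^; titration multistart
uses `optim`'s L-BFGS-B with tight `factr`.  Degenerate inputs are
handled explicitly: all-zero spectra refuse to normalize, zero totals
speciate exactly, all-zero absorbance matrices flag a degenerate
titration fit, identical spectra yield a degenerate isosbestic verdict,
and residuals of exactly zero take the positive sign in the runs test.

## Limitations

* Only the 1:1 A~L~ phase-solubility model is quantitative; A~P~/A~N~ and
  B-type diagrams are classified `nonlinear` and not fitted further.
* The titration machinery assumes activity coefficients of one and no
  competing protonation equilibria.
* The six-component O-H scheme is enforced for the thermodynamic
  analysis; it is the canonical choice for this system class but not a
  discovery procedure for the number of bands.
* The runs-test verdict has limited power against oscillatory misfits on
  few titration points (see above); rely on the full `select_model()`
  ranking rather than the trend verdict alone.
* `kc_from_diffusion()` assumes 1:1 binding and a known fully-bound
  diffusion coefficient.
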