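---
title: "Methods: models, numerics and design choices in piezodyn"
author: "piezodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in piezodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezodyn)
```

This vignette documents the physical models implemented in piezodyn, the
numerical choices behind the fitting routines, the realism and limits of the
synthetic-data generator, and the main design decisions. It is written for a
reader who knows basic neutron-scattering analysis and wants to understand
what the package actually computes before trusting it with data.

## 1. Data model and reduction

Measurements are held in two containers: `elastic_scan_set` (intensity
versus momentum transfer $q$, one row per temperature/pressure condition)
and `qens_dataset` (a dynamic structure factor $S(q,\omega)$ cube of
conditions $\times$ $q$ $\times$ energy transfer, plus the per-$q$
resolution function measured on vanadium). `raw_measurement` wraps either
payload with a kind (`sample`, `empty_cell`, `buffer`, `vanadium`), a
transmission, and a scan direction.

The reduction chain (`reduce_elastic`, `reduce_qens`) performs, in order:

1. **Background subtraction** with the standard transmission-weighted
   scheme: the empty cell is subtracted from both sample and buffer after
   scaling by the respective transmissions, and the buffer contribution is
   subtracted scaled by $(1 - f)$ where $f$ is the displaced-volume
   fraction. Uncertainties propagate in quadrature; negative intensities
   are clipped to zero and counted (`n_clipped`).
2. **Vanadium normalization** to remove detector-efficiency variation,
   with optional bad-channel masking.
3. **Detailed-balance symmetrization** (QENS only): multiplying by
   $\exp(-\hbar\omega / 2 k_B T)$ converts the measured quantum-asymmetric
   spectrum to its symmetric classical form. Because this factor depends on
   the sample temperature, backgrounds are subtracted *before*
   symmetrization and must carry the asymmetry of their own measurement
   temperature — the synthetic generator therefore emits one
   empty-cell/buffer measurement per sample condition.
4. **Binning**: weighted temperature binning for elastic ramps and
   flux-conserving energy rebinning (cell-averaged, exact for aligned bin
   edges) for spectra.

The master validation property — reduction applied to noiseless synthetic
raw data returns the reference spectra to machine precision — is enforced
in the test suite at $10^{-8}$ relative and is in practice $\sim 10^{-15}$.

## 2. Two-state elastic model

Elastic scans across a temperature ramp are fitted globally with

$$S(q,0) = A\, e^{-\langle\Delta x^2\rangle_T\, q^2}
  \left[ 1 - 2 p_1 p_2 \left(1 - \frac{\sin qd}{qd}\right) \right],
  \qquad p_1 p_2 = \frac{K}{(1+K)^2},\quad
  K = e^{-(\Delta H - T\Delta S)/RT}.$$

The global parameters are the inter-well distance $d$, the enthalpy and
entropy differences $\Delta H$, $\Delta S$, and a scale $A$; each
temperature contributes its own Debye–Waller term
$\langle\Delta x^2\rangle_T$. The fit uses bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a grid of starting points ranked by initial
cost, refining the best few.

**Sign degeneracy.** $p_1p_2$ is *exactly* invariant under
$(\Delta H, \Delta S) \to (-\Delta H, -\Delta S)$, which merely relabels
the two wells. Without intervention, noise can push the optimizer into the
mirrored branch, producing apparently catastrophic parameter errors that
are really the same physics. `fit_two_state` canonicalizes every result to
the $\Delta H \ge 0$ branch; this convention is stated in the
documentation.

The total mean-square displacement adds the inter-well contribution:
$\mathrm{MSD}_{tot} = \langle\Delta x^2\rangle + p_1 p_2 d^2$
(`total_msd`), the quantity used downstream for resilience and breakpoint
analysis.

## 3. QENS global fit

The model for one spectrum is an elastic line plus two Lorentzians, scaled
by a Debye–Waller factor and convolved with the measured resolution:

$$S(q,\omega) = A\, e^{-q^2 \langle u^2 \rangle}
  \Big\{ A_0(q)\, \delta(\omega) + (1 - A_0(q))\,
  \mathcal{L}\!\left[\Gamma_j(q) + \Gamma_{loc}\right](\omega) \Big\}
  \otimes R(q, \omega),$$

$$\Gamma_j(q) = \frac{\hbar}{\tau}
  \left[ 1 - e^{-q^2 \langle l^2 \rangle / 2} \right]
  \qquad \text{(Hall–Ross jump diffusion).}$$

Numerical choices worth knowing:

- **Convolution.** Resolution convolution uses an FFT on an extended grid
  with analytic evaluation of the model on the extension
  (`qens_model_convolved`), avoiding the wrap-around artifacts of circular
  convolution. Accuracy is verified against two closed forms: the
  Lorentzian$\otimes$Lorentzian summed-HWHM identity (fitted width within
  $3\times10^{-5}$ relative) and an independent quadrature Voigt
  evaluation (within $3\times10^{-13}$ at the peak).
- **Elastic fractions.** `fit_qens` offers two modes. With
  `a0_mode = "free"` (the default) one elastic fraction per $q$ channel is
  fitted jointly with the four or five dynamical parameters, bounded to
  $[0,1]$; the fitted $A_0(q)$ curve is returned as an `eisf_curve` ready
  for `fit_eisf`. With `a0_mode = "fixed"` the fractions are taken from a
  supplied curve (e.g. a previously characterized geometry) and only the
  dynamics are fitted. Fixing $A_0$ roughly halves the uncertainty on
  $\tau$ and $\langle l \rangle$ when the geometry is genuinely known.
- **Weighting.** Weighting residuals by uncertainties derived from the
  *observed* counts (Neyman $\chi^2$) biases fitted widths by tens of
  percent at realistic count levels, because downward noise fluctuations
  receive systematically larger weights. `fit_qens` therefore performs a
  few rounds of model-based iterative reweighting: after each fit, the
  per-channel variance is re-estimated from the *fitted* model intensity
  (plus a smoothed excess-variance term that absorbs non-Poisson
  contributions), and the fit is repeated. In Monte-Carlo tests at
  $10^4$ counts per $q$ channel this reduces median parameter errors from
  15–25% to 2–5%.
- **Correlation.** A single spectrum constrains $\tau$ and
  $\langle l \rangle$ mostly through their ratio (the low-$q$ slope of
  $\Gamma_j$); their estimate correlation is typically $> 0.95$. The fit
  stores the full covariance and `in_tau_l_region()` tests membership in
  the joint elliptical confidence region, which is the honest way to
  compare conditions.
- **Model-free check.** `model_free_fit` fits 1–3 free Lorentzians per $q$
  channel, selects the order by small-sample-corrected AIC, and classifies
  each width's $q$ dependence as flat (localized motion) or saturating
  (jump diffusion) — a model-independent sanity check before committing to
  the parametric form.

## 4. EISF geometry

$$A_0(q) = p + (1-p)\left[ s\, j_0^2\!\left(\frac{qR}{2}\right)
  + (1-s)\, \frac{1}{3}\left(1 + 2 j_0(q\, a_M)\right) \right]$$

with the methyl radius fixed at $a_M = 1.715$ Å and the half-argument
$j_0^2(qR/2)$ confinement form. The fit reports when $R$ is
unidentifiable (when the confined fraction $s$ is small the radius is
unconstrained, flagged from its relative uncertainty), and
`equivalent_radius` converts a cavity volume to the radius of the
equal-volume sphere for comparison.

## 5. Thermal laws, resilience, breakpoints

`select_thermal_law` fits both the Arrhenius and VFT forms to
$\tau(T)$ or rate data (weighted on the log scale for the Arrhenius
branch, bounded Levenberg–Marquardt for VFT) and compares them with AICc.
Two refinements avoid misleading verdicts:

- **Degenerate VFT.** As $T_0 \to 0$ with $D\,T_0$ held finite, VFT
  reduces *exactly* to Arrhenius. On clean Arrhenius data the extra
  parameter can then win the AICc comparison by overfitting noise that is
  not there. If the fitted $T_0$ is indistinguishable from zero (within
  twice its standard error), the selection is "arrhenius" regardless of
  AICc.
- **Indistinguishable.** If $|\Delta \mathrm{AICc}| < 2$, the result is
  flagged `indistinguishable` rather than forced into either class.

`resilience` converts the slope of $\mathrm{MSD}_{tot}(T)$ to a pseudo
force constant $k = 2 k_B / (\mathrm{d\,MSD/d}T)$ in N/m, with an explicit
overflow flag for non-positive slopes. `detect_breakpoint` exhaustively
searches interior breakpoints of a continuous two-segment linear model and
applies an F-test against the single-line null (with degrees of freedom
charged for the slope change and the breakpoint location); Monte-Carlo
calibration gives $\ge 90\%$ specificity on lines and $100\%$ sensitivity
within $\pm 10$ K on slope-ratio-3 kinks at 3% noise.

## 6. Synthetic generator: realism and limits

`generate_elastic_dataset` and `generate_qens_dataset` produce complete
raw measurement sets — sample, empty cell, buffer, vanadium — from a
`ground_truth` configuration: two-state parameters per pressure, QENS
dynamical parameters with configurable Arrhenius or VFT temperature laws,
EISF geometry, background levels and transmissions, a Gaussian resolution
of 70 µeV half-width by default, smooth detector-efficiency variation, and
detailed-balance asymmetry applied per condition. Noise is seeded and
either Gaussian (relative) or Poisson at a configurable total count per
$q$ channel.

What the generator deliberately does **not** model: multiple scattering,
self-shielding and absorption corrections, detector dead time, resolution
wings beyond the Gaussian shape, and sample-container Bragg contamination.
The problem sizes used in the examples and tests (9 temperatures × 25 $q$
points for elastic ramps, 7 $q$ × ~150 energy channels for spectra) are
the package's own choices, representative of backscattering and
time-of-flight practice.

All preset numerical values in `preset_profiles` are **fabricated
defaults** for testing and demonstration — the objects carry a
`fabricated_defaults` attribute and are not measurements of any real
system. The same applies to `synthetic_pmi_pair`, a constructed ortholog
stand-in that plants a known set of 16 substitutions for the sequence
module's worked example.

## 7. Sequence comparison

`align_pair` performs a global pairwise alignment (Biostrings,
BLOSUM62, standard gap penalties), `enumerate_substitutions` lists
substituted positions in first-sequence 1-based coordinates with labels
like `I35V`, and `classify_residue` assigns polarity classes
(acidic / basic / polar / hydrophobic) from a documented, overridable
mapping — glycine and histidine assignments vary by convention, so the
default table can be replaced per call.

## 8. Limitations

- The two-state model assumes a single effective hydrogen population; real
  proteins superpose environments, so fitted $\Delta H$, $\Delta S$ are
  effective values.
- Single-spectrum QENS fits constrain $\tau$ and $\langle l \rangle$
  jointly, not individually; compare conditions via the joint region.
- The EISF radius is unidentifiable when the confined fraction is small;
  the fit says so rather than reporting a meaningless number.
- Thermal-law discrimination needs an adequate temperature span; with few
  points or narrow ranges expect `indistinguishable`.
- The generator's idealizations listed above mean recovery statistics are
  a lower bound on real-instrument uncertainty.

```{r example, eval = FALSE}
# end-to-end example: see README.md for the same flow with printed output
gt  <- preset_profiles("piezophile_like")
ed  <- generate_elastic_dataset(gt, seed = 11, noise = "gaussian",
                                pressures = 1)
red <- reduce_elastic(ed$raw$sample, ed$raw$empty_cell, ed$raw$buffer,
                      ed$raw$vanadium, gt$backgrounds$displaced_fraction)
fit_two_state(red)
```
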