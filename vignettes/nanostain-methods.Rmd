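---
title: "Measuring dye-load-dependent DNA extension in nanochannels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dye-load-dependent DNA extension in nanochannels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanostain)
```

## The measurement problem

Bis-intercalating cyanine dyes such as YOYO-1 stain DNA heterogeneously at
substoichiometric dye:basepair ratios: in one freshly mixed tube, individual
molecules carry very different amounts of dye, forming a wide, continuous
distribution rather than two discrete populations. Because each bound dye
adds contour length, a nanochannel-confined molecule's extension grows with
its dye load. `nanostain` turns this heterogeneity into an instrument: one
heterogeneously stained sample spans dye saturations from the detection
limit (roughly one dye per 100 bp) up to the nearest-neighbour-exclusion
maximum of one dye per 4 bp, so a single experiment maps extension against
dye load and, by extrapolation to zero intensity, yields the extension of
native (dye-free) DNA — a quantity that cannot be imaged directly.

The package implements the full chain on synthetic data with known ground
truth: a population simulator, a per-frame profile estimator, population
intensity normalization, and the binned extension-curve analysis with
native-extension extrapolation and between-condition ratios.

## The profile model and its estimator

A uniformly stained molecule stretched along the channel produces, after
summing camera rows across the channel, a top-hat intensity profile
convolved with the microscope's point-spread function. With a Gaussian PSF
the profile is a difference of error functions:

$$ m(x) = b + \frac{A}{2}\left[\operatorname{erf}\!\Big(\frac{x-c+w/2}{\sqrt2\,\sigma}\Big) - \operatorname{erf}\!\Big(\frac{x-c-w/2}{\sqrt2\,\sigma}\Big)\right], $$

with centre $c$, extension $w$, plateau $A$, background $b$ and blur width
$\sigma$. Every kymograph line (one per frame) is fitted with this model by
unweighted least squares. The phrase "box convolved with an error function"
that is often used for this estimator describes exactly this closed form.

Numerical choices, all deliberate:

* **Optimizer.** A Levenberg–Marquardt loop with the analytic Jacobian,
  implemented in compiled code so that population-scale runs (hundreds of
  thousands of frames) stay cheap. Iterations stop when the residual sum of
  squares is stationary to $10^{-14}$ relative or the relative parameter
  step falls below $10^{-8}$, with a cap of 60 iterations; profiles that
  fail to converge by then are flagged rather than trusted. On noiseless
  model profiles the estimator recovers $c$ and $w$ to better than
  $10^{-10}$ px, and on noisy profiles its residual sum of squares is
  checked in the test suite against an exhaustive 0.1-px grid search over
  $(c, w)$ with $A, b$ profiled out by linear least squares and $\sigma$ by
  golden search.
* **Initialization** is deterministic and scale-free: $b_0$ = median of the
  outer 10% of pixels, $A_0$ = peak minus $b_0$, $c_0$ and $w_0$ from the
  half-maximum crossings, $\sigma_0 = 2$ px. No random restarts, so a rerun
  reproduces every fit bit for bit.
* **Bounds and validity.** $w \in (2\,\mathrm{px}, L)$,
  $\sigma \in (0.1, 10)$ px, $A > 0$. A solution resting on a bound
  invalidates the frame instead of raising an error.
* **Detection threshold.** A frame counts as signal only if the amplitude
  clears `snr_min` (default 3) times the robust background-noise estimate
  (1.4826 × MAD of the outer pixels). The threshold is applied twice: to
  the initial amplitude, and to the *fitted* plateau. The second
  application matters: at signal-to-noise near the threshold, roughly 3% of
  frames otherwise converge to a runaway solution — a very wide, very
  shallow box whose plateau sits inside the noise — which inflates the
  apparent extension of dim molecules and, downstream, visibly flattens the
  low-intensity end of the extension curve. Requiring the fitted plateau to
  clear the same threshold removes that failure mode; with it, the mean
  fitted extension of near-threshold molecules is unbiased to within a few
  nanometres. Molecules whose valid-frame fraction falls below
  `min_valid_fraction` (default 0.5) are flagged invalid as a whole; these
  are the operational "dark fraction".
* **Alignment** uses integer-pixel circular shifts to the median fitted
  centre, keeping photon counts exact; subpixel alignment is a non-goal.
  With half-integer centre offsets an integer shift is ambiguous by one
  pixel, which is why alignment-sensitive analyses should use the fit table
  (continuous centres), not the aligned image.
* **Per-molecule intensity** is the background-corrected integrated
  intensity $A \times w$, which is invariant to blur (the tests verify
  conservation to < 1% for $\sigma \le w/4$), rather than the per-length
  plateau. Whether published analyses used the integrated or per-length
  quantity is usually unstated; the integrated quantity is this package's
  choice and is recorded here rather than asserted of others.

## The synthetic-data generator

The simulator emulates the standard experiment: lambda-phage DNA (48.5 kb)
in a ~100 × 150 nm channel, EMCCD imaging at 100 ms exposure, 200 frames
per molecule, 0.16 µm pixels.

**Extension law.** Saturation $\theta$ is the fraction of the
one-dye-per-4-bp maximum. Each dye adds `dye_extension_nm` (default 0.51
nm) of contour; with a B-DNA rise of 0.34 nm/bp the relative contour gain
at saturation is $0.51/(4 \times 0.34) = 37.5\%$, consistent with the
independently reported ~36% contour increase for fully intercalated DNA.
The rise per basepair is not something the extension data themselves
constrain, so it is an explicit, documented configuration field rather
than a hidden constant. Confined extension is assumed proportional to
contour length, so

$$ w(\theta) = w_0\,(1 + 0.375\,\theta), $$

with $w_0$ the native extension of the condition. `dye_extension_nm` is
the *effective* per-dye gain of a condition: at high ionic strength the
net extension response to dye is weaker than the contour gain alone (the
dye's four positive charges reduce intramolecular repulsion), which the
simulator represents by a smaller effective value rather than by any
mechanistic polymer model — polymer physics of confinement is out of
scope.

**Dye-load distribution.** Saturations are drawn from a Beta distribution
with mean fixed by the sample stoichiometry ($\mu$ = `dye_site_bp` ×
dye/bp) and concentration $1/h$, where $h$ is the `heterogeneity`
parameter; variance $\mu(1-\mu)\,h/(1+h)$ grows monotonically with $h$
and $h = 0$ is the fully equilibrated point mass. The family was chosen as
the simplest two-parameter continuous distribution on $[0,1]$ with a
mean-conservation contract. $h = 2$ reproduces the phenomenology reported
for non-heated samples at dye:bp 1:40: a highly scattered distribution
whose detected (above-noise) molecules have a mean intensity several times
the population mean, because dim molecules fall below the camera's
detection limit.

**Equilibration.** Dye exchange between molecules is modelled as
first-order relaxation of each $\theta_i$ toward the cohort mean at rate
`relaxation_rate` (per hour), optionally with re-centred exchange noise.
Total dye is conserved to machine precision and variance decreases
monotonically in rate and duration. The rate is a free parameter — pass a
larger value for hotter or saltier buffers; no quantitative
dissociation-rate law versus ionic strength is claimed or fitted.

**Intensity model.** Total emission is assumed linear in bound dye, so the
*integrated* intensity is $I(\theta) = A_{sat}\, w(1)\, \theta$ and the
plateau is $A(\theta) = A_{sat}\,\theta\,w(1)/w(\theta)$. (Making the
plateau itself proportional to $\theta$ would make integrated intensity
superlinear in dye load and bias the relative-intensity axis; linearity of
total emission is the assumption the analysis chain actually relies on.)
`amplitude_at_saturation` = 400 photons/px puts the detection limit near
dye:bp 1:100, matching the range reported as detectable.

**Dynamics and noise.** Per-frame extension follows a stationary AR(1)
process (sd 0.3 µm, lag-one correlation 0.5 — slow breathing of the
confined chain between 140 ms frames); the centre performs a reflected
random walk (0.05 µm/frame). Molecule-to-molecule extension scatter
around the law (sd 0.15 µm) represents channel-to-channel variation.
Pixels receive Poisson shot noise plus Gaussian read noise (sd 2),
clipped at zero. Clipping makes the sample mean of low-count pixels sit
slightly above the noiseless expectation (about +0.08 photons at
background 4); the test suite therefore checks rendered means against the
closed-form mean of the clipped distribution. There is no EM-gain excess
noise, no photobleaching, no photonicking, and no sequence preference of
binding — so passing tests demonstrate correctness of the estimators
under this noise model, not robustness to every camera pathology of real
EMCCD data.

## Normalization and the dark fraction

Per-molecule intensities are normalized to the population's saturation
limit — the distinct upper edge of the intensity distribution attributed
to fully intercalated DNA. The limit is estimated as an empirical
quantile (default 97.5th percentile) of the pooled per-molecule
intensities: deterministic, robust to stray outliers, and configurable.
Estimate it on pooled, preferably equilibrated or high-dye samples so the
population actually reaches saturation; a per-condition override exists
for conditions where the constant-quantum-yield assumption fails (at high
ionic strength the observed maximum intensity can be markedly lower).
Relative intensities above 1 are reported and counted, never clipped, so
limit-estimation bias stays visible in QC output.

The dark fraction is `1 - detected/simulated`. Because detection selects
on brightness, detected molecules are brighter than the population
average; the simulator reproduces this selection bias and the test suite
asserts it.

## The extension curve

Molecules are sorted into half-open relative-intensity bins of width 0.04
anchored at zero (the convention this analysis standardizes on). Per
bin: arithmetic mean extension, its standard error, and the count; bins
under `min_per_bin` (default 3) are flagged unoccupied. The native
extension is the intercept of an unweighted ordinary-least-squares line
through the first eight occupied bin means, taken literally as "a linear
fit of the first eight binned values"; empty leading bins are skipped
with a message. The intercept's OLS standard error is reported as the
uncertainty — a package choice, since error bars on published
extrapolations of this kind are typically undefined in the text.

The expected-extension model line shares its functional form with the
simulator's law, so on simulated data the line through the recovered
intercept is directly comparable with the generating truth at every
$\theta$. Between-condition ratios divide binned means in bins occupied
in both curves, with first-order error propagation
($se_r = r\sqrt{(sem_a/m_a)^2 + (sem_b/m_b)^2}$).

Two properties worth stating precisely:

* **Sample independence.** Two samples at the same condition but
  different mean dye:bp land on the same curve, because relative
  intensity — not the tube's stoichiometry — determines extension. When
  comparing two such curves the package's tests use one pooled
  saturation limit for both samples (same condition, same quantum yield)
  and call bins "agreeing" when the difference of means is within twice
  the *sum* of the two standard errors, i.e. overlapping 2-SEM error
  bars; a joint z-test across 20 bins at 2 combined SE would reject
  correct implementations about half the time by multiplicity alone.
  Bins entering the comparison need at least 10 molecules on each side,
  since SEMs estimated from a handful of molecules are themselves too
  noisy to compare.
* **Intercept robustness.** The extrapolated intercept is insensitive to
  moderate error in the saturation limit: rescaling the relative-intensity
  axis changes the slope but not the value at zero.

## Problem sizes and reproducibility

The package's own demonstration sizes, chosen to give tight Monte-Carlo
checks while remaining desk-scale: full-chain recovery runs 2000 molecules
per condition (1000 each at dye:bp 1:20 and 1:5, 200 frames per molecule)
and recovers native extensions of 9.0 µm and 5.0 µm to well within 3%;
sample-independence comparisons use 600 molecules per sample; dark-fraction
runs 400 molecules at 1:40. Every stochastic operation takes an explicit
seed, and population runs derive per-molecule seeds deterministically from
a master seed, so any molecule can be re-rendered in isolation.
`scripts/acceptance.R` reruns the whole battery from scratch and writes the
headline numbers as JSON.

## Known limitations

* The extension law is imposed, not derived; no Odijk/de Gennes regime
  computation is performed, and ionic-strength effects enter only through
  the per-condition native extension and effective per-dye gain.
* Buffer dilution (e.g. TBE 0.05×–5×) is treated as a label; conversion to
  molar ionic strength is the user's lookup, not computed here.
* One molecule per region of interest: no segmentation of multi-molecule
  fields of view, no flat-fielding, no subpixel drift correction.
* The simulator's noise model omits EM-gain excess noise; absolute photon
  calibration (photons per dye) is out of scope — only relative
  saturation is measured.
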