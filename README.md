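# nanostain

Single-molecule analysis of heterogeneously stained, nanochannel-confined
DNA.

## The problem

Bis-intercalating dyes (YOYO-1 and relatives) stain DNA heterogeneously at
substoichiometric dye:basepair ratios: molecules in one tube carry widely
different dye loads, continuously distributed, and equilibrate only over
hours of heating or at high ionic strength. For anyone imaging DNA in
nanofluidic channels this is usually a nuisance — but it is also an
instrument: each bound dye adds contour length, so a heterogeneously
stained sample sweeps out the whole extension-versus-dye-load curve in a
single experiment, from the detection limit (~1 dye per 100 bp) to
intercalation saturation (1 per 4 bp). Extrapolating that curve to zero
intensity yields the extension of *native*, dye-free DNA, which cannot be
imaged directly.

`nanostain` implements the complete analysis for this experiment, plus a
ground-truthed simulator so every stage is testable without microscope
data:

* **simulation** — populations with Beta-distributed dye saturation
  (mean fixed by stoichiometry, spread by a heterogeneity parameter,
  total dye conserved), first-order equilibration kinetics, and rendered
  image stacks: PSF-blurred box profiles, Poisson shot noise, Gaussian
  read noise, extension breathing (AR(1)) and centre diffusion;
* **profile fitting** — every kymograph line is fitted with the
  box-convolved-with-Gaussian profile
  `b + (A/2)[erf((x−c+w/2)/√2σ) − erf((x−c−w/2)/√2σ)]`
  by Levenberg–Marquardt (compiled core, analytic Jacobian), giving
  per-frame centre `c`, extension `w`, plateau `A`, background `b` and
  blur `σ`, with a robust signal-to-noise validity rule that defines the
  "dark fraction" of undetectable molecules;
* **normalization** — per-molecule integrated intensities `A·w` divided
  by the population saturation limit (empirical 97.5th percentile),
  yielding relative intensities that proxy dye saturation;
* **extension curve** — fixed-width (0.04) intensity binning, an
  ordinary-least-squares line through the first eight occupied bins whose
  intercept is the native extension, the expected-extension model line
  `w(θ) = w₀(1 + θ·0.51/1.36)`, and between-condition extension ratios
  with propagated errors.

## Worked example

Simulate a 500-molecule population at dye:bp 1:5 with wide staining
heterogeneity, run the full chain, and extrapolate the native extension:

```r
library(nanostain)

cfg <- sim_config(native_extension_um = 5.0,   # dye-free extension, um
                  dye_extension_nm   = 0.40,   # effective gain per dye
                  condition_label    = "0.5x TBE")
pop  <- simulate_population(cfg, 500, mean_dye_per_bp = 1/5,
                            heterogeneity = 1.5, seed = 7)
summ <- analyze_population(pop)          # render -> kymograph -> fit -> average
res  <- analyze_extension_curve(summ)    # normalize -> bin -> extrapolate
res$extrapolation
```

```
#> first 1 bin(s) empty; fit starts at bin [0.04, 0.08)
#> <extrapolation_result> native extension 4.927 +/- 0.056 um (slope 1.71 um/unit, 8 bins)
```

The intercept is the recovered native extension (truth: 5.0 µm); the slope
is the extension gained per unit relative intensity, and the standard
errors come from the ordinary-least-squares fit through the first eight
occupied bin means. `res$normalization` reports the estimated saturation
intensity and how many molecules exceeded it; `res$curve$bins` holds the
binned curve (centre, mean, SEM, count per bin).

A file-based round trip (multi-page TIFF stacks in, CSV/JSON out) is
available both from R (`run_simulate()`, `run_analyze()`) and from the
shell:

```sh
Rscript inst/scripts/nanostain run-all \
    --config inst/extdata/toy_scenario.yaml --out /tmp/nanostain_demo
```

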