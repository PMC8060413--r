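# eprdist

Spin-label EPR mobility and distance-distribution analysis in R.

Site-directed spin labeling (SDSL) attaches a nitroxide radical to an
engineered cysteine of a protein. Two EPR experiments then report on
structure: continuous-wave (CW) spectra, whose lineshape reflects the
label's rotational mobility and therefore local contacts (e.g. a ribosome
binding next to the labeled site), and four-pulse DEER (PELDOR), whose
dipolar modulation encodes the distance distribution P(r) between two
labels over ~1.8–8 nm. `eprdist` implements the analysis chain for both,
plus the structure-model side needed to compare measured distributions
with conformer ensembles:

* **CW mobility** — field-axis recalculation, center-peak normalization,
  Savitzky–Golay smoothing, and the low-field peak ratio
  LFPR = I(B_mobile)/I(B_immobile), normalized to the protein free in
  solution, with a baseline-noise error bar.
* **DEER inversion** — background fit B(t) = exp(−k t^(d/3)) with joint
  (λ, k) refinement, form factor F(t) = V(t)/B(t) normalized to the
  modulation depth λ, Tikhonov regularization with non-negativity

      P̂ = argmin_{p ≥ 0} ‖Kp − F̃‖² + α²‖L₂p‖²,   ∫P(r)dr = 1,

  with the powder-average point-dipole kernel K (ν_dd ≈ 52.04 MHz·nm³/r³),
  α chosen by the L-curve corner criterion, and an uncertainty band from a
  background-model ensemble × 5 noise realizations.
* **Structure-based prediction** — Kabsch-superposition RMSD, gromos
  clustering (cutoff 0.15 nm, clusters with >50 members per 1000 frames),
  pseudo-label broadening of Cβ–Cβ distances, and cluster-size-weighted
  averaging with a ±weighted-SD band clipped at 0.
* **Synthetic data** — Gaussian-mixture P(r) with simulated DEER traces,
  two-component (mobile/immobilized) nitroxide CW spectra, and
  helical/unfolded conformer ensembles, all seeded and with truth
  side-cars, so every stage is testable without external data.

See the vignette (`vignettes/epr-distance-analysis.Rmd`) for the models,
assumptions, parameter choices and limitations.

## Worked example

```r
library(eprdist)

# simulate a DEER measurement with known truth: P(r) = N(3.5, 0.3) nm,
# modulation depth 0.3, background k = 0.05, SNR 30, 4 us window
ds <- make_deer_dataset(deer_ground_truth(
  components = list(c(3.5, 0.3, 1)), lambda = 0.3, k = 0.05, snr = 30,
  seed = 11))

inv <- invert_deer(ds$trace)
inv
#> <inversion_result> alpha 119, lambda 0.297, k 0.0489, noise 1.00e-02
#>   P(r): mean 3.481 nm, sd 0.336 nm
```

The recovered mean (3.48 nm) and width (0.34 nm) sit within the inversion's
resolution of the 3.5/0.3 nm truth; `alpha` is the L-curve-selected
regularization parameter, `lambda`/`k` the refined modulation depth and
background rate (truth: 0.3/0.05), and `noise` the estimated trace noise
(injected: 0.01).

```r
# CW mobility: a site that becomes 60% immobilized on binding.
# On synthetic spectra the LFPR landmarks are the generator's own
# low-field extrema (on measured spectra they are read off the data).
lm <- cw_landmarks()
ana <- lfpr_analysis(
  make_cw_spectrum(cw_ground_truth(immobilized_fraction = 0.6,
                                   noise_sigma = 0.002, seed = 1)),
  make_cw_spectrum(cw_ground_truth(noise_sigma = 0.002, seed = 2)),
  field_mobile = lm["mobile"], field_immobile = lm["immobile"])
round(unlist(ana), 4)
#>        raw_ratio  reference_ratio normalized_ratio            error
#>           1.9587         209.0134           0.0094           0.0055
```

The normalized LFPR far below 1 flags the mobility loss at the labeled
site; the error is the baseline-noise/peak ratio. A flexible label on a
non-contact site would give a normalized ratio near 1.

## Command line

A thin wrapper over the pipeline functions ships in
`inst/scripts/eprdist.R`:

```sh
Rscript inst/scripts/eprdist.R simulate --kind deer --seed 1 --out run/
Rscript inst/scripts/eprdist.R invert-deer --trace run/simulate/trace.dat --validate --seed 1 --out run/
Rscript inst/scripts/eprdist.R lfpr --spectrum s.dat --reference ref.dat --out run/
Rscript inst/scripts/eprdist.R predict-distances --pdb model.pdb --site-a 351 --site-b 363 --out run/
```
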