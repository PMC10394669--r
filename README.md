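# dlsinvert

Single-angle dynamic light scattering (DLS) is the workhorse quality-control
measurement for macromolecules in solution: a few microlitres of sample, a
minute of acquisition, and the instrument returns the normalized
second-order autocorrelation function g²(τ) of the scattered intensity.
What the experimenter wants is the distribution of hydrodynamic radii
behind that curve — is the protein monomeric, how polydisperse is it, is
there aggregate.  `dlsinvert` performs that inversion for R users:
instrument scientists screening plates of buffer conditions, and anyone
teaching or validating DLS analysis who needs a transparent, scriptable
alternative to vendor software.

## The model

The Siegert relation links the measured curve to the field autocorrelation,

```
g²(τ) = 1 + β [g¹(τ)]²
```

and for a mixture of diffusing species g¹ is an intensity-weighted sum of
exponential decays over a log-spaced grid of hydrodynamic radii R_h,j:

```
g¹(τ) = Σ_j x_j exp(−τ / s_j),   s_j = 1/(D_j q²),   D_j = k_B T / (6π μ R_h,j),
q = 4π n sin(θ/2) / λ
```

Because neighbouring exponentials are nearly collinear, the contributions
x are recovered by Tikhonov–Phillips regularized non-negative least
squares,

```
min_{x ≥ 0}  ‖Ax − b‖² + α‖Lx‖²   subject to  Σ x_j = 1,
```

with A the exponential kernel, b the truncated Siegert-inverted data, and
L the second-difference matrix penalizing curvature of the distribution.
The regularization parameter α is either fixed or selected automatically
at the corner of the L-curve (log-fidelity vs log-penalty across an α
ladder), located with the triangle method.  Fitted distributions are
summarized per region of interest by peak radius (mode), weighted harmonic
mean (WHM), weighted mean, and polydispersity index PdI = (σ/μ)² with
%PdI = 100 σ/μ.

A forward simulator produces realistic synthetic correlograms from
Gaussian particle populations — Mie scattering intensities at the
detection angle, multi-exponential decay, Siegert map, additive Gaussian
noise — so the whole pipeline can be validated without instrument data.

## Worked example

```r
library(dlsinvert)

setup <- dls_setup(wavelength_nm = 817, angle_deg = 150, temperature_C = 20,
                   refractive_index = 1.33, viscosity_Pa_s = 0.00089)

# simulate one sample: mean Rh 6 nm, 10% CV, beta 0.2, noise SD 0.002
sim <- simulate_correlogram(population(mean_nm = 6, cv_pct = 10), setup, seed = 1)

fit <- fit_curve(sim$curve, setup, alpha = "lcurve")
print(fit)
#> DLS fit 'sim': beta = 0.2006, alpha = 6.31, 83/83 lag points used
#>   fidelity ||Ax-b|| = 0.135, penalty ||Lx|| = 0.01723
#>   WHM = 6.07 nm, mode = 6.22 nm

peak_search(intensity_distribution(fit), list(c(1, 100)))
#>   roi_low roi_high empty mode_r_nm whm_r_nm  wm_r_nm area
#> 1       1      100 FALSE  6.222571 6.066981 6.549495    1
```

The estimated coherence factor (0.2006) matches the simulated β = 0.2; the
fit used all 83 lag points preceding the first g²(τ) < 1; and the reported
WHM of 6.07 nm agrees with the true intensity-weighted WHM of this sample
(6.29 nm) to 3.5%.  `area = 1` says the whole distribution sits inside the
1–100 nm region of interest — a clean, monomer-like sample.

`run_pipeline(run_config(...))` runs the same steps over a whole CSV of
curves and writes: `filter_report.csv` (per curve: `id`, `intercept`,
`baseline_sd`, `kept`, `reason`), `distribution.csv` (per grid point:
`curve_id`, `r_h_nm`, `intensity_weight`, `alpha`, `residual_norm`,
`penalty_norm`), `peaks.csv` (per ROI: `curve_id`, `roi_low`, `roi_high`,
`empty`, `mode_r_nm`, `whm_r_nm`, `wm_r_nm`, `area`), `fits.json` (per
curve: β, α, truncation index, norms, RMS residual), per-curve
`lcurve_<id>.csv` tables (`alpha`, `fidelity`, `penalty`, log₁₀ columns)
when α is selected automatically, and `run_log.json`, which round-trips
the full configuration via `load_run_config()`.  A thin command-line
wrapper with `simulate`, `fit` and `panel` subcommands lives in
`inst/cli/dlsinvert.R`.

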