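---
title: "Recovering size distributions from DLS correlograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering size distributions from DLS correlograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlsinvert)
```

## The measurement and the model

A dynamic light scattering (DLS) instrument illuminates a sample with a
monochromatic laser and records the intensity of light scattered at a fixed
angle with sub-microsecond resolution.  Brownian motion of the suspended
particles decorrelates the scattered field, and the instrument reports the
normalized second-order (intensity) autocorrelation function g2(tau).  The
Siegert relation connects it to the first-order (field) autocorrelation,

    g2(tau) = 1 + beta * g1(tau)^2,

where beta, the coherence factor, depends on the optical train and is close
to the amplitude of the decay above the baseline of 1.  For a mixture of
diffusing species, g1 is an intensity-weighted sum of exponentials,

    g1(tau) = sum_j x_j exp(-tau / s_j),    s_j = 1 / (D_j q^2),

with q = 4 pi n sin(theta/2) / lambda the scattering wavevector and D_j the
translational diffusion coefficient, converted to a hydrodynamic radius by
the Stokes-Einstein relation D = kB T / (6 pi mu Rh).  Recovering the
non-negative contributions x from a noisy g2 is a classically ill-posed
inverse problem: exponentials with nearby decay rates are almost linearly
dependent, so unregularized least squares amplifies noise into wildly
oscillating solutions.

## The inversion

`fit_curve()` proceeds in four steps.

1. **Coherence factor.**  A least-squares quadratic in tau is fitted through
   the g2 points with lag times below 5 microseconds and beta is read off
   the extrapolated intercept, beta = p(0) - 1, since g1(0) = 1.  The
   intercept is the only physically meaningful way to extract beta from the
   polynomial; the quadratic absorbs the initial decay curvature.  The
   window must hold at least three points, otherwise the user is asked to
   supply beta directly.

2. **Truncation and Siegert inversion.**  g1 = sqrt((g2 - 1)/beta) exists
   only where g2 >= 1, so the curve is cut at the first occurrence of
   g2 < 1; beyond that point the signal has decayed into baseline noise.
   Fewer than five surviving points aborts the fit (the curve is noise).

3. **Grid and kernel.**  The radius support is 200 points log-spaced between
   0.1 nm and 1e6 nm — free dye to dust.  The kernel A[i, j] =
   exp(-tau_i / s_j) maps grid contributions to g1 values.

4. **Regularized non-negative least squares.**  The solution minimizes

       || A x - b ||^2  +  alpha || L x ||^2   subject to  x >= 0, sum x = 1,

   where L is the interior (n-2) x n second-difference matrix with rows
   (1, -2, 1).  L annihilates constant and affine trends, so the penalty
   measures curvature of the contribution profile across neighbouring grid
   points; alpha sets how strongly smoothness is preferred over fidelity.
   The problem is solved as a single Lawson-Hanson NNLS run
   (`pracma::lsqnonneg`) on the stacked system [A; sqrt(alpha) L; w 1'] vs
   [b; 0; w].  The sum-to-one constraint is a soft row with weight w = 100
   relative to the unit-scale data rows — large enough that the constraint
   residual is negligible, small enough not to degrade the conditioning of
   the solve — and the returned weights are renormalized to sum exactly
   to 1.  Published alpha conventions differ in whether the penalty enters
   as alpha or alpha squared; this package minimizes
   fidelity^2 + alpha * penalty^2, the convention under which useful alphas
   for DLS fall in the familiar 1e-6 to 10 range.  Both w and the alpha
   convention are visible in `tikhonov_nnls()` so results can be matched
   against other implementations.

## Choosing alpha: the L-curve

`trace_lcurve()` fits the curve over a ladder of alphas log-evenly spaced
via 10^(start + k step) (defaults -6, 1, 0.2: 36 values).  Plotting log10
fidelity against log10 penalty gives an L-shaped curve: at small alpha the
penalty falls rapidly at little cost in fidelity, at large alpha fidelity
degrades with little smoothness gain.  The corner balances the two.
`triangle_corner()` locates it with a fixed-endpoint triangle rule: every
interior point is the apex of the triangle spanned by the first and last
points; apexes on the convex (origin-facing) side of the chord, identified
by the sign of the oriented area, are candidates, and the apex with the
sharpest vertex angle is the corner.  This variant is deterministic and
O(m), and a direct angle-enumeration oracle in the test suite pins its
semantics.  Angle ties are broken toward larger alpha — when two apexes
bend equally, the smoother solution is the conservative choice.  When every
point is collinear within tolerance there is no corner and `fit_curve()`
falls back to alpha = 0.01, a mid-ladder value that performs well on
monodisperse protein-like samples.  Corner selection at a ladder end point
triggers a warning to widen the ladder.

## Reported numbers

The fitted weights are summarized per user-selected region of interest
(ROI), e.g. 1-100 nm for protein work:

* **mode** — grid radius of the highest local maximum inside the ROI
  (strict local maxima; plateaus count at their lowest index; ties between
  equal peaks resolve toward the ROI's log-midpoint).
* **WHM / WM** — weighted harmonic and arithmetic mean radius.  These are
  computed over the detected peak's support (the contiguous run of positive
  weights containing the mode, clipped to the ROI), not over the whole ROI.
  The reason is robustness: the harmonic mean weights small radii as 1/r,
  so a stray 0.3% of weight parked at the 0.1 nm grid edge — which NNLS
  occasionally does when the estimated beta is a fraction of a percent
  above the effective one — would shift an ROI-wide WHM by tens of percent
  while leaving the distribution visually unchanged.  Restricting to the
  detected peak makes the reported size a property of that peak alone, and
  matches reporting radii through peak detection rather than global
  averages.  The mean inequality WHM <= geometric mean <= WM is asserted
  on every ROI-level computation.
* **PdI and %PdI** — (sigma/mu)^2 and 100 sigma/mu from the weighted
  moments of the distribution.  %PdI is numerically the percentage
  coefficient of variation; PdI = 0.05 (%PdI ~ 22) is the conventional
  monodispersity bound.  The moments come from the fitted distribution,
  not from a cumulant expansion: cumulant fits are notoriously distorted
  by trace aggregates.
* **volume weights** — `to_volume_weights()` divides intensity weights by
  the per-particle Mie intensity and multiplies by r^3.  This is only
  valid for homogeneous hard spheres of known refractive index, which
  macromolecules are not; the function warns on every call and is provided
  for comparability with instrument software.

Replicate acquisitions are fitted separately and combined by
`aggregate_fits()`, which reports the mean and sample SD of the per-curve
WHM plus the renormalized mean weight vector.

## Quality filters

Raw curves are dropped when the intercept (mean of g2 - 1 over the first
three points) falls below 0.05 — buffer-like, nothing is decaying — or
when the baseline (last 20% of points) has a standard deviation above 0.01,
symptomatic of dust transits and aggregates.  Both thresholds are
user-settable; the estimators are the simplest robust choices and the
defaults suit curves with beta around 0.2 and noise SD around 0.002.
After fitting, curves are filtered on the root-mean-square residual in the
g2 domain (default threshold 0.01, about five times a typical instrument
noise SD).  Residuals are deliberately not taken in the g1 domain: the
inverse Siegert transform divides the measurement noise by 2 beta g1, which
diverges as the signal decays, so no fixed first-order threshold separates
good fits from bad ones.

## The simulator

`simulate_correlogram()` emulates the forward physics: a number-weighted
Gaussian radius population (deterministic quadrature over mean +/- 5 sigma,
truncated at r > 0; Monte-Carlo particle sampling available behind
`method = "sampling"`), per-radius Mie scattering intensity at the
detection angle, binning onto the analysis grid, normalization to relative
intensity contributions, the multi-exponential g1, the Siegert map, and
i.i.d. Gaussian noise on g2.  Quadrature is the default because it removes
one Monte-Carlo noise source from validation studies; a seed is mandatory
whenever anything stochastic runs, and identical configuration plus seed
reproduces curves bit for bit.

The Mie series (Riccati-Bessel recurrences with a downward logarithmic
derivative) is implemented in the package; its values were verified against
two independent reference implementations agreeing to 1e-13, and the r^6
Rayleigh limit is part of the test suite.  The particle refractive index is
not part of the correlogram model — it only shapes number-to-intensity
conversion — and defaults to 1.45, protein-like; every simulation records
the value used in the curve metadata.

Defaults follow the published simulation conditions for this class of
instrument: wavelength 817 nm, detection angle 150 degrees, solvent index
1.33, viscosity 0.00089 Pa s, beta 0.2, g2 noise SD 0.002, and 20 C (the
temperature is the plate-reader operating point; it is the one instrument
constant the simulation protocol leaves implicit).  The default lag-time
vector is 200 points log-spaced from 0.5 microseconds to 1 second, wide
enough to resolve decays across the whole radius grid at both common
instrument geometries.

What the simulator does *not* model: multiple scattering, number
fluctuations, rotational diffusion, particle shape (form factors), and
correlated noise from finite acquisition times.  Passing validation on
simulated data therefore demonstrates the inversion machinery under ideal
single-scattering assumptions, not instrument-specific artifacts.

## The polydispersity benchmark

`polydispersity_panel()` simulates single populations over a grid of mean
radii (2, 6, 18, 54 nm) and 11 %CV values evenly spaced from 5 to 100
(the published range and count; the exact spacing is this package's
choice, recorded in the output), fits each at a set of fixed alphas, and
reports per (mean, alpha) the Spearman correlation across %CV between the
SD of the fitted and of the true intensity distribution.  SDs are computed
inside a 0.1-1000 nm window: it covers the support of every panel sample
(the widest reaches 324 nm) while excluding super-micron grid points,
where trace quasi-baseline weight would otherwise dominate the second
moment through the r^2 factor.  Rank correlations over 11 noisy fits are
coarse — single-panel Spearman values scatter by up to +/- 0.1 between
seeds — which is why the acceptance script averages three independent
panel replicates per reported value.

```{r, eval = FALSE}
pan <- polydispersity_panel(seed = 1)
round(pan$correlations, 2)
```

## Numerical choices and degenerate inputs

* Interface units are the ones instruments print — nm, degrees, Celsius,
  microseconds — converted to SI internally once, in `dls_setup()` and
  `correlogram()`.
* A grid built for one instrument setup refuses to fit curves analysed
  under another; s depends on q and the solvent.
* Exactly uniform data (b = A u) is reproduced for every alpha, since the
  uniform vector zeroes both the penalty and the fidelity terms.
* Fidelity and penalty are floored at machine epsilon before taking logs
  when tracing the L-curve.
* Monotonicity of fidelity (non-decreasing) and penalty (non-increasing)
  along the ladder is checked at solver tolerance and violations warn.
* The inversion itself contains no randomness; fitting the same curve
  twice is bit-identical.

Validation in the test suite runs on reduced problem sizes where that does
not change what is being tested (60-100 point grids for solver properties;
the full 200-point grid wherever a published quantity is reproduced).

## Limitations

Single-angle data cannot resolve species closer than a factor of roughly
two to three in radius, and no regularizer fixes that; the benchmark
quantifies what ranking information survives.  Intensity weighting means a
trace of large aggregate outshines the species of interest; the
number/volume views inherit hard-sphere optics assumptions.  The L-curve
corner is a heuristic — on nearly monodisperse, low-noise curves it can
select a larger alpha than distribution-recovery would want, which is why
fixed-alpha comparison across samples is kept as a first-class mode.
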