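---
title: "Dose-ratio calibration of radiochromic film: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-ratio calibration of radiochromic film}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmratio)
```

## The calibration problem

A radiochromic film records absorbed dose as a change in optical
absorption. After scanning, the measurement is the net optical density
$o = \log_{10}(\bar I_\mathrm{before} / I_\mathrm{after})$ of the red
channel, and dosimetry requires the batch- and scanner-specific inverse
response $d = f^{-1}(o\,|\,\theta)$. The conventional ("standard")
calibration exposes films to homogeneous doses at many levels and fits
$f^{-1}$ to the (plateau OD, reference dose) pairs; reliable fits need
more dose levels than free parameters, in practice eight or more
exposures.

The dose-ratio method calibrates from far fewer exposures by exploiting a
*spatially varying* profile delivered several times at different
monitor-unit scalings $k_i$. Writing $o_i(r) = f(k_i d(r)\,|\,\theta)$
for the measured OD profile of delivery $i$, the true dose ratio between
two deliveries is $k_i/k_j$ at *every* position, while the OD ratio is
not constant. Each profile position therefore contributes a residual

$$h_{i,j,r} = (k_i k_j)^{-1}\left(k_j f^{-1}(o_{i,r}) -
  k_i f^{-1}(o_{j,r})\right),$$

zero for the true $\theta$ regardless of the (unknown) relative profile
$d(r)$. The prefactor $(k_i k_j)^{-1}$ normalizes the difference, whose
two terms both approach $k_i k_j d_r$ near the solution, so residuals of
different level pairs are comparable. The fitted parameters minimize

$$\chi = \chi_a + \chi_b, \qquad
  \chi_a = \sum_{i<j}\sum_{r=r_{lb}}^{r_{ub}} w_r\, h^2_{i,j,r},$$

where the pair sum runs over all measurements that do not share a dose
level — repetitions are individual measurements, giving $9N(N-1)/2$ pairs
for $N$ levels in triplicate — and $r_{lb..ub}$ is the dose-falloff
annulus. Ratios alone fix the curve only up to a monotone
reparameterization of scale, so an absolute side objective anchors it:

$$\chi_b = \sum_{i=1}^{N_d} w_b \left(f^{-1}(o_i) - d_i\right)^2$$

over the plateau statistic of the highest measured dose level, with
$w_b = w_s\, N_r\, n_\mathrm{pairs} / N_d$ balancing the summand counts of
the two parts and $w_s = 10$ by default. Only the highest level anchors
because the calibration is valid strictly between the lowest and highest
trained OD: anchoring the top keeps every reconstruction an
interpolation. All repetitions of that level enter $\chi_b$ as individual
points ($N_d$ = number of anchor films); the balance factor makes the
result insensitive to that bookkeeping choice.

## Calibration families

Two differentiable, bijective families are provided.

* **Bimolecular** (3 parameters):
  $f^{-1}(o) = \theta_2\,(o/(\theta_1 - o))^{1/\theta_3}$, with
  $\theta_1$ the saturation net OD, $\theta_2$ the half-saturation dose
  (Gy) and $\theta_3$ a shape exponent. The forward map is the closed-form
  saturation sigmoid. Round trips are exact to $10^{-9}$ relative across
  0.1–15 Gy (tested).
* **Polynomial** (degree 4 by default, configurable):
  $f^{-1}(o) = \sum_m \theta_m o^m$. The constant term stays free because
  the zero-OD region is outside the valid range anyway. The forward map is
  obtained by bracketed monotone root finding (tolerance $10^{-12}$ on
  normalized OD).

Fitting happens in normalized coordinates ($o$ and $d$ divided by their
training maxima); physical-unit parameters are produced on demand
(`physical_theta()`, and in the JSON serialization). For the polynomial
family the mapping is $\theta_m^\mathrm{phys} = \theta_m\,
s_d / s_o^m$; identity of the two parameterizations is tested to
$10^{-12}$.

Analytic parameter gradients (the powers $o^m$ for polynomials; closed
forms for the bimolecular partials) feed the cost gradient

$$\partial_{\theta_m}\chi_a = \sum_{i<j}\sum_r 2 w_r h_{i,j,r}
  (k_ik_j)^{-1}\left(k_j \partial_{\theta_m} f^{-1}(o_{i,r})
  - k_i \partial_{\theta_m} f^{-1}(o_{j,r})\right),$$

verified against central finite differences at 100 random parameter and
data draws per family.

## Optimization

The default engine is Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
weighted residual vector with analytic Jacobian; a BFGS engine on the
scalar cost with analytic gradient is available and gives held-out
residuals identical to within 0.01 percentage points on the recovery test
(the choice of minimizer is configuration, not semantics — the
polynomial cost is exactly quadratic in $\theta$, so any conforming
method finds the same unique optimum). Iterations are capped at 1000 and
the convergence flag reflects either the engine's own criterion or a
gradient norm below $10^{-10}$ in normalized coordinates.

Start values are i.i.d. normal with standard deviation 0.1 in normalized
coordinates. Polynomial starts are centred at zero — small start values
avoid beginning in oscillatory configurations. Bimolecular starts are
centred at $(1.5, 0.5, 1.0)$: a saturation OD $\theta_1 \le 1$ (the
largest normalized OD) is never physically meaningful, so zero-centred
draws would be rejected wholesale. Starts with non-finite initial cost
are rejected; each completed restart must pass the bijectivity check
(dose finite, positive and strictly increasing on a 512-point grid over
the trained OD range) to be accepted; the best accepted restart by final
cost wins, ties broken by restart index. 20 restarts per fit by default;
the repeated-fit distributions of the evaluation module use one fresh
start per repeat instead, so the spread across repeats shows the
start-value sensitivity.

During optimization, samples where the model is undefined (bimolecular
$o \ge \theta_1$) contribute a large finite penalty ($10^3$ per residual,
zero derivative) instead of `NaN`, keeping line searches well defined.

## Image front end

Scans are 16-bit TIFF before/after pairs; the OD map uses the film-wide
mean of the before scan (a per-pixel option exists). Zero or saturated
after-pixels are masked, and more than 1% of them is an error.
Coordinates are mm from the top-left pixel centre, x rightward, y
downward; radial bins are half-open $[b\Delta r, (b+1)\Delta r)$.

The field centre is found by minimizing the OD standard deviation
$\sigma_{or}$ on the ring where the dose is 50% of the plateau — the
steepest part of the falloff, hence the most centre-sensitive statistic.
The search is a coarse grid (±5 mm, 1 mm steps) about the geometric
centre followed by a fine grid (±1 mm, 0.1 mm steps) about the coarse
minimum; the ring has half-a-bin thickness, ties go to the first
candidate in row-major order, and a flat map raises a degeneracy error.
The grid extents and ring thickness are implementation choices: the
coarse extent covers realistic placement errors, and the fine step of
0.1 mm is well below one pixel even at the coarsened test resolution.
Centre recovery is tested to within one pixel over 50 random offsets up
to 5 mm, and re-running the search from the recovered centre stays put.

The 50% radius default (21.5 mm) derives from the assumed profile — the
profile is known a priori in this calibration geometry. Gradient samples
for the fit come from 15–27 mm (inside the film with a safety margin);
the plateau statistic is the unweighted mean of bin means up to 7.8 mm.
Plateau positions all see the same dose, so including them in $\chi_a$
would add no shape information, only noise and cost evaluations — they
are used for anchoring and verification only.

## The synthetic generator

The generator emulates the measurement campaign so every stage is
testable without scanner data: a radially symmetric profile with a 15 mm
plateau, a linear falloff from 80% at 17 mm to 20% at 26 mm (the shoulder
between plateau and falloff is joined by a monotone cubic, and the tail
below 20% continues the falloff slope exponentially — the join shapes are
not critical and are chosen smooth), samples below 5% of the plateau dose
excluded; dose levels 0.25–12 Gy in triplicate; 67 mm film pieces; and a
four-quadrant single-exposure layout with 4/12/2/0.75 Gy fields spaced
120 mm apart, optionally perturbed by a uniform 1% cross-scatter term.
Rendered images are produced at a coarsened 0.4 mm pixel size so the test
suite runs in minutes; 300 dpi (0.085 mm) is available by configuration.
The acceptance computations use the sizes stated there: 200 random splits
per training-set size, 50 repeats per sweep cell, 50 rendered films.

The ground-truth response is bimolecular with $\theta = (0.70,\ 8.0\
\mathrm{Gy},\ 1.0)$: saturation net OD 0.70, half-saturation 8 Gy, and
the classical bimolecular kinetics exponent $\theta_3 = 1$, giving net OD
0.42 at 12 Gy and a response linear in dose at the low-dose end, like
measured film. These are synthetic defaults, not batch parameters. The
exponent and saturation strength were chosen once so that the synthetic
curve shares a decisive property of real EBT3 response curves: a
fourth-order polynomial tracks it to about one percent over the working
range. That property is not cosmetic. With a strongly hyperbolic truth
(half-saturation well below the top dose, or $\theta_3 > 1$, which makes
$\mathrm{d}f^{-1}/\mathrm{d}o$ singular at zero OD), no quartic can
approximate the curve in relative terms, and the ratio cost then pushes
the irreducible model error into its weakly determined directions,
producing tens-of-percent held-out errors at the *global* optimum — a
regime in which polynomial film calibration as practised would not work
at all, on real or synthetic data.

The noise model has two parts: additive per-pixel OD noise (relative 1%
plus an absolute floor of 0.002, scaled by $1/\sqrt{\mathrm{count}}$ per
radial bin to emulate pixel averaging) and a per-film multiplicative
sensitivity factor (0.5% standard deviation), as in active-layer
thickness variation between film pieces. Every stochastic output is
reproducible from the seed.

### What the defaults imply for the method — and what they do not show

The ratio cost has a structurally soft direction: a multiplicative error
applied uniformly to all reconstructed doses leaves every ratio unchanged
and is resisted only by the single-level anchor and by the rigidity of
the calibration family. Per-pixel noise averages out over positions and
barely excites this mode. Per-*film* systematics do not average out
within a film, and at the default 0.5% sensitivity spread they displace
the global optimum by several percent — visibly worse than the standard
method on the same splits, and the dominant term in the split-experiment
medians the acceptance script reports. The script therefore also reports
the same eight-level experiment with the per-film component disabled,
where the ratio method's median drops to the sub-percent regime and the
method's advertised behaviour (few exposures at standard-method quality)
is reproduced. The practical reading: the dose-ratio method presumes
film-to-film repeatability at the few-tenths-of-a-percent level, which
well-handled protons-grade film achieves and which poorer film/scanner
combinations do not; the generator's default sits deliberately at the
pessimistic end. The passing of noise-free and low-noise tests says
nothing about scanner artifacts (lateral response, polarization, film
curl), which the generator does not model and the pipeline does not
correct.

Within one multi-field exposure the sensitivity factor is common to all
fields, so the single-measurement calibration is insensitive to it — one
of the practical attractions of the four-quadrant layout, and the reason
its residuals sit well inside the few-percent envelope at default noise.

## Numerical choices and degenerate inputs

Tolerances: polynomial forward inversion $10^{-12}$; LM stopping
tolerances $10^{-15}$ (effectively machine-limited); bijectivity grid 512
points; OD range checks allow $10^{-12}$ relative slack. Degenerate
inputs raise typed errors rather than propagating: fewer than two dose
levels, a standard-method fit without strictly more points than
parameters, mismatched radius grids between measurements (profiles must
be rebinned to a shared grid before pairing), empty plateau or gradient
regions, flat OD maps in centre finding, and four-field layouts whose
cutoff radii would overlap. Test points above the trained OD range are
excluded from RMSD but counted and reported (a saturating curve has no
usable inverse there); points below the trained range are evaluated by
downward extrapolation and flagged, so the cost of calibrating without
low dose levels is visible rather than hidden — this is what makes the
two-level sweep blow up at the near-unity dose ratio, where most of the
dose range lies below the trained window.

## Known limitations

* No scanner-artifact corrections (lateral response, polarization, film
  curling) and no multichannel dosimetry; small centred film pieces are
  assumed.
* The relative profile must be identical across deliveries up to the
  monitor-unit scaling; geometric distortions between deliveries bias the
  ratios.
* The anchor ties the absolute scale to the highest level's plateau;
  per-film systematics on those films propagate multiplicatively to the
  whole curve.
* Evaluation metrics are plateau-based; the gradient region is used for
  fitting only.
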