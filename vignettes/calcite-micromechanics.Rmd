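---
title: "Models and methods for calcite micromechanics"
author: "calcmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for calcite micromechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcmech)
```

`calcmech` implements the quantitative analysis chain for the intrinsic
mechanics of calcite single crystals: reduction of uniaxial micro-pillar
compression data, Weibull strength statistics, Schmid-factor analysis of
calcite's deformation systems, a wing-crack strength model for crystals
containing nanoscopic intracrystalline defects, and geometric statistics of
defect populations. This vignette records the models, their assumptions,
the numerical choices, and the places where the design was genuinely open.

## Micro-pillar compression reduction

A focused-ion-beam-milled micro-pillar is slightly tapered (top diameter
$D_1$, bottom diameter $D_2$, height $h$) and sits on an elastic half-space
of the same material. The measured depth therefore contains both pillar
compression and substrate sink-in. The normalization used throughout is

$$\varepsilon_n = \frac{\delta}{h}, \qquad
\sigma_n = \left(\frac{4}{\pi D_1 D_2} + \frac{1-\nu^2}{D_2 h}\right) F,$$

a Sneddon-type compliance correction for a slightly tapered pillar: the
first term is the mean-cross-section stress, the second the substrate
contribution, which vanishes as $h \to \infty$. Units are
instrument-native on input (mN, nm, µm) and GPa/dimensionless on output;
with these units the conversion constant is exactly 1. The Poisson ratio
defaults to 0.3, the average value for calcite. Strengths, by contrast,
are referred to the *top* cross section where stresses concentrate:
$\sigma_Y = 4F_Y/(\pi D_1^2)$ and $\sigma_\max = 4F_\max/(\pi D_1^2)$.

**Modulus.** $E$ is the least-squares slope of $\sigma_n(\varepsilon_n)$ on
a stress window of the rising loading curve, by default 50--95% of a
reference stress. Because a window referenced to the curve maximum would
swallow post-yield points of a hardening curve, `reduce_curve()` iterates:
a preliminary fit on the 25--50% window (safely elastic for both observed
material classes), a yield detection against that line, then the final fit
on 50--95% of the *pre-yield* stress range and a second yield pass. Points
past the global stress peak (burst reloads, flow plateaus, fracture drops)
are never used. Fits with fewer than 3 points are an error.

**Yield.** The instruments report no yield marker, and "onset of
nonlinearity" needs an operational rule. The rule here: the first loading
point whose running-median-smoothed stress (window 5) falls below the
elastic line by more than 2% relative, sustained for 3 consecutive points,
with the absolute deviation also exceeding 4 residual standard deviations
of the modulus fit. The relative threshold gives scale invariance and
reduces to the exact knee as it tends to zero; the noise floor (zero for
clean data) keeps transducer scatter from triggering early; the smoothing
and persistence requirements guard single outliers. Because a pure
threshold crossing lands systematically late on a hardening curve (by
$\approx$ tol$/(1-h/E)$ in strain), the knee is refined by intersecting the
elastic line with a secant through the first post-threshold points — exact
for clean bilinear data. If the first deviating point follows a
displacement burst (strain step > 5 × median), the last pre-burst point is
the yield point instead. A curve that never deviates is flagged
`yielded = FALSE`, not an error.

**Fracture and bursts.** Terminal fracture is a single-step relative force
drop above 50%, from at least half the peak force, after which the force
never recovers above 25% of the peak; the recovery condition distinguishes
it from the recoverable load drop of a displacement burst. A burst is a
single-step strain increment above 5 × the median loading increment; the
flow strength $\sigma_f$ is the mean stress over the longest contiguous
post-burst region with $|d\sigma/d\varepsilon| < 0.1E$ (at least 5
points). All thresholds are arguments.

**Cohorts.** `summarize_cohort()` reports per-group mean ± sd per property
and two-sample t-tests (equal variances by default, Welch optional). A
single observation gives `sd = NA` rather than an error.

## Weibull strength statistics

Brittle strengths follow
$f = 1 - \exp\left[-(\sigma_Y/\sigma_{Y0})^m\right]$; the Weibull modulus
$m$ measures scatter (higher = more reproducible). Two fits are provided:

* **Linearized** (default): regress $\ln(-\ln(1-f))$ on $\ln\sigma_Y$
  through the empirical failure fractions; slope $=m$, intercept
  $=-m\ln\sigma_{Y0}$. This matches the straight-line Weibull-plot
  presentation and is exact when points lie on the model CDF.
* **Maximum likelihood**: the standard two-parameter score equations,
  profiled to one dimension in $m$ and solved by bisection
  (`uniroot`, tolerance 1e-12), with
  $\sigma_{Y0} = (\tfrac1n\sum \sigma_i^m)^{1/m}$.

The plotting position is the median-rank style $(i-0.5)/n$; the source
material for such analyses rarely states one, so it is an argument
(`"mean"` gives $i/(n+1)$). Ties keep input order (stable sort). Standard
errors are nonparametric bootstrap (default 2000 resamples, seeded); the
provenance of published "±" values on Weibull moduli is typically unstated,
and the bootstrap makes ours explicit. Degenerate samples (all equal) and
samples below $n=3$ are errors. At cohort sizes near $n=25$ the shape
estimate scatters by tens of percent; recovery should be judged by medians
over replicates, as the tests do.

## Calcite crystallography and Schmid factors

The low-temperature deformation systems of calcite are e-twinning
$\{\bar1018\}\langle40\bar41\rangle^+$ (three systems, unidirectional),
r-slip $\{10\bar14\}\langle\bar2021\rangle^\pm$ (three), and f-slip
$\{\bar1012\}\langle2\bar201\rangle^\pm$ (six; each f plane contains two
symmetry-related shear directions). The catalog is generated by cyclic
permutation of the basal Miller--Bravais indices (the threefold rotation
about c) and every entry is checked against the direction-in-plane
invariant at 1e-8.

Indices are interpreted in the hexagonal **structural cell**, default
a = 4.99 Å, c = 17.06 Å. This is a real choice: Schmid factors depend on
c/a, and alternative cells (morphological, cleavage) give different
numbers. With the structural cell the r systems under exact c-axis
compression come out at $|m| = 0.49996$, threefold degenerate to machine
precision; the cell is configurable, and the value's smooth dependence on
c/a is exercised in the tests rather than asserted as universal.

Plane normals use the reciprocal basis; directions use the direct basis
with the standard reduction $U = u - t$, $V = v - t$, $W = w$. The Schmid
factor is reported *signed*, $m = (\hat n \cdot \hat\ell)(\hat d \cdot
\hat\ell)$, and the resolved shear sense under the stated load sign
(compression negates it) decides activation: twins activate only in their
positive sense, slip in either. Under c-axis compression the r systems
resolve in the negative sense, and the e twins are not activated — the
catalog makes both statements checkable. Load axes are normalized with a
warning rather than rejected; ranking uses $|m|$ with ties (symmetry
degeneracy, 1e-9) grouped.

## Wing-crack strength model

Compressive failure of a quasi-brittle solid with pre-existing flaws is
controlled by tensile "wing" cracks nucleating at the tips of sliding
defects and coalescing between neighbours. For elliptical intracrystalline
defects of half-length $a$, spacing $L$, and inclination $\theta$ from the
transverse plane, the strength is

$$\sigma_y = \left(\frac{2\pi}{11}\right)^{1/4} L^{1/2}\,
\frac{\sigma_{Y,c}\sqrt{\pi a}}{20\,\beta(\theta)\,a},$$

with $\sigma_{Y,c}$ the compressive strength of the defect-free matrix
(0.96 GPa for geological calcite from pillar compression) and
$a \approx 5.5$ nm. Only $L/a$ enters, so the prediction is independent of
the length unit; the $\sqrt L$ scaling is exact and is asserted at 1e-12 in
the tests. The numerical constants are implemented literally as part of the
model definition.

$\beta(\theta)$ encodes the orientation and friction dependence of defect
sliding. Its published functional form was not available to this package,
so the default is the resolved-sliding factor
$\beta = \max(\sin\theta\cos\theta - \mu\cos^2\theta,\ \beta_{\rm floor})$
with $\mu = 0.3$ and $\beta_{\rm floor} = 0.1$: it vanishes (hence the
floor) for near-transverse defects, rises through 30--50°, and reproduces
the qualitative trend that tilting defects toward 30--50° weakens the
crystal about as much as crowding them does. The whole function is
injectable (`beta_fun`) so an exact form can be dropped in. Consequences of
this choice: absolute strengths are meaningful only after calibration.
`calibrate_wing_crack()` rescales $\beta$ so a reference configuration
(nominal spacing 32 nm, $\theta = 0$) carries an anchor strength
(0.96 GPa); the model is linear in $1/\beta$, so the spacing/orientation
*dependence* — e.g. the $0.96(1-\sqrt{10/32}) \approx 0.42$ GPa drop when
spacing falls to 10 nm — is calibration-free. Strength maps over
$(L, \theta)$ carry the observed-configuration box (L 10--32 nm,
$\theta < 5°$) as an annotation.

The stress-concentration anisotropy of the flattened defects is summarized
by the Inglis hole ratio $(1+2r)/(1+2/r)$, $r$ = span/height — a
deliberately simplified stand-in for a stress-intensity analysis of the
ellipsoid tips, documented as such. For the measured 10 × 5 nm geometry it
exceeds 2, consistent with preferred cracking along the defects' long
axes.

## Strengthening by hardness contrast

Obstacles that pin dislocations raise hardness and flow stress together,
$H = H_0 + C\,\Delta\sigma_Y$, so the strengthening increment is
$(H-H_0)/C$. $C$ is material-specific; the default 3 is the classical
Tabor-style constraint factor and is always explicit in the interface,
because published analyses often use calibrated values that are not
recoverable here. Negative increments (softening) are flagged, not
rejected. `predicted_strength()` adds the increment to a base strength and
flags `fracture_before_yield` when the prediction exceeds a supplied
measured strength — the signature that the measured strength is
fracture-limited rather than slip-limited.

## Defect-population geometry

**Ellipse fitting** is the numerically stable partitioned formulation of
the direct least-squares conic fit with the ellipse constraint
$4ac - b^2 = 1$: points are centered and scaled, the scatter matrix is
split into quadratic and linear blocks, and the constrained eigenproblem is
solved on the reduced 3×3 system before converting to geometric
parameters. It is exact on noise-free contours, equivariant under rigid
motions, and errors cleanly on collinear or sub-5-point input. Orientation
is reported in $(-90°, 90°]$ from the +x (transverse) image axis, matching
the convention that $\theta = 0$ means a defect lying in the transverse
plane. Small low-eccentricity bias at high noise is inherent to direct
conic fits; the tests bound it at 0.2 nm point noise.

**Spacing** is center-to-center nearest neighbour (the operational
definition of "spacing" is rarely stated for micrograph data; center-based
is the primary choice, edge-to-edge — center distance minus mean radii —
is an option). **Density classing** counts neighbours within 50 nm and
splits at the field median. **Orientation profiles** bin defects by
shortest distance to the boundary polyline and report mean $|\theta|$ per
bin, with a Spearman correlation as a monotonicity diagnostic.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the chain consumes, with the seed an
explicit argument; every generator is a pure function of (spec, seed) and
restores the caller's RNG state.

**Curves.** The biogenic template is linear to yield, linearly hardening to
fracture at $\varepsilon_f$, then an abrupt drop; the geological template is
linear to yield, a single-step strain jump with a load drop to 70% of the
flow stress, an elastic-slope reload, and a flat plateau — a simplified
rendering of the retract/reload excursion a displacement-controlled
transducer performs during a slip avalanche. Defaults are the measured
cohort means (biogenic: E 34.4 GPa, σ_Y 1.16 GPa, ε_f 0.074; geological:
E 47.9 GPa, σ_Y 0.96 GPa, σ_f 0.47 GPa); `sample_curve_specs()` draws
per-pillar parameters from the measured means and standard deviations,
truncated away from unphysical combinations (failure strain below the
implied elastic limit). The hardening modulus of 4 GPa is chosen so the
default template reaches ≈1.32 GPa at failure. Noise is additive Gaussian
on stress (default sd 0.01 GPa) carried into the force channel; the strain
step defaults to 1e-4. Not emulated: thermal drift, frame compliance, tip
misalignment, load-controlled segments, partial unloads. Passing the
round-trip tests therefore shows the reduction is self-consistent and
robust to stationary Gaussian noise — not that it is robust to every
instrument artifact in real exports.

**Strengths** are inverse-CDF Weibull draws,
$\sigma = \sigma_{Y0}(-\ln(1-u))^{1/m}$.

**Defect fields** place centers on jittered square lattices (jitter sd 2%
of the pitch) in alternating high/low-density bands (pitch 10 nm / 32 nm,
band period 200 nm — the "several hundred nanometre" zone alternation seen
in longitudinal sections; a random-patch layout emulates transverse
sections), with ellipse sizes 5 × 2.5 nm semi-axes (5% relative scatter)
and inclinations following $\theta(d) = 35° e^{-d/50\,\rm nm}$ plus 2°
scatter, $d$ the distance to the boundary polyline at the domain's left
edge. The near-regular lattice is a deliberate idealization that makes the
per-zone mean spacing identifiable to a few percent; real defect fields are
more disordered, and the Poisson-field test covers that opposite extreme.
The decay law is chosen to reproduce the observed contrast (interior
inclinations below 5°, above 30° at the interface); the decay length 50 nm
is the package's own choice, as no measured profile was available.

## Problem sizes and numerical conventions

The test-suite and recovery experiments use: 100 noise-free parameter draws
and cohorts of 25–50 noisy curves (strain step 1e-4, ≈ 750–1100 samples per
curve); Weibull recovery at n = 1e4 (point estimates) and 200 replicates at
n = 25 (medians); 1000 random load axes for the Schmid bound; defect fields
of ≈ 400 × 400 nm (≈ 900 defects). These sizes make the estimator behavior
visible while keeping the full suite in the tens of seconds.

Conventions worth knowing: stresses in GPa, lengths in the module-native
units stated above; angles in degrees at the interfaces, radians
internally; equality tolerances in tests are relative unless stated; the
(i−0.5)/n plotting position, the 2% yield offset, μ = 0.3, β floor 0.1,
C = 3, and the 50 nm density-classing radius are all defaults, not
constants.

## Known limitations

* The β(θ) form and the constraint coefficient C stand in for unavailable
  material-specific calibrations; absolute wing-crack strengths and
  strengthening increments should be read as calibrated or parameterized
  quantities, with only their structural dependences parameter-free.
* No contact-mechanics modeling of the punch, no Oliver–Pharr indentation
  analysis (hardness values are consumed, not computed), no
  three-parameter or censored Weibull, no critical resolved shear
  stresses or dislocation dynamics, no image segmentation (contours are
  input), and no crack-path / finite-element simulation.
* The compression reduction assumes a single monotone loading ramp per
  record; hold segments are tolerated but multi-cycle protocols are not
  interpreted.
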