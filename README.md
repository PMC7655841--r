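# calcmech

Micromechanics of biogenic and geological calcite: micro-pillar compression
analysis, Weibull strength statistics, calcite slip-system crystallography,
and micromechanical models for the nanoscopic intracrystalline defects that
strengthen and toughen biomineral calcite.

Biogenic calcite — for instance the prismatic shell layer of the pen shell
*Atrina rigida* — embeds nanoscopic organic inclusions ("intracrystalline
defects", roughly 10 nm wide and 5 nm tall) inside single-crystal prisms.
These defects suppress the easy dislocation slip of pure calcite and
redirect failure into controlled micro-fracture. `calcmech` packages the
quantitative chain needed to analyze that behavior from uniaxial
micro-pillar compression experiments and defect micrographs, together with
seeded synthetic-data generators so every stage is testable end to end. It
is aimed at researchers in biomineral and small-scale ceramic mechanics.

## What it computes

**Compression reduction.** Raw force–depth records (`F` in mN, `δ` in nm)
from a tapered micro-pillar are converted to normalized engineering stress
and strain with a Sneddon-type substrate-compliance correction,

    ε_n = δ / h,     σ_n = ( 4/(π D₁ D₂) + (1 − ν²)/(D₂ h) ) · F,

and reduced to Young's modulus `E` (least-squares fit on a 50–95% stress
window), yield strength `σ_Y = 4F_Y/(π D₁²)` at the onset of nonlinearity,
maximum strength `σ_max = 4F_max/(π D₁²)`, elastic limit `ε_e`, failure
strain `ε_f` at the abrupt terminal fracture, displacement bursts `Δε`, and
post-burst flow strength `σ_f`. Cohorts are compared with two-sample
t-tests.

**Weibull statistics.** Yield strengths are fitted with the two-parameter
Weibull model `f = 1 − exp(−(σ_Y/σ_Y0)^m)` by linearized rank regression
(the classical Weibull plot) or maximum likelihood, with bootstrap
uncertainties.

**Crystallography.** The twin and slip systems of calcite — e-twinning
{-1 0 1 8}<4 0 -4 1> (3 systems, unidirectional), r-slip
{1 0 -1 4}<-2 0 2 1> (3), f-slip {-1 0 1 2}<2 -2 0 1> (6) — are enumerated
in Miller–Bravais indices for the hexagonal structural cell (a = 4.99 Å,
c = 17.06 Å) and ranked by Schmid factor `m = cos φ · cos λ` for any
uniaxial load. Under c-axis compression the three r systems are degenerate
at m = 0.49996 and resolve in the negative sense.

**Defect micromechanics.** A wing-crack model maps defect spacing `L` and
inclination `θ` to compressive strength,

    σ_y = (2π/11)^¼ · L^½ · σ_Y,c √(πa) / (20 β(θ) a),

with `a` the defect half-length and `σ_Y,c` the matrix strength; an
Inglis-type ratio quantifies the stress-concentration anisotropy of the
flattened defects; and a hardness contrast `H = H₀ + C Δσ_Y` yields the
precipitation-strengthening increment.

**Defect geometry.** Digitized contours are fitted with a direct
least-squares ellipse fit; populations are summarized by size/orientation
statistics, mean contours, nearest-neighbour spacings, and
inclination-versus-boundary-distance profiles.

## Worked example

```r
library(calcmech)

geom <- pillar_geometry(D1 = 2, h = 6, taper = 2.5)   # nominal FIB pillar
rec  <- generate_curve(curve_spec("biogenic"), geom, seed = 42)
reduce_curve(rec, geom)
#> Micro-pillar mechanical summary
#>   E        =   34.338 GPa (R^2 = 0.99576)
#>   sigma_Y  =    1.142 GPa (F_Y = 3.589 mN), eps_e = 0.0328
#>   sigma_max=    1.333 GPa (F_max = 4.187 mN)
#>   eps_f    =   0.0740 (abrupt terminal fracture)
```

The synthetic biogenic pillar was generated at the cohort means (E = 34.4
GPa, σ_Y = 1.16 GPa, ε_f = 0.074) with 0.01 GPa stress noise; the reduction
recovers them to within a percent or so.

```r
x <- generate_strengths(25, shape = 5.74, scale = 1.25, seed = 1)
fit_weibull(x, n_boot = 500, seed = 2)
#> Weibull strength fit (linearized, n = 25):
#>   modulus m = 6.472 +/- 0.85
#>   scale sigma_Y0 = 1.279 GPa +/- 0.0445
#>   R^2 = 0.96040
```

A 25-strength sample at the biogenic Weibull modulus 5.74 fits back to
m = 6.5 ± 0.9 — cohort-sized samples carry that much scatter, which is why
the recovery tests check medians over many replicates.

```r
head(rank_active_systems(c(0, 0, 1), load = "compression")[,
     c("family", "label", "schmid", "resolved_sense")], 3)
#>   family                 label    schmid resolved_sense
#> 1      r (1 0 -1 4) [-2 0 2 1] 0.4999568       negative
#> 2      r (-1 1 0 4) [2 -2 0 1] 0.4999568       negative
#> 3      r (0 -1 1 4) [0 2 -2 1] 0.4999568       negative
```

Compressing along the c-axis resolves the highest shear on the three
equivalent r rhombohedral slip planes (m ≈ 0.5, negative sense) — the slip
mode observed in geological calcite pillars.

```r
s <- calibrate_wing_crack(L_ref = 32, target = 0.96)   # anchor at geological strength
wing_crack_strength(32, beta_scale = s) - wing_crack_strength(10, beta_scale = s)
#> [1] 0.4233437
```

Crowding the defects from the nominal 32 nm spacing to the 10 nm of
high-density zones lowers the predicted strength by ~0.42 GPa.

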