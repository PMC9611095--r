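---
title: "Thermodynamics of mixed Langmuir monolayers: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of mixed Langmuir monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monolayermix)
```

## The measurement and the model

A Langmuir film balance compresses a monomolecular film spread at the
air/water interface and records surface pressure $\pi$ (mN/m, the drop in
surface tension caused by the film) against mean molecular area $A$
(Å²/molecule, interface area divided by the number of spread molecules).
For a two-component film at mole fractions $X_1 = 1 - X_2$ and $X_2$,
three quantities summarise the mixing thermodynamics at a common surface
pressure:

* the **additivity (ideal-mixing) line** $X_1 A_1 + X_2 A_2$, on which the
  mixed film's area falls if the components mix ideally *or* do not mix at
  all — the additivity rule cannot distinguish those two cases, which is
  why the package's corresponding verdict is the single label
  `ideal-or-immiscible`;
* the **excess molecular area**
  $A_{ex} = A_{12} - (X_1 A_1 + X_2 A_2)$, positive when the components
  repel (the mixed film is expanded), negative when they attract;
* the **excess Gibbs free energy of mixing**
  $\Delta G_{ex}(\pi^\ast) = \int_0^{\pi^\ast} A_{ex}\, d\pi$, converted
  to molar units with $N_A \times 10^{-23}$ J/mol per mN/m·Å² = 6.02214
  (1 mN/m × 1 Å² = 10⁻²³ J).

Film rigidity is summarised by the compressibility modulus
$C_s^{-1} = -A\,(\partial\pi/\partial A)$. The sign convention deserves a
note: the quantity is often *printed* without the minus sign, but on
compression $\partial\pi/\partial A < 0$, so the minus sign is required
for the conventional positive rigidity values; this package reports
positive moduli. Bands of $C_s^{-1}$ (in mN/m) give the usual 2D phase
reading: below 12.5 gaseous, 12.5–50 liquid-expanded (LE), 50–100 LE/LC
coexistence, 100–250 liquid-condensed (LC), above 250 solid-like. A dip
in $C_s^{-1}(\pi)$ between two maxima marks a first-order LE–LC
transition.

## The synthetic world

No public isotherm data accompany the motivating study, so the package
ships a generator whose defaults state, once, a world matching the
study's design; all tests and acceptance checks run against it.

* **Host lipid** (`eos_dmpc()`): a Volmer-type equation of state
  $A(\pi) = A_0 + kT/(\pi + \pi_c)$ with $A_0 = 40$ Å², $\pi_c = 5.7$
  mN/m and $kT = 428.2$ mN/m·Å² (that is $k_B \cdot 310.15\,$K in film
  units — 37 °C, the default and exposed as a parameter). This puts
  lift-off at $A_0 + kT/\pi_c = 115.1$ Å² with a soft gaseous shoulder
  reaching ~130 Å², the landmark shape of a fluid phosphatidylcholine
  monolayer at body temperature.
* **Non-spreading guest** (`eos_non_spreading()`): a water-soluble,
  drug-like compound that fails to form a monolayer; its record is pure
  sensor noise on a descending area ramp (130 → 20 Å²), and its area
  contribution to any analysis is 0 with an explicit `unattained` flag.
* **Low-collapse amphiphiles** (`eos_low_collapse(pi_max)`): bulky
  triacyl conjugates whose pure films top out near 6 or 8 mN/m. The cap
  is modelled as a collapse pressure (the pure film cannot be pushed
  past it) rather than a sigmoidal LE–LC step, because the described
  behaviour — a maximum pressure maintained on further compression — is
  a collapse plateau. A genuine LE–LC step is available separately via
  `pure_eos_params(plateau = list(pi_t, delta_A, width))`, which
  subtracts a logistic area loss centred at $\pi_t$.
* **Mixing rule**: the generator composes
  $A_{12}(\pi) = X_1 A_1(\pi) + X_2 A_2(\pi) + A_{ex}(\pi, X_2)$ with a
  symmetric first-order regular-solution excess
  $A_{ex} = 4 X_2 (1 - X_2)\, a_{ex}\, e^{-\pi/\pi_s}$. The factor 4
  normalises $a_{ex}$ to the equimolar excess at zero pressure; the
  exponential decay encodes the observation that mixing deviations fade
  as films are compressed. This yields the closed form
  $\Delta G_{ex}(\pi^\ast) = 6.02214 \cdot 4 X_2(1-X_2)\, a_{ex} \pi_s
  (1 - e^{-\pi^\ast/\pi_s})$ J/mol (limit
  $6.02214\, A_{ex} \pi^\ast$ as $\pi_s \to \infty$), the oracle every
  numerical stage is checked against. Defaults $a_{ex} = 5$ Å²,
  $\pi_s = 20$ mN/m put $\Delta G_{ex}$ in the few-hundred J/mol range
  typical of a weakly repulsive drug–lipid pair; they were chosen once
  and not revisited.
* **Noise**: i.i.d. Gaussian with $\sigma = 0.1$ mN/m on the pressure
  channel only (the blank-subphase tolerance of a clean film balance;
  barrier position is far more precise than the Wilhelmy sensor), clamped
  at $-3\sigma$. Mole fractions default to the dose series 0.015, 0.03,
  0.045, 0.06, 0.09, 0.12, 0.25, 0.50; target pressures to 10, 20,
  30 mN/m; the pressure grid to 0–35 mN/m at 0.1 mN/m, the sampling
  density of a slow (10 mm/min) compression.

What the generator does **not** emulate: collapse kinetics and
hysteresis, area-channel noise, asymmetric (composition-skewed) excess
terms, subphase pH/ionic effects, and multi-run replicates. A green test
therefore establishes correctness of the estimators on this stated
world, not robustness to every instrumental pathology. In particular,
the bimodal $\Delta G_{ex}$ maxima near $X_2 = 0.18$–0.25 reported for
strongly interacting triacyl conjugates require an asymmetric excess
model and are deliberately out of scope; the bimodal *detection* logic
is tested on constructed fixtures instead.

## Estimators and numerical choices

**Compression branch.** Analysis uses the compression run only: the
record is truncated at its global area minimum, then a running-minimum
pass enforces strictly decreasing areas. A backward area step within
`area_jitter_tol` (default 0.05 Å², barrier jitter) is merged into its
predecessor by averaging; larger steps are dropped. The operation is
idempotent and metadata-preserving.

**Area readout.** `area_at_pressure()` interpolates at the *first upward
crossing* of the target pressure along compression (the largest-area
crossing), which resolves plateau re-crossings and noise wiggles
deterministically; an unattained target yields area 0 plus a flag — this
0-area convention is also how a non-spreading pure component enters the
ideal-mixing line, one defensible choice for a case the additivity
construction leaves undefined. Inside the table-building functions the
branch's pressure channel is first conditioned by an order-2
Savitzky–Golay pass (window 25 points, shifted stencils at the record
ends): a pointwise crossing uses only two bracketing samples and would
otherwise inherit the full sensor noise amplified by $|dA/d\pi|$ (≈13
Å² per mN/m near lift-off). On noiseless data the conditioning is
inconsequential — all films of a study share the same pressure channel,
so readout shifts cancel identically in every excess quantity.

**Gibbs integration.** Two estimators, cross-validated against each
other:

* `method = "parts"` (default) integrates each film's
  $\int A\, d\pi$ term by parts over the measured points,
  $\pi^\ast A(\pi^\ast) - \int \pi\, dA$, holding the area constant
  below the first recorded pressure (the gaseous regime is nearly flat
  in area). The pressure readings enter weighted by the *exact*
  barrier-position increments, and the result is first-order insensitive
  to where the upper crossing falls. This reaches the information floor
  of a ±0.1 mN/m record: the 100-seed mean of $\Delta G_{ex}$ recovers
  the generator's closed form to better than 2% even for the smallest
  fraction, where a pointwise-readout trapezoid (whose crossing errors
  have a correlation length that grows as fast as smoothing shrinks
  their amplitude) is several times noisier.
* `method = "grid"` is the textbook composite trapezoid on a common
  pressure grid (default step 0.1 mN/m) with pointwise readouts, the
  integrand held constant below the common lift-off (first pressure
  above 0.3 mN/m = 3× the noise bound, since the measurable record
  starts at lift-off, not at $\pi = 0$). Its convergence is verified by
  10× grid refinement; both methods agree to well under 0.5% on clean
  data and are exactly zero at the pure endpoints.

**Differentiation.** $C_s^{-1}$ uses Savitzky–Golay local-polynomial
differentiation (window 11 points, order 3, both configurable) on a
uniform area grid, because raw finite differences explode under ±0.1
mN/m noise. Resampling onto that grid is by *bin averaging* of both
axes followed by interpolation — averaging divides the sensor noise by
√(points per bin), which plain interpolation would not. Small negative
moduli produced by noise are clamped to zero before phase labelling.

**Transition detection.** A qualifying transition is the deepest local
minimum of $C_s^{-1}(\pi)$ between two maxima of topographic prominence
≥ 5 mN/m. Long records are conditioned first (samples below 1 mN/m
discarded — below lift-off there is no film, only clamped noise;
0.25 mN/m bins; ±1.5 mN/m running mean), the minimum is refined by a
local quadratic fit so it is not quantised to the grid, and record
endpoints may act as flanking maxima: a film with no collapse inside the
recorded window has its condensed-branch modulus still rising at the end
of the record, so insisting on an interior right-hand maximum would miss
every such transition. With these choices a $\pi_t = 15$ mN/m plateau is
recovered within ±0.5 mN/m in 100/100 noisy seeds while 100/100 pure
Volmer records yield no detection.

**Miscibility verdict.** The by-eye reading of deviation plots is
quantified with two thresholds, both exposed: `tol = 0.5` Å² (roughly
the area scatter a ±0.1 mN/m sensor induces at the target pressures)
separates "within scatter" from a real deviation, and doubles as the
prominence gate when hunting for the two-maxima-with-minimum pattern.
The verdict table: all deviations below `tol` → `ideal-or-immiscible`;
a bimodal pattern at any pressure, *or* deviations of both signs (a
composition-dependent sign change likewise indicates domains rich in one
or the other component; the original verdict taxonomy leaves this case
open) → `partially-miscible`; otherwise `miscible-repulsive` or
`miscible-attractive` by the common sign. Extrema are only ever reported
at interior compositions: the excess curves are pinned to zero at
$X_2 = 0$ and $1$, so domain endpoints are not extrema of mixing
behaviour.

## Degenerate inputs and edge cases

Isotherms need ≥ 4 points, positive areas, and pressures above
$-3\sigma$. Pressures are clamped at 0 for analysis (blank noise).
A branch shorter than the smoothing window is an error for
$C_s^{-1}$; a target pressure the mixture never attains is an error for
$\Delta G_{ex}$ (for pure components it is a flagged 0). Ties at exact
grid hits return the tabulated point without interpolation. All study
products are sorted internally by mole fraction, making them invariant
to input file order.

## Known limitations

* The additivity rule cannot separate ideal mixing from immiscibility;
  the verdict says so explicitly.
* $\Delta G_{ex}$ for the smallest fraction (X₂ = 0.015) carries an
  irreducible ~35% single-record noise at σ = 0.1 mN/m; conclusions at
  such doses need replicate averaging (the package's estimator is at the
  data's information floor, so more smoothing cannot help).
* Phase bands are conventions; films near a band edge will flip labels
  under noise.
* The config format is a flat YAML subset (`key: value`, dotted nesting);
  full YAML documents are not parsed.
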