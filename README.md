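# monolayermix

Thermodynamic analysis of two-component Langmuir monolayers from surface
pressure–area (π–A) compression isotherms.

When an amphiphile film is compressed on a film balance, the recorded π–A
isotherm encodes how the molecules pack and interact. For a two-component
film (say, a phospholipid host and a drug-like guest at mole fraction
X₂), three standard quantities summarise the mixing behaviour:

- **Excess molecular area**
  `A_ex(π) = A₁₂ − (X₁A₁ + X₂A₂)` — the deviation of the mixed film's
  mean molecular area from the mole-fraction-weighted additivity line of
  the pure components at the same surface pressure. Positive values mean
  the components repel (film expansion), negative that they attract.
- **Excess Gibbs free energy of mixing**
  `ΔG_ex(π*) = ∫₀^π* [A₁₂ − (X₁A₁ + X₂A₂)] dπ`, converted to J/mol via
  6.02214 J·mol⁻¹ per (mN/m·Å²/molecule). Zero for ideal (or fully
  immiscible) mixtures.
- **Compressibility modulus**
  `Cs⁻¹ = −A (∂π/∂A)` — the in-plane rigidity of the film. Bands of Cs⁻¹
  classify the 2D phase (gaseous < 12.5 < LE < 50 < LE–LC < 100 < LC <
  250 ≤ solid, in mN/m), and a dip between two maxima marks a first-order
  LE–LC transition.

The package provides: a documented plain-text isotherm format with
readers/writers and compression-branch extraction; these three analyses
with noise-aware estimators; composition profiles and a rule-based
miscibility verdict; a command-line style pipeline; and a seeded
synthetic-isotherm generator (Volmer-type equation of state, optional
LE–LC plateau, regular-solution excess term, Gaussian sensor noise) whose
closed-form ground truth backs the entire test suite.

## Worked example

```r
library(monolayermix)

# a synthetic mixing study: fluid lipid host + non-spreading guest,
# guest fractions as in a typical dose series, repulsive excess term
cfg <- study_config(component1 = eos_dmpc(),
                    component2 = eos_non_spreading("guest"),
                    excess     = excess_params(a_ex = 5, pi_s = 20),
                    noise_sigma = 0.1, seed = 1)
isos <- generate_study_isotherms(cfg)

tab <- excess_profile_table(isos, pressures = c(10, 20, 30))
subset(tab, pressure_mN_per_m == 10 & x2 > 0 & x2 < 1,
       select = c(x2, a_excess_A2, dg_excess_J_mol))
#>       x2 a_excess_A2 dg_excess_J_mol
#> 4  0.015   0.2076992        18.12081
#> 7  0.030   0.3255881        26.35523
#> 10 0.045   0.4871878        39.76006
#> 13 0.060   0.6837473        56.64386
#> 16 0.090   0.9255004        72.93093
#> 19 0.120   1.2535969        97.19465
#> 22 0.250   2.2824961       170.94844
#> 25 0.500   3.0344903       232.70542

assess_miscibility(tab)
#> <miscibility assessment> verdict: miscible-repulsive
#>   pi = 10 mN/m: positive deviations, 1 interior extremum
#>   pi = 20 mN/m: positive deviations, 1 interior extremum
#>   pi = 30 mN/m: positive deviations, 1 interior extremum
```

The excess area is positive everywhere and largest at the equimolar
point; ΔG_ex grows with the integration pressure and peaks at X₂ = 0.5
(here 232.7 J/mol at 10 mN/m on one noisy record, against a closed-form
ground truth of 237.0 J/mol) — the signature of weak, symmetric repulsion between host
and guest. The verdict is "miscible-repulsive": deviations exceed the
0.5 Å² scatter tolerance, all with the same sign, with a single interior
maximum.

Phase behaviour of a single film:

```r
pl <- pure_eos_params(40, 5.7, 428.2,
                      plateau = list(pi_t = 15, delta_A = 12, width = 1))
iso <- generate_pure_isotherm(pl, noise_sigma = 0.1, seed = 1)
cc <- compressibility_curve(extract_compression_branch(iso))
detect_transition_pressure(cc)
#> [1] 15.00682
```

## Command line

```sh
Rscript -e 'monolayermix::cli_main()' full --out runs/demo --seed 1
Rscript -e 'monolayermix::cli_main()' analyze --in runs/demo/isotherms \
    --pressures 10,20,30 --out runs/reanalysis
```

`full` writes the simulated isotherms plus `ground_truth.csv`, one
`profile_pi<p>.csv` per target pressure, `excess.csv`, a
`compressibility_<film>.csv` per film, `assessment.json` and a
`manifest.json` that records every setting needed to reproduce the run.

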