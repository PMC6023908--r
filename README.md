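# memprobe

Quantitative analysis of small-molecule–membrane interactions, built for
studies that combine isothermal titration calorimetry (ITC), infrared
spectroscopy of lipid phase transitions, molecular-dynamics trajectory
post-processing and seedling phytotoxicity bioassays — the standard toolkit
for asking whether an amphipathic solute (for example a plant allelochemical
such as gramine or hordenine) partitions into, reorders or destabilises a
lipid bilayer, and whether that correlates with its biological activity.

## What it computes

**ITC partitioning.** Injecting lipid vesicles into a dilute solute solution
releases a heat per injection; the cumulative heat follows the partition
isotherm

    Σ δh_i = ΔH_D^{w→b} · V_cell · C_A⁰ · K·C_L⁰ / (1 + K·C_L⁰)

where K (L/mol) is the water→bilayer partition constant, ΔH_D^{w→b}
(cal/mol) the transfer enthalpy, and C_A⁰, C_L⁰ the solute and lipid
concentrations in the cell after each injection under the constant-volume
overflow dilution model. `integrate_thermogram()` turns a raw heat-flow
trace plus an injection schedule into per-injection heats (trapezoidal
integration over per-injection windows after median-anchored baseline
subtraction) and `fit_partition()` estimates (K, ΔH) by nonlinear least
squares, returning a classed fit with `print`, `summary`, `coef`,
`predict`, `plot` and `residuals` methods.

**FTIR thermotropics.** The CH₂ symmetric-stretch band near 2850 cm⁻¹
shifts upward as acyl chains melt. `pick_symmetric_ch2_peak()` locates the
band (parabolic sub-grid refinement), `build_melting_curve()` averages
replicates, and `fit_boltzmann()` fits

    ν(T) = ν_fluid + (ν_gel − ν_fluid) / (1 + exp((T − Tm)/w))

whose inflection is the phase-transition temperature Tm; `delta_tm()` gives
the shift caused by an additive with propagated uncertainty.

**Trajectory geometry.** From bilayer+solute coordinate frames (multi-frame
GRO or built in code) with a YAML role selection, the package computes
solute insertion depth along the bilayer normal (`depth_profile()`),
hydrogen-bond counts per solute classified by acceptor chemistry
(phosphate / ester / glycerol; geometric criterion d ≤ 0.35 nm,
H–D–A ≤ 30°; `hbond_timeseries()`), leaflet assignment, and orientation
distributions of solute bond vectors and ring-plane normals against the
bilayer normal (`bond_vector_angles()`, `ring_normal_angles()`).

**Bioassay statistics.** `summarize_bioassay()` and `anova_tukey_cld()`
give per-treatment means/SDs, growth-inhibition percentages versus the
control, randomized-block ANOVA, Tukey HSD (Tukey–Kramer under unequal
replication) and a compact letter display.

**Synthetic data.** Every stage has a ground-truth-known generator
(`gen_itc()`, `gen_melting_curve()`, `gen_membrane_traj()`,
`gen_bioassay()`), so the whole pipeline is testable without instruments:
at zero noise each analysis recovers its generator's truth to numerical
precision.

## Worked example

```r
library(memprobe)

# ITC: simulate a titration (28 x 10 uL of 10 mM lipid into 10 uM solute,
# 1.4565 mL cell) with 1% heat-flow noise, then fit the partition model
g <- gen_itc(K = 800, dH = -4000, flow_noise_frac = 0.01, seed = 42)
fit <- fit_partition(integrate_thermogram(g$thermogram, g$schedule))
print(fit)
#> Lipid partition model fit
#>   K  = 751.7 L/mol (SE 4.79)
#>   dH = -4026 cal/mol (SE 13.7)
#>   RSS = 0.114 ucal^2 over 28 injections

# FTIR: melting-temperature shift between two systems
fit_with    <- fit_boltzmann(gen_melting_curve(Tm = 20.17, width = 1.1,
                             noise_sd = 0.05, seed = 42)$curve)
fit_without <- fit_boltzmann(gen_melting_curve(Tm = 24.03, width = 0.8,
                             noise_sd = 0.05, seed = 43)$curve)
print(delta_tm(fit_with, fit_without))
#> delta Tm = -3.77 C (propagated SE 0.06)

# Bioassay: randomized blocks, Tukey letters
b <- gen_bioassay(seed = 42)
print(anova_tukey_cld(b$table))
#>                           treatment mean_mm sd_mm  n inhibition_pct letters
#> 1                           Control    23.0   1.9 14            0.0       a
#> 2                  Hordenine 0.5 mM    18.0   1.6  7           21.8       b
#> 3                    Hordenine 1 mM    17.1   3.3  7           25.7       b
#> 4                    Gramine 0.5 mM     9.0   2.9  7           61.0       c
#> 5 Gramine 0.5 mM + Hordenine 0.5 mM     8.0   1.5  7           65.1       c
#> 6                      Gramine 1 mM     6.9   1.1  7           70.1       c
#> treatment F(5, 37) = 131, p = 1.77e-22
```

The fitted K and ΔH are read as: a solute with K ≈ 800 L/mol partitions
spontaneously and exothermically into the bilayer; treatments that share a
Tukey letter do not differ significantly at α = 0.05; a negative ΔTm means
the additive destabilises the ordered gel phase of the lipid.

A single scripting entry point, `run_stage()`, runs any stage from a YAML
config and writes CSV/JSON reports (see `inst/cli/memprobe.R` for a thin
command-line wrapper).

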