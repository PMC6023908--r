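---
title: "Models and methods behind memprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

memprobe quantifies how small amphipathic solutes — plant alkaloids such as
gramine and hordenine are the motivating case — interact with lipid
bilayers, through four measurement channels: titration calorimetry,
infrared thermotropics, trajectory geometry and a seedling bioassay. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, what the synthetic-data generators do and do not
emulate, and the known limitations.

## The partition model for titration calorimetry

When vesicles are injected into a dilute solute solution, each aliquot of
lipid binds a share of the free solute and releases (or absorbs) heat. For
a solute that partitions between water and bilayer with equilibrium
constant $K$ (L/mol), the cumulative heat after reaching cell
concentrations $C_A^0$ (solute) and $C_L^0$ (lipid) is

$$\sum_k \delta h_k \;=\; \Delta H\, V_{cell}\, C_A^0\,
  \frac{K C_L^0}{1 + K C_L^0},$$

with $\Delta H$ the molar water-to-bilayer transfer enthalpy and
$V_{cell}$ the cell volume. `eval_partition_model()` is this expression;
`fit_partition()` estimates $(K, \Delta H)$ by nonlinear least squares
(Levenberg–Marquardt via minpack.lm).

**Dilution bookkeeping.** A perfusion-type cell keeps constant volume: each
injection of volume $v$ displaces a fraction $v/V$ of the *pre-existing*
contents while the aliquot itself is retained. After $i$ injections the
retained fraction of the original solution is $f_i = \prod_j (1 - v_j/V)$,
so $C_A^0(i) = C_A^{init} f_i$ and $C_L^0(i) = C_{syr}(1 - f_i)$. The
instrument-software convention for this correction varies; a no-dilution
variant ($C_A$ constant) is available via `dilute_solute = FALSE`. The
model uses the *total* lipid concentration; if only the outer leaflet of
intact vesicles is accessible on the experiment's timescale, set
`accessible_lipid_fraction = 0.5` (this simply rescales the fitted $K$).

**First-injection handling.** Titrations commonly start with a small (2 µL)
priming injection whose heat is unreliable and is excluded from fitting,
while its volume still dilutes the cell. Because the per-injection heats
are successive differences of the isotherm, excluding injection 1 means the
fitted cumulative series equals $H(i) - H(1)$, not $H(i)$; the fit
therefore references the model to the state after the last excluded
injection. Without this the (small but nonzero) heat of the priming
injection appears as a systematic offset and noiseless round trips no
longer close.

**Peak integration.** Injection $i$ owns the half-open time window
$[\,i\cdot s,\ (i{+}1)\cdot s\,)$ for spacing $s$; the sample at the next
injection start carries that injection's rising edge and belongs to the
next window. The baseline is interpolated linearly between anchors placed
at each injection start, valued at the median heat flow over the trailing
10% of the preceding inter-injection interval — the median resists
contamination by slowly decaying peak tails. Integration is trapezoidal.

**Initialisation and tolerances.** $\Delta H_0$ is the final cumulative
heat divided by $V_{cell} C_A^0$ (the saturation plateau), and $K_0$ is the
reciprocal lipid concentration at the injection reaching half the final
heat. $K$ is bounded below by 0. The optimiser runs on the microcalorie
scale with tight convergence tolerances (`ftol = 1e-15`, `ptol = 1e-13`,
generous iteration budget): weakly partitioning solutes
($K \sim 10$ L/mol) produce nearly linear isotherms on which $K$ and
$\Delta H$ are separated only by a percent-level curvature, and default
stopping rules quit before resolving it. An all-zero heat series is
reported as non-identifiable (`converged = FALSE`) rather than an error.

## The Boltzmann sigmoid for chain melting

The position of the methylene symmetric-stretch band ($s\nu_{CH_2}$, near
2850 cm⁻¹) reports acyl-chain conformational order and rises by ~2–3 cm⁻¹
across the gel → liquid-crystalline transition. The band position is
located as the absorbance maximum inside a window (default 2840–2865 cm⁻¹,
which excludes the antisymmetric band at ~2920 cm⁻¹), refined by a
three-point parabolic interpolation that can move the estimate at most one
grid step — on the instrument's 2 cm⁻¹ grid this gives roughly
±0.05 cm⁻¹. A maximum on the window edge is flagged, not refined.

The melting curve $\nu(T)$ is fitted with the four-parameter logistic

$$\nu(T) = \nu_f + \frac{\nu_g - \nu_f}{1 + e^{(T - T_m)/w}},$$

whose inflection $T_m$ is the phase-transition temperature; $\nu_g$,
$\nu_f$ are the gel/fluid asymptotes and $w > 0$ the transition width.
The exact parameterisation of "a Boltzmann fit" is a convention choice;
this one makes $T_m$ the inflection directly. Starting values: asymptotes
from the data extremes, $T_m$ at the half-height crossing, $w_0 = 1$ °C.
A fit is reported unconverged unless it yields a rising sigmoid
($\nu_f > \nu_g$) with $T_m$ inside the data range; widths collapsing
below a twentieth of the grid step are flagged step-like. $T_m$ is carried
at full precision and echoed at two decimals in reports. The shift
$\Delta T_m = T_m(\text{with}) - T_m(\text{without})$ combines the two fit
uncertainties in quadrature — the quoted uncertainties are treated as fit
standard errors, not replicate SDs.

## Trajectory observables

The bilayer normal is fixed to the z axis (the simulation convention);
there is no frame-wise normal refit. All displacements use the
minimal-image convention per axis, molecules are made whole across the
periodic boundary before centre-of-mass computation, and masses come from
a built-in element table keyed by the first letter of the atom name
(overridable in the selection config — required for united-atom beads
whose names do not start with their element).

- **Depth**: per frame, the mass-weighted z centre of mass of all lipid
  atoms defines the bilayer centre; the reported depth per group is the
  mean absolute wrapped z offset of solute molecule COMs, phosphate atoms,
  and per-lipid glycerol-group COMs. Wrapping bounds every depth by half
  the box height.
- **Leaflets**: a lipid is upper or lower by the sign of its phosphate's
  wrapped z offset from the bilayer centre. A one-sided distribution
  triggers a warning (not a bilayer).
- **Hydrogen bonds**: the geometric criterion is donor–acceptor distance
  ≤ 0.35 nm *and* hydrogen–donor–acceptor angle ≤ 30°, the de-facto MD
  community default; both thresholds are parameters. Counts are classified
  by acceptor chemistry (phosphate, ester, headgroup-glycerol oxygens),
  include both donation directions where the selection defines them, and
  are normalised per solute. Trailing-window means (e.g. the last 100 ns)
  summarise the converged regime.
- **Orientation**: the angle between a configured solute bond vector (or
  the normal of a ring-atom triplet) and +z, pooled over solutes and
  frames into 2°-bin histograms normalised to probability per degree.
  Solutes in the two leaflets produce supplementary-angle populations
  ($\theta$ and $180° - \theta$); `fold = TRUE` maps them onto one mode.
  Which atoms define the vectors for a given solute is an interpretation
  the user must supply (for gramine-like solutes a natural choice runs
  from the substituted indole carbon to the protonated amine nitrogen;
  for hordenine-like solutes from the phenol oxygen to the amine
  nitrogen); the defaults in the synthetic generator are schematic.
  Zero-length vectors and collinear triplets are skipped and counted.

## Bioassay statistics

The experimental unit is the dish (a filter paper with ~75 seeds): the
analysis operates on per-dish mean root lengths, matching a design with 7
replicate dishes per treatment and the control plated twice per block (14
replicates, one treatment level). The model is a two-way fixed-effects
ANOVA (treatment + block); with incomplete blocks the function either
errors listing the empty cells or, on request, falls back to one-way.
Pairwise comparisons use the studentized-range distribution with the ANOVA
residual mean square and Tukey–Kramer standard errors under unequal
replication. The compact letter display is built by insert-and-absorb:
starting from one group holding all treatments, each significant pair
splits every group containing both members, and subset groups are
absorbed; treatments share a letter iff they are not significantly
different (verified in tests against an exhaustive pairwise oracle and
against multcomp's display). A perfectly fitting degenerate design (zero
residual MS) classifies equal means as non-significant and unequal means
as significant rather than producing undefined statistics. Inhibition is
$100\,(\bar x_{ctrl} - \bar x_{trt})/\bar x_{ctrl}$, reported to one
decimal.

## What the generators emulate — and what they do not

Each generator emits a machine-readable truth record, and each analysis
run on its generator at zero noise recovers that truth to numerical
precision; with a fixed seed the output is identical across runs.

- `gen_itc()` renders per-injection heats (successive isotherm differences
  under the default 2 µL + 28 × 10 µL, 600 s schedule into a 1456.5 µL
  cell: 10 mM lipid into 10 µM solute) as exponential pulses with
  $\tau = 30$ s whose areas equal the heats. Only the area matters
  downstream; instrument feedback dynamics, heat-of-dilution blanks and
  drift are not modelled. Noise can be applied to the heat-flow trace
  (absolute, or relative to the peak amplitude — the 1%-of-peak condition
  used in the acceptance checks) or to the per-injection heats directly.
- `gen_melting_curve()` samples the Boltzmann sigmoid (defaults near a
  phosphatidylcholine transition: $T_m = 23.69$ °C, $w = 0.8$ °C,
  asymptotes 2850.4/2852.9 cm⁻¹) on a 3/2/1 °C grid refined around
  $T_m$, three replicates, Gaussian band-position noise; optionally full
  Gaussian-band spectra (with a decoy band at 2920 cm⁻¹) for the peak
  picker. Real band shapes, baselines and atmospheric lines are not
  emulated.
- `gen_membrane_traj()` builds a schematic two-leaflet slab (128 pseudo-
  lipids, 32 rigid pseudo-solutes at a 4:1 lipid:solute ratio by default)
  in which only the measured observables are controlled: solute COM depth
  (per frame, enabling adsorption ramps), mirrored bond-vector and
  ring-plane tilts, and a per-frame hydrogen-bond schedule realised by
  moving dedicated acceptor atoms into or out of the geometric criterion.
  There is no force field, water, or thermal motion: passing tests show
  the *analysis* is correct, not that any physical system behaves this
  way.
- `gen_bioassay()` draws per-dish means as
  control mean × (1 − effect) + block effect + noise, truncated at zero.
  Default effects span the 21–73% inhibition range typical of published
  gramine/hordenine assays (control 22.6 mm), with block SD 1.0 mm and
  dish SD 1.5 mm — chosen once as realistic magnitudes for ~1.1–2.6 mm
  observed treatment SDs. Seedling-level variation within a dish is not
  modelled, consistent with the dish being the unit of analysis.

## Problem sizes and reproducibility checks

The test suite and `scripts/acceptance.R` exercise: noiseless partition
recovery at $K \in \{10, 10^2, 800, 5\times10^3, 10^5\}$ L/mol (worst-case
relative error ~$10^{-5}$, the residue of trapezoidal integration at 1 s
sampling); 100 noisy titrations at 1% heat-flow noise (≥ 90% of fits
within 10% of the true $K$); 200 melting-curve fits at 0.05 cm⁻¹ noise on
15 temperatures × 3 replicates (≥ 95% within 0.15 °C of the true $T_m$);
hydrogen-bond equality with a brute-force all-pairs oracle on 50 random
frames; constructed depths to $10^{-6}$ nm and tilt modes to 0.5° (the
exactness checks use 0.5° histogram bins, since a mode can only be located
to half a bin); and 500 null bioassays for the Tukey family-wise error
(held at $\alpha$ within Monte-Carlo error). These sizes were chosen to
give stable Monte-Carlo estimates while keeping a full run in tens of
seconds.

## Known limitations

- One-site partitioning only: no multi-site binding, no kinetic modelling,
  no heat-of-dilution reference subtraction beyond the per-window baseline.
- The melting analysis uses the symmetric band only; second-derivative or
  deconvolution band analysis and van't Hoff thermodynamics are out of
  scope.
- The bilayer normal is assumed global and fixed; undulating or curved
  membranes would need a local normal.
- GRO coordinates carry 0.001 nm precision; exactness-grade comparisons
  should use in-memory frames, as file round trips quantise coordinates.
- Tukey's procedure assumes homoscedastic, approximately normal residuals;
  blocks are fixed effects (no mixed models).
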