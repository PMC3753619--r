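---
title: "Two-state melting thermodynamics of duplex DNA next to four-stranded structures"
author: "duplexmelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state melting thermodynamics of duplex DNA next to four-stranded structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmelt)
```

# The problem and the model

Putative G-quadruplex-forming sequences (four runs of three or more
guanines separated by short loops) and their C-rich complements, which can
fold into i-motifs at acidic pH, frequently border duplex DNA in promoter
and telomeric regions. Whether those four-stranded structures can form *in
vivo* depends in part on how much folding free energy they cost the
neighbouring duplex. The experimental probe is thermal melting: a short
duplex carrying a quadruplex- or i-motif-forming overhang is denatured
slowly while absorbance (260 nm for the duplex, 295 nm for the quadruplex)
or ellipticity (280 nm) is recorded, and the duplex transition is analysed
under the **two-state** assumption — only fully folded and fully unfolded
species are populated, so a single folded fraction $\theta(T)$ describes
the curve.

All thermodynamics in the package use the **association** convention, so a
stable duplex has negative $\Delta H$ (kJ·mol⁻¹) and $\Delta S$
(J·K⁻¹·mol⁻¹), matching the sign convention of tabulated melting studies.
With $R = 8.314$ J·K⁻¹·mol⁻¹:

* unimolecular transitions (hairpin, quadruplex, i-motif):
  $K = \theta/(1-\theta)$ and $T_m = \Delta H/\Delta S$, independent of
  concentration;
* bimolecular duplexes formed from two different strands at equal
  concentration: with $C_T$ the **total** single-strand concentration
  (3 µM per strand gives $C_T = 6$ µM — stated explicitly because the
  literature is inconsistent about factors of two),
  $K = \theta\,/\,\big((1-\theta)^2\,C_T/2\big)$, and
  $T_m = \Delta H\,/\,(\Delta S + R\ln(C_T/4))$;
* $\Delta G^\circ = \Delta H - T\Delta S$ reported at $T = 298.15$ K.

`thetaFromParams()` inverts the mass-action law in the cancellation-free
form $\theta = 2a/(2a + 1 + \sqrt{4a+1})$, $a = K C_T/2$, so it is stable
from $\theta \approx 0$ up to the overflow region far below $T_m$, where
$\theta$ clamps to 1. Self-complementary duplexes and unequal strand
mixtures are out of scope (the molecularity type is extensible).

# From a raw trace to van't Hoff parameters

A recorded run contains several monotone temperature ramps (the default
protocol is 90→10→90→10 °C, i.e. cooling/heating/cooling);
`splitRamps()` separates them at direction reversals and discards segments
shorter than 20 points. Each ramp is then analysed independently
(replicates are aggregated afterwards, never pooled before fitting):

1. **Baselines** (`fitBaselines`). Ordinary least-squares lines over the
   outer 15% of the temperature span by default; both windows are
   overridable, which is required for traces containing a second
   transition. The low-temperature line is always the folded plateau,
   which makes the same code handle hyperchromic 260 nm duplex melts and
   hypochromic 295 nm quadruplex melts without a sign switch.
2. **Folded fraction** (`fractionFolded`).
   $\theta(T) = (U(T) - s(T))/(U(T) - F(T))$, clipped to $[0,1]$;
   coinciding or crossing baselines raise an error rather than returning
   nonsense. $\theta$ is invariant under gain/offset changes of the signal.
3. **Melting temperature** (`meltingTemperature`). The profile is smoothed
   with a centered moving-window quadratic (Savitzky–Golay, 11 points,
   suited to the 0.25 °C instrument grid); $T_m$ is the first
   $\theta = 0.5$ crossing in the heating direction by linear
   interpolation (multiple crossings warn and use the first), or the
   parabolic-refined extremum of $d\theta/dT$.
4. **Van't Hoff regression** (`vantHoffFit`). Points with
   $0.15 < \theta < 0.85$ (configurable) enter an OLS fit of $\ln K$
   against $1/T$: $\Delta H = -R\,\text{slope}$, $\Delta S =
   R\,\text{intercept}$. The window default reflects standard practice —
   outside it the signal is baseline-dominated and $\ln K$ blows up. At
   least 5 in-window points are required; $R^2$ is reported.
5. **Direct two-state refinement** (`fitTwoState`, run by default from
   `analyzeCurve`). The two-stage analysis inherits a small bias from
   plateau contamination of the baseline windows: the fitted baseline
   absorbs the sigmoid tail, and the error propagates into the regression
   slope (on noise-free synthetic curves we measure up to ~1–2% in
   $\Delta H$). The refinement therefore refits the complete curve,
   $s(T) = \theta(T)F(T) + (1-\theta(T))U(T)$ with all six parameters
   free, by Levenberg–Marquardt least squares starting from the linear
   estimates — the approach modern melting-fit tools take. On noise-free
   curves this recovers generating parameters to numerical precision;
   `refine = FALSE` gives the plain two-stage analysis.

Diagnostics mirror how such experiments are validated: `hysteresis()`
compares heating and cooling $T_m$ (beyond 1 °C the melt is not at
equilibrium and van't Hoff analysis is invalid); `transitionSeparation()`
enforces the ≥ 25 °C duplex/quadruplex separation that duplex-only
analysis needs; `molecularityTest()` regresses $1/T_m$ on $\ln C_T$, whose
slope is $R/\Delta H$ for a bimolecular duplex and 0 for a unimolecular
structure (classification threshold: half the expected magnitude).

For traces with a second, higher-melting transition the supported protocol
is a temperature cutoff: `trimCurve()` the 260 nm trace below the
quadruplex transition (in practice duplex $T_m$ + 20 °C when the
separation is ≥ 25 °C) and analyse the rest as a single melt. Automatic
deconvolution of overlapping transitions is deliberately not attempted —
the experiments the package targets are designed to avoid overlap.

# Replicate statistics and destabilization measures

`aggregateReplicates()` reports mean and **sample** standard deviation
(1σ) of $T_m$, $\Delta H$, $\Delta S$, $\Delta G^\circ$ over replicate
ramps; $\Delta G^\circ$ is averaged over per-replicate values rather than
recomputed from mean $\Delta H/\Delta S$. Construct-vs-reference measures:

* $\Delta\Delta G^\circ = \Delta G^\circ_\text{construct} -
  \Delta G^\circ_\text{reference}$, **positive = destabilized**, with
  quadrature $\sigma = \sqrt{\sigma^2_\text{ref} + \sigma^2_\text{con}}$;
* $\Delta T_m = T_{m,\text{ref}} - T_{m,\text{con}}$ (positive = melts
  lower), quadrature σ;
* relative destabilization $100\,\Delta\Delta G^\circ / |\Delta
  G^\circ_\text{ref}|$ with relative quadrature σ — the measure of choice
  across pH, where the reference duplex itself weakens.

Significance uses a one-way fixed-effects ANOVA over per-replicate
$\Delta G^\circ$ values followed by construct-vs-reference contrasts on
the pooled residual variance. The package deliberately adds no
Tukey/Dunnett machinery: contrasts are Bonferroni-corrected,
$p_\text{adj} = \min(1, m\,p)$, where the family $m$ is the set of
contrasts sharing one reference (i.e. everything shown together in one
figure); the family definition is configurable because other groupings
are defensible. Stars follow the caption convention (\*, \*\*, \*\*\* at
0.05, 0.01, 0.001). If every replicate value is identical there is
nothing to test and $p = 1$ is returned directly.

# What the synthetic generator emulates

`simulateCurve()` produces
$s(T) = \theta(T)F(T) + (1-\theta(T))U(T) + \mathcal N(0, \sigma)$ on the
instrument grid (10–90 °C, 0.25 °C steps — matching a 0.25 °C/min ramp
sampled once per minute) with linear sloping baselines; defaults mimic a
3 µM/strand duplex at 260 nm (~0.59 A folded plateau, ~20%
hyperchromicity). `simulateMeltTrace()` produces the cool–heat–cool
time-ordered trace, with an optional artificial $T_m$ offset between
directions to exercise the hysteresis diagnostic (default 0: slow ramps
melt at equilibrium). `simulateTwoTransition()` superimposes a
higher-melting unimolecular quadruplex: a minor additive contribution at
260 nm (default amplitude one sixth of the duplex transition — quadruplex
melting changes 260 nm absorbance only modestly, which is exactly why the
quadruplex is monitored at 295 nm, where it dominates with
folding-increases-signal orientation). `simulateConcentrationSeries()`
feeds the molecularity test. Noise is additive i.i.d. Gaussian on the
signal — the simplest model consistent with smooth instrument traces —
and reproducible by seed.

What the generator does **not** emulate, and hence what passing round
trips cannot demonstrate about real data: kinetic (rate-limited) melting,
pH-dependent i-motif protonation equilibria (pH enters only as metadata),
baseline curvature, correlated instrument drift, and heat-capacity
changes ($\Delta C_p = 0$ throughout, as in the tabulated analyses).

## Validation conditions

The core oracle is the noise-free round trip: generator → full pipeline →
generating parameters. The named working point ($\Delta H = -336.4$
kJ·mol⁻¹, $\Delta S = -902.0$ J·K⁻¹·mol⁻¹, $C_T = 6$ µM, $T_m \approx
58.8$ °C) is checked to 1% in $\Delta H$ and 0.2 °C in $T_m$, and a grid
of 50 random parameter sets ($\Delta H \in [-450, -150]$ kJ·mol⁻¹, $T_m
\in [35, 65]$ °C) is held to the same tolerances. Grid draws are accepted
only when both plateaus genuinely lie inside the measured range — the
true $\theta$ must be within 0.002 of its asymptote across both baseline
windows, i.e. plateau contamination below the 0.2%-of-amplitude noise
level the generator assumes. This is a study-design constraint, not a
numerical convenience: a shallow transition melting near the bottom of
the instrument range leaves no folded plateau in the data, and no
baseline method can recover what was never measured; the corresponding
experiments are the ones a melting study redesigns. Stochastic checks
(replicate scatter, family-wise error of the Bonferroni procedure over
10,000 null simulations, detection of a 15 kJ·mol⁻¹ effect at σ = 1.5
kJ·mol⁻¹, n = 3) run at fixed seeds; problem sizes were chosen so the
whole suite completes in about a minute.

# Sequence scanning and oligo utilities

`scanQuadruplex()` implements the canonical putative-quadruplex grammar —
`nRuns = 4` maximal G-runs of `minRun = 3` or more, loops of 1–7 nt —
as a run-window scan rather than a regex: maximal G-runs are located
first, then windows of four consecutive runs whose gaps satisfy the loop
bounds are reported. This yields the run/loop decomposition directly and
reads one long G-tract as a single run instead of letting a regex split
it into run–loop–run. Default reporting is greedy, leftmost,
non-overlapping (deterministic output); `allOverlaps = TRUE` enumerates
every qualifying window, and that exhaustive set is exactly
strand-symmetric with `scanImotif()` on the reverse complement — the
greedy selection is not, since it scans left to right on each strand.
Coordinates are 1-based inclusive in R (the Bioconductor convention);
BED output converts to 0-based half-open.

Extinction coefficients at 260 nm are additive over a shipped monomer
table (A 15.4, C 7.4, G 11.5, T 8.7 mM⁻¹cm⁻¹ — classical
nucleoside-monophosphate values, user-overridable). Additivity ignores
nearest-neighbour hypochromicity, so agreement with published per-oligo
values is expected only within a few percent, and the G-richest
quadruplex constructs deviate the most; the bundled table
`referenceOligos()` stores the published values themselves for exact
work.

# End-to-end configuration

The YAML experiment config binds the stages: each pair carries label,
molecularity, per-strand concentration (mol/L; the package converts to
total $C_T$ internally), pH, trace files and an optional reference label.
`simulateFromConfig()` writes deterministic trace CSVs for pairs with a
`simulate` block; `runExperiment()` analyses every ramp, aggregates
replicates and compares constructs against their references;
`writeResultTSV()`/`writeFitsJSON()` serialize results (temperatures in
°C, energies in kJ·mol⁻¹, entropies in J·K⁻¹·mol⁻¹ everywhere).

```{r, eval = FALSE}
cfg <- simulateFromConfig("experiment.yaml", "traces", seed = 1)
res <- runExperiment(cfg, dir = "traces")
res$comparisons
```

# Numerical choices and limitations

* Kelvin internally for all thermodynamics, °C at every user interface.
* $\theta$ clipping to $[0,1]$ happens before windowing, so baseline
  noise cannot produce undefined $\ln K$; non-finite $\ln K$ inside the
  window is still an error, not a silent drop.
* Degenerate inputs fail loudly: constant-temperature traces, coinciding
  baselines, profiles that never cross $\theta = 0.5$, fewer than three
  concentrations in the molecularity test, fewer than two replicates per
  ANOVA group.
* Ties/multiplicity: first 0.5-crossing in the heating direction wins,
  with a warning rather than a failure.
* The `top1::GQ1` row of the bundled thermodynamic table is internally
  inconsistent as published (its $\Delta H/\Delta S$ imply a $\Delta
  G^\circ$ near −77.8 kJ·mol⁻¹, not the listed −52.7) and is flagged
  `consistent = FALSE`; it is excluded from model-consistency checks and
  intentionally left uncorrected.
* No global multi-curve fitting, no calorimetric (model-free) $\Delta H$,
  no $\Delta C_p$ corrections, no nearest-neighbour sequence-based $T_m$
  prediction, no folding-topology prediction or G4Hunter-style scoring.
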