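---
title: "Steady-state interventions and sensitivity analysis for SBML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state interventions and sensitivity analysis for SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlsens)
```

## The intervention pipeline

`sbmlsens` studies how a biochemical model responds to a perturbation
applied *after* the system has reached a baseline. The pipeline never
edits a running simulation and never uses SBML Event semantics. Instead
it manufactures documents:

1. **Design** — a sampling scheme assigns values to a chosen subset of
   parameters or species initial concentrations.
2. **Generation** — one SBML file per design row, differing from the base
   model only in the designed targets (`generate_models`, plus a manifest
   CSV keyed by filename).
3. **Solve** — each file is integrated to a time "sufficient for all
   populations to become stable" (`solve_model`, or any external SBML
   solver producing a `time`-headed CSV).
4. **Snapshot** — `snapshot_from_trajectory` copies the base document and
   sets every species initial concentration to the trajectory value at a
   chosen time; `"auto"` takes the last time point, so ensembles whose
   members settle at different times need no per-model bookkeeping. The
   chosen time is recorded in an annotation.
5. **Intervention** — `apply_interventions` sets a target to a discrete
   value (`SET`) or to a multiple of its final-state value (`SCALE`),
   records the change in an annotation, and leaves everything else
   untouched.
6. **Analysis** — responses measured on the re-solved models are joined
   to the design and summarised by the statistic matching the technique.

Separating these stages keeps the baseline interpretable: every
intervention lands on an explicit, inspectable state, and the generated
files run on any SBML-compliant solver.

## The SBML subset

The reader/writer supports SBML L2V4 and L3V2 core: compartments,
species, global parameters, and reactions whose kinetic laws use the
MathML arithmetic subset (`plus`, `minus`, `times`, `divide`, `power`,
`ci`, `cn`). This is exactly the surface the pipeline touches. Species
initialisation is normalised to **concentration** on read
(`initialAmount` is divided by the compartment size) because
interventions and the solver operate on concentration fields. Numbers are
serialised with 17 significant digits, so write-then-parse recovers every
double bit-for-bit — an ensemble member's identity is its parameter
values, and any rounding would silently corrupt the manifest join.

Constructs outside the subset are handled loudly, never silently: events
are preserved verbatim but never modified (with a warning); rules,
function definitions and constraints are recorded and warned about;
`piecewise` and other non-arithmetic MathML raise an error. Local
kinetic-law parameters are inlined by value with a warning. What the
package does not model, it does not preserve when rewriting — the
warnings are the contract.

## Sampling designs

* **Local sweeps** take each target in turn as the factor of interest,
  assigning `increments` evenly spaced values across its range (endpoints
  included) with all other targets at baseline.
* **Latin-hypercube sampling** stratifies each column into `n`
  equal-width strata, one sample per stratum, stratum order an
  independent uniform permutation per column, within-stratum position
  uniform. No correlation-reduction optimisation beyond stratification is
  applied: stratified permutation is the canonical baseline, and the
  statistics downstream (PRCC) are rank-based and robust to the residual
  correlation of a random LHS.
* **eFAST designs** drive the factor of interest along
  `x(s) = min + (max − min)(½ + asin(sin(ω s + φ))/π)` with
  `ω_max = ⌊(N_s − 1)/(2M)⌋` and interference factor `M = 4`;
  complementary factors get low frequencies cycling `1..⌊ω_max/(2M)⌋`
  (with `N_s = 65` that band collapses to frequency 1 — the price of the
  smallest valid sample size). Phases are uniform per factor and curve;
  `N_s` must be odd and at least 65 so the spectrum at the analysed
  harmonics is alias-free. A **dummy factor**, sampled like the others
  but connected to nothing, is included by default: its indices estimate
  the bias floor, and factor significance is a two-sample t test against
  it across resample curves.

All designs are deterministic under a seed, and the generator restores
the caller's RNG state.

## Statistics

**PRCC.** All columns and the response are rank-transformed; the PRCC of
target `j` is the correlation of the residuals of `rank(x_j)` and
`rank(y)` after linear regression on the ranks of the other `k − 1`
targets. Significance uses `t = ρ √((n − 2 − (k − 1))/(1 − ρ²))` on
`n − 2 − (k − 1)` degrees of freedom. Raw p-values are reported by
default (a Bonferroni flag exists) — the sensible default when the output
is a ranked bar chart rather than a hypothesis test. Constant columns
yield a flagged missing value rather than a fabricated zero.

**eFAST.** Within each factor-of-interest block and curve, power at
integer frequencies is estimated by direct cosine/sine projection on the
block's `s` grid; `S_i` sums power at `ω_max, 2ω_max, …, M·ω_max` over
total variance, and `ST_i = 1 −` (power in the complementary band
`1..⌊ω_max/2⌋`)/total. Indices are averaged across curves. On the
Ishigami benchmark with `N_s = 257` the first-order indices agree with an
independent pick-freeze Monte-Carlo Sobol oracle within 0.03 (asserted at
±0.05 in the acceptance suite).

## The solver

Kinetic laws are compiled once into a plain R function (constants
inlined, byte-compiled) computing the stoichiometry-weighted net rates
divided by compartment size. Integration is embedded Dormand–Prince 5(4)
with proportional step control, relative tolerance 1e-8 and absolute
1e-10. The *output* grid `0, step, …, t_end` is pure sampling: internal
steps land exactly on grid times and subdivide adaptively in between, so
halving the output step changes shared-grid values only within
integration tolerance. Non-finite derivatives or step underflow raise an
error carrying the failure time — a trajectory either exists completely
or not at all.

**Steady state** is declared at the earliest grid time `t*` such that
every species stays within `rel_tol · max(|x(t*)|, 10⁻⁹)` of `x(t*)`
throughout `[t*, t* + window]`. The windowed sup-norm is this package's
definition (upstream tooling only assumed "a length of time sufficient
for all populations to become stable"); the absolute floor `10⁻⁹` keeps
the criterion meaningful for species decaying to zero.

## The Th17/Th1 case study

The case-study model tracks seven species in one unit compartment over
hours: T-bet mRNA `T`, RORγt mRNA `R`, polarising cytokines `C1` and
`C17`, receptor X, the receptor–cytokine complex `XC`, and cytokine
`CX`. The transcription-factor core is the standard
autoactivation/mutual-inhibition motif with saturating cytokine
induction:

$$\frac{dT}{dt} = \beta_1
  + \frac{a_1 T^2}{(k_1^2 + T^2)(1 + R/k_2)}
  + \frac{a_3 C_1}{(k_3 + C_1)(1 + R/k_4)}
  \;[+\, a_6\, \mathrm{XC}/(k_{10} + \mathrm{XC})]\; - \mu_1 T$$

with the symmetric equation for `R` (parameters `a_2, k_5, k_6, a_4, k_7,
k_8, \mu_2`; the bracketed term appears with sign − and a factor `R` in
the inhibition variant, see below). Cytokines decay first-order
(`\mu_3, \mu_4`); receptor X forms at `a_5 R/(k_9 + R)`, decays at
`\mu_7`, and binds `CX` at mass-action rate `b_1` into `XC`, which decays
at `\mu_8` while `CX` decays at `\mu_9`.

The exact equations are a **reconstruction**: the lineage (Hill
autoactivation, mutual inhibition, receptor upregulation driven by the
Th17 factor) is established in the T-cell modelling literature, but the
specific published coefficient tables for this model are not available.
Two choices deserve explanation:

* **Basal transcription `β1`, `β2`.** The phenotype rule is a fold change
  over baseline, which is degenerate at a zero baseline, so both
  transcription factors get a small constitutive production
  (`β = 0.001`), placing the basal fixed point at `T₀ = R₀ ≈ 0.011`.
  Bistability then requires the low fixed point to survive even with the
  competitor absent, i.e. `μ² ≥ 4 β a / k²` for the small-`T` quadratic —
  satisfied by an order of magnitude at the defaults
  (`a = 1, k = 1, μ = 0.1`).
* **The ±a₆ term.** The two candidate mechanisms are stated as a rate
  `+a₆` (T-bet promotion) or `−a₆` (RORγt inhibition). A literal negative
  production term can push concentrations below zero, so the inhibition
  variant is implemented as saturable enhanced *degradation*
  `−a₆ R·XC/(k₁₀ + XC)` while promotion keeps the absolute production
  form `+a₆·XC/(k₁₀ + XC)`. The asymmetry is deliberate: it preserves
  positivity, and it preserves the intended biology (an inhibitor cannot
  remove transcript that is not there).

Default rates (per hour, concentrations in arbitrary units) were chosen
analytically from these bistability conditions and then *verified*, not
fitted, by `scripts/tune-defaults.R`; they were not revisited after the
test suite was written. Stimuli are `SET` interventions on initial
concentrations at a steady-state snapshot (dose 100, within the 10–10⁴
range probed by the robustness sweep), which matches the decaying-pulse
character of the cytokine profiles the pipeline is meant to emulate — a
sustained source term would be a different experiment.

**Classification.** A factor is "expressed" when it exceeds
`fold_threshold` (default 2, an exposed knob — any value in roughly
[1.5, 20] gives the same calls at the defaults, since polarisation moves
levels ~800-fold) times its baseline at the evaluation time. Neither
above → `UNPOLARISED`; `R` only → `TH17`; both → `DOUBLE_POSITIVE`; `T`
only → `TH1`, or `EX_TH17` when the trajectory (or the supplied
cross-stage history) passed through a Th17 state. Time-to-switch is
measured from CX addition: the earliest grid time after which the
ex-Th17 condition holds through the end of the solve.

**What the ensembles mean.** `run_switching_experiment` samples only the
eight receptor-block parameters (`a₅, a₆, k₉, k₁₀, μ₇, μ₈, μ₉, b₁`),
ten-fold above and below defaults, uniform on the interval — the core
polarisation machinery is held fixed, so every ensemble member polarises
identically and the ensembles isolate receptor kinetics. Under T-bet
promotion a large fraction of sets switch (44/50 at seed 2026, as
computed by the acceptance suite); under RORγt inhibition none do,
because inhibition can only deplete RORγt — it contains no path that
raises T-bet, and once `CX` has decayed or been absorbed the Th17
attractor (or, for extreme parameter draws, the unpolarised one)
reclaims the cell; the ex-Th17 end state is unreachable either way. That
asymmetry is structural, which is exactly why it is a robust qualitative
prediction and why the published headline count for the promotion arm is
*not* asserted numerically: it depends on coefficient ranges that are
not public.

## What the synthetic world does and does not establish

Every test input is generated in code: toy decay/conversion networks
with known closed forms for the solver oracle, random Hill-law documents
for round-trip properties, analytic test functions (additive, Ishigami)
for the sensitivity oracles, and the case-study model itself. A green
suite therefore establishes internal correctness — designs satisfy their
definitional properties, the solver matches closed forms and continuation
oracles, PRCC/eFAST match independent estimators, the case-study dynamics
realise the stated qualitative behaviours. It does **not** establish
biological calibration of the Th17 model (its parameters are a tuned
reconstruction, not data-fitted), nor byte compatibility with other
tools' settings files (the settings vocabulary here is defined by
`inst/schema/settings.xsd`), nor coverage of SBML features outside the
documented subset.

## Numerical choices and degenerate inputs

* Doubles serialise at 17 significant digits everywhere (SBML, design
  CSVs); manifest joins are by filename, never by float comparison.
* `increments = 1` in a local sweep degenerates to the range minimum and
  warns; `min ≥ max` ranges are rejected at construction.
* Zero-variance responses make eFAST indices flagged-missing, not zero;
  constant design columns do the same for PRCC.
* The continuation contract (snapshot + re-solve equals the
  uninterrupted solve within 1e-6 relative) is the operational definition
  of "the snapshot captures the state"; it is enforced on random toy
  models in the acceptance suite.
* Ties in ranks are handled by midranks (R's `rank` default), which keeps
  PRCC invariant under any strictly monotone transform.

## Known limitations

* No SBML packages (comp, fbc), algebraic/assignment rules, function
  definitions, units checking, delays, or stochastic semantics; events
  pass through untouched but uninterpreted.
* The integrator is explicit; strongly stiff models will integrate
  slowly (correctly, but with small steps). The case-study model is
  non-stiff at all sampled parameter sets.
* eFAST assumes independent factors; PRCC assumes monotone (not merely
  any) dependence.
* `SCALE` interventions may target parameters as well as species; if a
  solver's CSV omits parameter columns, scaling a parameter requires
  supplying the final state explicitly.
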