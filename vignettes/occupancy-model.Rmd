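---
title: "An occupancy model for tuning inducible promoter dynamic range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An occupancy model for tuning inducible promoter dynamic range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promtune)
```

## The model and its assumptions

`promtune` treats transcription initiation at a σ70 promoter as an
equilibrium-occupancy problem. The promoter carries a σ70 site (the −35
and −10 hexamers), at most one activator operator immediately upstream of
the −35, and zero or more repressor operators in the spacer (or, for
auxiliary copies, at +1 / far upstream). Each joint binding state gets a
Boltzmann weight relative to the empty promoter:

* σ70 alone: `K_eq = exp(−(ΔG₋₁₀ + ΔG₋₃₅))`, energies in k_BT. Only the
  *sum* of the two site energies enters, which is the additivity
  assumption behind the combinatorial library design: a −35 part and a
  −10 part each contribute a sequence-specific energy, independent of the
  partner.
* Active activator: `q_A = a(c)·K_A`; a state holding both activator and
  σ70 is further weighted by the cooperativity ω. With ω ≫ 1 the
  activator-plus-σ70 state dominates σ70-alone binding in the induced
  promoter, which is how recruitment is represented.
* Each active repressor: `q_R = ρ(c)·K_R`; any state holding a repressor
  excludes σ70 (steric occlusion of the spacer). Repressors are mutually
  compatible and independent of the activator.

Summing weights gives the closed-form occupancy implemented in
`p_sigma_bound()`, and the observable rate is `r = α·P + b`. Assumptions
worth keeping in mind: fluorescence is proportional to transcription rate;
initiation, not escape or elongation, is limiting; RNAP/σ70 concentration
is constant and absorbed into `K_eq` and α; ligand binding equilibrates
fast relative to growth.

The additive background `b` matters structurally: it makes fold change
approach 1 at *both* `K_eq` extremes (a dead promoter measures as
autofluorescence; a saturated one no longer responds), producing the
characteristic interior optimum of the dynamic range. Without `b` the
fold-change curve would rise monotonically as `K_eq` falls, which is not
what plate assays show.

A deliberately simple alternative not taken: giving the σ70-alone and
activator–σ70 states different intrinsic rates. The single-α-plus-background
form fits every qualitative statement the model needs and keeps the
parameter count identifiable from two-condition data; `fit_model()`'s
template structure leaves the two-rate form as an extension point.

## Parameters, units, defaults

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| ΔG₋₃₅, ΔG₋₁₀ | site binding energies | k_BT | fitted / fixture | relative to consensus anchors at 0 |
| α | maximal rate scale | RPU | 1e5 | strongest library members reach ~1e5 RPU |
| b | background signal | RPU | 10 | autofluorescence + reporter leak, ~1e-4 of α |
| ω | activator–σ70 cooperativity | — | 100 | strong recruitment; induced occupancy near-saturates for medium K_eq |
| K_A, K_R | regulator binding weights | — | 50 | active regulator mostly bound to its operator |
| n (Hill) | ligand cooperativity | — | 2 | generic sigmoidal dose response |
| EC50 / K_I | half-maximal ligand conc. | per-ligand | working conc. / 10 | regulators near-saturated at the working dose |

Working concentrations are arabinose 5 mM, xylose 5 mM, IPTG 1 mM, C4-HSL
10 µM, 3O-C6-HSL 0.1 µM, 3O-C12-HSL 0.1 µM, aTc 100 ng/mL; each ligand
keeps its own natural unit, used consistently for its `half_conc`. The
Hill parameters of the real strains are not known from printed data, so
the EC50-at-a-tenth rule is the package's own calibration choice: it makes
every "on" condition ≈ 99% activating, so truth-table logic is crisp while
titrations still resolve the transition.

The two TetO2 copies of the three-input promoters (at +1 and ~−400) are
modelled as a single effective TetR weight rather than two sites; the data
motivating a per-site decomposition (the +1 site dominating repression)
are not available at part-level resolution, and a single weight reproduces
the gate phenotype.

## What the synthetic generator emulates — and what it does not

`generate_library_dataset()`, `generate_dose_response()` and
`generate_gate_dataset()` produce raw plate wells: one plate per
(condition, replicate) holding every variant plus an on-plate
reference-standard well and a blank, OD600 fixed at 0.5, and
`fluor_4h = fluor_2h + rate · noise · OD`. Noise is multiplicative
lognormal with mean exactly 1 at CV 0.10 — plate fluorescence errors are
scale-proportional — applied independently per well, including the
reference. Biological triplicates are the default.

The fixture energies (−35: a 0.7, b 4.5, c 1.5, d 2.3, e 0, f 3.2; −10:
A 0.5, B 1.0, C 3.5, D 6.0, E 2.6, F 1.8, G 0, H 4.6 k_BT) are fixture
choices, not measurements; they tile `ln(K_eq)` from −10.5 to 0 so the 48
combinations span the whole dynamic-range curve, and they are assigned to
labels so the documented phenotypes hold: bD weakest (low leak/low
signal), eG strongest (high leak/high signal), d of medium affinity, E
weaker than F (so dE is tighter and dF leakier but higher-signal). Only
d (TTTACA), d* (TTTACT), E (GATACT) and F (GATAAT) are authoritative part
sequences; the rest are placeholders and the model never reads base
content — energies are fitted, not predicted from sequence.

Real plate data differ in ways the generator deliberately omits: growth
dynamics and OD-dependent expression, well-position and edge effects,
plasmid copy-number fluctuations, day-to-day reference drift, activator
crosstalk (e.g. SdiA on quorum-sensing promoters), and any deviation from
lognormal noise. Passing tests therefore demonstrate internal correctness
of the estimator and pipeline under the stated error model, not robustness
to these real-data effects; in particular the ~0.03 recovery RMSE on
ln(K_eq) is a noise-floor figure, and the repressed/uninduced condition of
real hybrid promoters is known to deviate from this model at high
`ln(K_eq)` (states such as DNA looping are not modelled).

## Fitting: objective, gauge, optimizer

The objective is `Σ (ln r_obs − ln r_pred)²` over wells — least squares on
log rates, appropriate for multiplicative noise and for data spanning four
decades. Observed non-positive rates are floored at half the smallest
positive rate before logging (`floor_rates()`).

Per-site energies carry a one-dimensional degeneracy: shifting all −35
energies by δ and all −10 energies by −δ changes no `ln(K_eq)`. The gauge
is fixed by anchoring one site per family at ΔG = 0 — by default the
consensus-matching sites (e, G) — *during* optimization, so both anchors
are structurally zero and all energies read as "k_BT relative to
consensus". `apply_gauge()` re-gauges foreign results by the δ-shift that
zeroes the −35 anchor; since one shift cannot zero two anchors of an
arbitrary result without touching `ln(K_eq)`, any residual on the −10
anchor after that shift is genuine, not gauge.

Optimization is multistart BFGS (`stats::optim`) on a log scale for the
positive globals (α, b, ω, K): one data-informed start (occupancy
inversion of the least-induced condition followed by a least-squares
additive decomposition) plus seven wide seeded random starts; the reported
fit is the best of the eight, so best-so-far loss is monotone in starts,
and the whole procedure is deterministic given the config seed. Global
parameters are shared across the library; per-variant parameters are only
the site energies (the additivity assumption). An unconstrained
`energy_model = "per_combination"` variant (one free `ln(K_eq)` per
variant) is supported for checking additivity; additive is the default.
Note that ω and K_A are only weakly identifiable from two-condition
library data (a near-saturating activator constrains mainly their
combination); `ln(K_eq)`, α and b are the well-determined quantities, and
tests assert recovery of those.

## Numerical choices and degenerate inputs

* Occupancy is computed in closed form; the state enumeration exists
  independently and the two agree to < 1e−12 over random draws (an
  oracle, not a code path shared with the closed form).
* `K_eq = exp(ln_keq)` underflows to 0 for ΔG sums beyond ~745 k_BT, which
  correctly yields P = 0; `fold_change()` errors only when the OFF rate is
  exactly 0 (background 0 and underflowed K_eq).
* Empty libraries, reference-only plates and single-variant tables are
  legal inputs with the obvious outputs.
* Ranking ties break by fold change, then lexicographic (−35, −10) label,
  so orderings are reproducible.
* `truth_table()` requires a complete 2^k condition set and names any
  missing state; condition ids are binary strings by convention
  (first input = most significant bit, all-off first).

## Problem sizes

The test suite and acceptance script use the study-scale conditions
throughout: the 48-member library with triplicates (288 wells per fit),
20 seeded repetitions for the recovery study, 1e4 random draws for the
closed-form/enumeration comparison, and 201-point `ln(K_eq)` grids for
shape checks. A single library fit takes on the order of a second; the
full recovery study under a minute.

## Known limitations

* Repression is steric exclusion only — no DNA looping, no
  repressor–repressor cooperativity, no per-operator decomposition of
  multi-copy repressor sites; quantitative accuracy for repressed states
  at high `ln(K_eq)` is expected to be worse than for activation.
* No σ-factor competition, promoter escape kinetics, or explicit RNAP
  concentration; all are absorbed into `K_eq`, α and ω.
* Energies are relative (gauge-fixed); absolute binding free energies are
  not identifiable from this assay design.
* The RPU normalization uses the 4 h OD reading; the choice of OD time
  point is configurable in the sense that `compute_fluo()` takes whatever
  OD the caller supplies, but the packaged pipeline always passes the 4 h
  value. Blank subtraction is available but off by default.
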