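---
title: "Methods: constraint-based flux analysis of grapevine cell suspensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based flux analysis of grapevine cell suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisflux)
```

## The modelling problem

Grapevine cell suspensions of teinturier cultivars accumulate anthocyanins
in response to nitrogen limitation. To understand *which* fluxes reorganise
— carbon entry, the 2-oxoglutarate branch point, NADPH supply, ATP
budget — we pose the classical steady-state flux balance problem on a
hand-curated network of central and polyphenol metabolism and resolve its
remaining degrees of freedom by quadratic flux minimization.

The model describes one average cell in a homogeneous suspension. With
$N$ the stoichiometric matrix over the $m_{int}$ internal (balanced)
metabolites and $v$ the vector of $n$ reaction rates
(mmol gDW$^{-1}$ day$^{-1}$),

$$ N v = 0, \qquad lb \le v \le ub, $$

and among all feasible $v$ we report

$$ v^\star = \arg\min \sum_i w_i v_i^2 \quad (w_i > 0,\ \text{default } 1). $$

Strict convexity makes $v^\star$ unique, which is the point of the
quadratic objective: a parsimonious, reproducible flux map rather than one
arbitrary vertex of the flux polytope. An L1 variant of the flux-
minimization principle exists in the literature; we use the quadratic form
as default because uniqueness and smooth sensitivity to the measured
constraints are what the comparisons between conditions rely on. All
fluxes enter the objective; measured (fixed) fluxes only add constants and
cannot change the minimiser.

## The GT3 reconstruction

`build_gt3_network()` ships a curated reconstruction (73 reactions, 53
internal metabolites): glycolysis, TCA cycle, oxidative and non-oxidative
pentose phosphate pathway, starch and sucrose metabolism, nitrate
assimilation, the shikimate–phenylpropanoid–flavonoid route, four overall
phenolic product reactions (anthocyanins, flavonols, tannins, stilbenes),
four overall biomass reactions (cell wall, protein, DAG, nucleotides),
eight simple accumulation reactions (malate, glucose, fructose, sucrose,
Glu, Asp, Ala, Phe), oxidative phosphorylation (`Vnrj1`, `Vnrj2`),
adenylate kinase and non-growth ATP maintenance (`Vnga-ATPm`).
Compartment tags are informational only — each species is one pooled
quantity. Stoichiometries follow standard plant biochemistry (KEGG
reference reactions), with bookkeeping simplifications (water and protons
omitted; phosphate tracked explicitly). Every cofactor pair is internal
and therefore balanced, so redox and energy status genuinely constrain
the carbon solution.

Choices where the underlying biology allows latitude:

* **P/O ratios.** ATP yields of oxidative phosphorylation are set to the
  textbook 2.5 ATP/NADH and 1.5 ATP/FADH$_2$, both arguments of
  `build_gt3_network()`.
* **Directionality.** 33 internal reactions are irreversible — the
  canonical one-way steps (kinases, decarboxylating dehydrogenases,
  synthases, the assimilatory nitrogen enzymes, PAL/C4H/4CL, CHS). The
  flavonoid core carries its three classically reversible steps at
  naringenin (`Vnar`), dihydroquercetin (`Vdhq`) and leucocyanidin
  (`Vlcc`). Exchange, overall and maintenance reactions are
  one-directional by construction and not part of the count.
* **Lumping.** Nitrate reduction is split NR (NADH) / NiR (3 NADPH) so the
  redox cost of assimilation lands on the right carriers; the shikimate
  pathway is lumped to chorismate plus a chorismate→Phe step; lower
  glycolysis lumps GAPDH+PGK and PGM+enolase.
* **Protein composition.** `Vprotein` uses an equal-molar composition over
  the five amino acids present in the network by default; a measured
  composition can be passed as an argument. ATP cost: 4.3 per residue.
* **2-oxoglutarate dioxygenases.** `Vdhq`, `Vflav` and `Vanthoc` consume
  2-oxoglutarate and release succinate, coupling flavonoid hydroxylation
  to the TCA/nitrogen branch point — the coupling the branch-point audit
  (`akg_branch_summary()`) quantifies.
* **Ammonium uptake is omitted**: at the low medium concentration it is a
  negligible nitrogen source next to nitrate.

A user-supplied SBML or reaction-table model takes precedence over the
built-in network throughout the pipeline.

## From measurements to constraints

* **Growth.** $\mu$ is the slope of a log-linear least-squares fit of
  biomass over a window ending at the evaluation day (default: all
  timepoints up to it). The numerical scheme is a deliberate choice —
  only the definition of $\mu$ (growth rate per biomass) is fixed by the
  experimental design; the fit $R^2$ is reported so a failing
  exponential-phase assumption is visible. A flat series returns
  $\mu = 0$ with $R^2$ flagged `NA`.
* **Accumulation fluxes.** $v = c \cdot \mu$, with mass-based
  concentrations first converted to mmol gDW$^{-1}$ via the component's
  molar mass. Each measured component fixes its exchange flux as both
  lower and upper bound (hard equality; measurement SE is deliberately
  not propagated — see Limitations).
* **Capacities.** A measured enzyme capacity bounds the flux above, and
  below with opposite sign when the enzyme is reversible. Unknown
  capacities are infinite markers, converted to a finite cap
  ($10^6$ mmol gDW$^{-1}$ day$^{-1}$, configurable) only at solver
  hand-off, with a post-solve warning if any flux lands within 1% of the
  cap.
* **Respiration.** The measured ATP synthesis rate constrains
  `Vnrj1 + Vnrj2` through one coupling row — an equality at the mean by
  default; `respiration_mode = "interval"` widens it to mean ± SE, since
  the measurement carries an SE but the hard-equality convention is how
  such constraints usually enter the solver. Conversion from O$_2$ uptake
  measurements needs the fresh/dry weight ratio and a P/O assumption;
  `atp_rate_from_o2()` makes both explicit instead of hiding defaults.
* **Coverage.** `biomass_coverage()` reports what fraction of a gram of
  dry biomass the measured components explain — the honest bound on how
  much of the cell the flux map describes.

## Solving and verifying

`minimize_flux()` eliminates fixed variables (better conditioning),
rank-reduces the equality rows by QR (stoichiometric matrices commonly
carry dependent conservation rows; consistency of dropped rows is
re-checked post-solve), caps infinite bounds, and calls the Goldfarb–
Idnani dual active-set method. The identified active set is then
re-solved exactly (KKT linear system), bringing the optimum to near
machine precision — this is what makes permutation invariance and the
exact $\lambda$-scaling equivariance of the solution hold to $10^{-8}$
relative rather than to loose solver tolerance. Feasibility tolerance is
$10^{-9}$ and optimality $10^{-8}$ (relative), both configurable.
Infeasibility is reported as a status, never as a silent near-solution;
`diagnose_infeasibility()` then solves an elastic relaxation (quadratic
slack on every fixed exchange and coupling row; mass balance and
directionality stay hard) and ranks the constraints by required
relaxation. The slack penalty is quadratic rather than L1, so blame for a
deeply inconsistent data set can spread across constraints; the ranking
by magnitude is still informative and the leave-one-out pattern can be
confirmed manually.

Verification is two-route. `solve_oracle_small()` enumerates every
bound-activation combination on problems of at most 12 reactions and
solves each equality-constrained candidate in closed form (SVD
pseudo-inverse) — sharing no code with the production path — and
`check_kkt()` reconstructs Lagrange multipliers by least squares at any
reported optimum, checking stationarity, feasibility, complementary
slackness and multiplier signs.

## What the synthetic generator emulates — and what it does not

`make_scenario()` fixes (or draws) the sixteen measured exchange targets,
imposes the measured respiration coupling, and solves for the ground
truth `v_true`; the truth is thereby the minimum-norm point of its own
constraint set, so the pipeline is a left inverse of the generator and
noise-free recovery must be exact — the sharpest end-to-end test the
design admits. Defaults are the study conditions: $\mu = 0.288$
day$^{-1}$ (day-4 exponential phase), $X_0 = 1.6$ g DW L$^{-1}$, sampling
days $\{0, 4, 6, 8, 11\}$, respiration 3.54 mmol gDW$^{-1}$ day$^{-1}$
(control, day 4; 2.86 for the low-nitrogen reference set), measurement CV
5%. The respiration default matters: without it the minimum-norm truth
parks at the stoichiometric respiration minimum with zero maintenance
ATP, an unphysiological corner where any downward measurement noise makes
the assembled problem infeasible. A culture respiring above the minimum —
positive `Vnga-ATPm` — is both the realistic state and what the
measured-respiration constraint encodes.

Noise is multiplicative lognormal with unit mean: concentrations are
positive and assay errors relative, and the family makes zero-noise
degenerate exactly to the noiseless value. Fabricated capacities are
$\alpha \, |v_{true}|$ with $\alpha \in [1.5, 3]$, so they never cut the
truth unless a scenario demands it. Amino-acid components are written
mass-based (mg gDW$^{-1}$ with molar masses) to exercise the unit
conversion inside the full pipeline.

Passing recovery tests therefore shows the *pipeline* is consistent, not
that real cultures satisfy its assumptions. The generator does not
emulate: non-steady-state transitions between sampling days, correlated
assay errors, systematic biases (extraction losses), day-6 growth
deceleration within one scenario, or biological replicate variance.

## Numerical and design notes

* Problem sizes used in routine testing: the full 73-reaction network for
  pipeline checks; 6–9-reaction random problems (200 of them) for
  solver-vs-oracle equivalence; 60 Monte-Carlo repeats for estimator
  bias. All chosen to make the suite a desk-scale computation.
* Percent changes use the control-flux magnitude as denominator; sign
  flips are flagged separately, and `|v_c| < 10^{-9}` entries are
  undefined rather than $\pm\infty$. The "unchanged" dead-band is ±5%, a
  reporting convention, not an inference.
* The day-6 question (whether conversions reuse the day-4 $\mu$ or the
  day-6 value) defaults to the same-day $\mu$: each day's problem is
  internally consistent with its own growth state.
* Degenerate inputs: duplicate ids, unknown metabolites, contradictory
  bounds (`lb > ub`), unmatched measured components and missing molar
  masses are all hard, named errors; consistency checking
  (`check_consistency()`) finds unconserved stoichiometry, orphan
  metabolites and dead ends before any solving.
* Conservation weights are found by box-constrained least squares
  ($\min \|B^\top w\|^2,\ w \ge 1$, L-BFGS-B), equivalent to the usual
  linear-feasibility formulation for deciding conservation.

## Limitations

Measurement uncertainty stops at the constraint boundary: SEs of the
fixed exchange fluxes are not propagated into flux confidence intervals
(only the respiration interval mode exposes one SE). The network is a
core model, not genome-scale — no gene–protein–reaction rules, no
thermodynamic $\Delta G$ constraints, no kinetics. The flux map is the
unique minimum-norm solution, which is a modelling convention: real cells
may sit elsewhere in the feasible polytope, and capacity bounds that are
never active (the `at_bound` column makes this visible) provide no
evidence either way.
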