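---
title: "Constraint-based analysis of redox trade-offs in a methanotroph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of redox trade-offs in a methanotroph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxflux)
```

## The scientific problem

Verrucomicrobial methanotrophs such as *Methylacidiphilum* species grow
on methane, on H2 + CO2, and on C3 compounds (propane, isopropanol,
acetone), in all cases fixing carbon exclusively through the
Calvin–Benson–Bassham (CBB) cycle. Their electron transport chain is
menaquinone-based; the periplasmic methane monooxygenase (PMMO) draws
its electrons from the menaquinol pool, the lanthanide-dependent
methanol dehydrogenase (XoxF-MDH) donates electrons to cytochrome *c*,
and hydrogen can be oxidized either periplasmically (quinone-coupled)
or cytosolically (NAD-coupled). The consequence is a stiff accounting
problem: every substrate choice shifts where electrons enter the chain
and therefore how much NAD(P)H, proton-motive force (pmf) and ATP are
available for carbon fixation and biosynthesis. `redoxflux` implements
the constraint-based machinery to quantify those trade-offs: flux
balance analysis (FBA) with flux-split ratio constraints, maintenance
sensitivity scans, H2 phase planes with reverse electron flow, uniform
flux sampling with differential-flux statistics, and mass flow graphs
ranked by PageRank centrality.

## Flux balance analysis and the linear program

A metabolic model is a stoichiometric matrix $S$ (metabolites ×
reactions) with flux bounds $lb \le v \le ub$ and a biomass objective.
FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where $c$ selects the biomass reaction, so the optimum is the growth
rate $\mu$ in 1/h. The package solves these programs with its own dense
bounded-variable two-phase revised simplex (`lp_solve`, internal),
using Bland's anti-cycling rule and an explicit basis refactorization
at every iteration. For the problem sizes handled here (tens to a few
hundred variables) this is fast, numerically transparent, and —
because artificial variables are simply pinned at zero in phase two —
robust to the redundant mass-balance rows that real stoichiometric
matrices contain. The default pivot tolerance is $10^{-9}$.

### Ratio (flux-split) constraints

Several analyses constrain the *share* of a branch in a total
oxidation flux, e.g. "the direct cytochrome-coupled formaldehyde
dehydrogenase carries 20% of total formaldehyde oxidation" or "the
periplasmic hydrogenase oxidizes 76% of the H2 flux". These are linear
equalities

$$v_{\text{focal}} = \phi \sum_{r \in D} v_r, \qquad \phi \in [0, 1],$$

implemented as extra rows of the LP rather than as bound manipulation,
so they compose correctly with flux variability analysis and with
sampling (every sampled point satisfies them). The denominator set $D$
is derived from the stoichiometry: all reactions that consume (and do
not merely translocate) formaldehyde or H2 (`formaldehyde_consumers()`,
`h2_consumers()`). This reading of "total oxidation rate" is a design
choice; the denominator can always be given explicitly.

### Alternate optima and the parsimonious stage

FBA optima are typically degenerate: many flux vectors attain the same
$\mu$. All *per-reaction* fluxes reported by the scans, phase planes
and panels therefore come from a second LP that minimizes
$\sum_r |v_r|$ at the fixed optimum (the standard positive/negative
flux-split reformulation). This gives a deterministic, documented
tie-break; it does not make individual fluxes unique in every
pathological case, but the quantities tracked here (complex I, ATP
synthase, cytochrome oxidase under the standard conditions) are stable
under it. Flux variability analysis (`flux_variability`) is available
to diagnose remaining degeneracy.

## Curation procedures

* **Elemental balance** (`validate_mass_balance`): per-element
  imbalance $\sum_i c_i n_{ie}$ over every internal reaction, from the
  metabolite formulas; metabolites with placeholder residues (R, X) are
  excluded and reported as skipped. Proton or water imbalances are
  reported, never auto-fixed.
* **Gibbs directionality** (`assign_directionality`): a reaction is
  fixed irreversible only when $|\Delta G^0| > 1$ kJ/mol *and* the
  standard deviation is below 3% of that magnitude; the sign decides
  the direction. Precomputed energies are consumed from TSV; no
  thermodynamic estimation is performed.
* **Energy-generating cycles** (`detect_energy_generating_cycles`):
  for each energy metabolite a dissipation reaction is added (ATP
  hydrolysis, electron release for redox couples, a proton leak for the
  transmembrane gradient), every exchange is closed, and the
  dissipation flux is maximized; any positive optimum is a
  thermodynamically impossible internal loop. The default list covers
  ATP, CTP, GTP, UTP, ITP, NADH, NADPH, FADH2, FMNH2, menaquinol,
  acetyl-CoA and the periplasmic proton gradient — the conventional
  panel adapted to a menaquinone chain; entries absent from a model are
  skipped. Detection reports cycle members (from the parsimonious
  dissipating solution); repair is a curation act left to the modeler.
* **Biomass normalization** (`normalize_biomass`): precursor
  coefficients are scaled by one common factor so that
  $\sum_i |c_i| \cdot MW_i = 1000$ g/mol (1 g biomass per mmol). GAM
  currency metabolites (ATP, ADP, Pi, water, protons) are excluded from
  the weight sum *and* from the scaling — scaling them would silently
  change the maintenance parameter, which has its own installer.
* **Maintenance** (`set_maintenance`): GAM is an ATP + H2O cost added
  to the biomass reaction (mmol ATP per gDW; the 1/h dimension enters
  through $\mu$), NGAM the lower bound of the ATP hydrolysis reaction
  (mmol ATP/gDW/h). Re-application replaces rather than accumulates.
  Defaults: GAM 10.86, NGAM 3.5, P/O 2.5.
* **GAM fitting** (`fit_gam_to_yield`): bisection on GAM in [0, 100]
  (tolerance 0.01) for a target O2 yield, with a monotonicity check at
  the bracket ends and an explicit error reporting the attainable range
  when the target lies outside it.

## Condition scans and phase planes

`build_condition` encodes the standard scenarios: substrate uptake
normalized to a common carbon uptake rate (default 3.5 C-mmol/gDW/h, so
a C3 substrate enters at 3.5/3 ≈ 1.167 mmol/gDW/h), O2/ammonium/water/
proton exchange unconstrained, CO2 secretion open, and the default
ratio constraints (formaldehyde split 0.2 on methane; periplasmic H2
share 0.76 with complex I reversible under autotrophy; uptake of 13.2
mmol H2/gDW/h). Uptake is a *negative* exchange flux; conditions store
positive magnitudes and apply them as lower bounds, matching the
dominant SBML convention.

The H2 phase plane (`phase_plane_h2`) scans total H2 uptake against the
periplasmic fraction $f$, recording $\mu$, the complex I flux (positive
= NADH-oxidizing; negative = pmf-driven reverse electron flow) and the
ATP synthase flux from parsimonious solutions. Two bisection utilities
resolve the derived quantities to $10^{-3}$: `find_switch_fraction`
(zero crossing of complex I in $f$; an explicit "no switch" result when
the flux does not change sign) and `find_min_h2_uptake` (smallest
uptake with $\mu > 10^{-6}$/h, by default at $f = 1$, the pure
reverse-electron-flow regime that makes the feasibility threshold an
energetic statement). "Feasible growth" means $\mu > 10^{-6}$/h
throughout.

## Flux sampling

`sample_fluxes` draws from the uniform distribution over the bounded
polytope $\{v : Sv = 0, \text{ratio rows}, lb \le v \le ub\}$ with
artificially-centered hit-and-run: warmup points are the flux
variability vertices (two LPs per reaction), chain directions are
differences between a random warmup point and the running center,
projected onto the null space of the equality rows (with bound-pinned
coordinates treated as equalities), and the step is uniform on the
feasible segment. Defaults: warmup $10 \times$ the number of reactions,
thinning 100, 10,000 samples. Growth is left free during sampling;
`min_growth_fraction` optionally constrains it. The chain core is
compiled (Rcpp) and uses R's RNG, so a seed makes the whole sample
matrix reproducible; all chain parameters are recorded in the returned
object. `check_sample_validity` verifies steady state (max $|Sv|$ per
row), bounds, and containment of empirical ranges in FVA ranges.

## Differential fluxes and mass flow graphs

Between two sampled conditions, each shared reaction gets the
Kolmogorov–Smirnov distance between its two flux distributions (the
sup-difference of empirical CDFs — used descriptively, no p-value) and
the log2 fold change of absolute medians,
$\log_2((|m_{alt}|+\varepsilon)/(|m_{ref}|+\varepsilon))$ with
$\varepsilon = 10^{-6}$ on the flux scale. Absolute values keep the
ratio defined when a flux reverses direction; reversals are flagged in
a separate sign-flip column, and reactions with both medians below
$\varepsilon$ are marked quiescent and excluded from calls. A reaction
is *significant* when $|\text{log2FC}| \ge 0.5$ and KS $\ge 0.2$ —
fixed descriptive cutoffs, deliberately without multiple-testing
correction. Significant changes are aggregated per subsystem as total
median flux change.

A mass flow graph (`build_mfg`) turns one flux vector into a directed
weighted graph: reactions (split into `_fwd`/`_rev` unidirectional
nodes) are nodes, and the edge $i \to j$ carries
$\sum_m p_i(m)\, c_j(m) / P(m)$ — each producer's output of metabolite
$m$ apportioned among its consumers by consumption share. All
metabolites including currency species participate by default (an
exclusion list exists, since currency handling is a modeling choice);
exchange reactions are nodes, so uptakes and secretions appear as
sources and sinks; metabolites with production below $10^{-9}$ are
skipped as numerical noise. Reactions are ranked by weighted PageRank
(damping 0.85 — the classical default — power iteration, dangling
nodes redistributing uniformly, L1 tolerance $10^{-10}$);
`centrality_over_samples` repeats graph construction and ranking per
sampled flux vector and aggregates directional node scores per
reaction.

## The synthetic mini-model

`build_minimodel` generates a ~50-reaction, 3-compartment
methanotroph-style network embodying the architecture above: PMMO
(menaquinol-consuming), XoxF-MDH with the cytochrome branch and its
direct formaldehyde oxidation side-activity, the THF-dependent
formaldehyde route producing NADPH and ATP, formate dehydrogenase, a
lumped CBB route (3 CO2 + 5 NADPH + 7 ATP per pyruvate), a lumped
pyruvate-oxidation (TCA) step, the periplasmic propane → isopropanol →
acetone → acetol → methylglyoxal chain with its GMC-oxidoreductase /
PMMO redox couplings (methylglyoxal → pyruvate is one lumped step
standing in for a three-step pathway), both hydrogenases, an ETC with
reversible complex I (4 H+/2e−), an alternative-complex-III surrogate
(2 chemical + `aciii_protons` pumped protons; the true stoichiometry of
that complex is uncertain, so it is a knob, default 2), a cbb3-type
oxidase, and an ATP synthase whose proton cost is tied to the
configured P/O ratio: $n_{H^+/ATP} = (8 + \text{aciii})/\text{P/O}$,
giving the default 4 H+/ATP at P/O 2.5.

Three properties hold by construction and are enforced by tests:

* every internal reaction is elementally balanced — the five biomass
  precursor pools (carbon skeleton, amino acid, nucleotide, lipid,
  cofactor) receive the exact residual formula of their synthesis
  reactions, and the biomass pseudo-metabolite the residual of the
  normalized biomass reaction;
* the biomass weight is exactly 1 g/mmol after `normalize_biomass`;
* the network is free of energy-generating cycles.

The generator reproduces the *structure* of the redox trade-offs —
$\mu$ non-increasing in the formaldehyde split, in the periplasmic H2
fraction and in NGAM; a complex I directionality switch inside (0, 1);
isopropanol outgrowing acetone and propane at equal carbon uptake
because its first oxidation step donates electrons to cytochrome
instead of spending menaquinol on an oxygenation — but its lumped
stoichiometries are *not* calibrated to any genome-scale model's
numbers, and its growth rates are not expected to match published
values. Notable divergences from real data: no nitrogen/sulfur side
metabolism, no annotation layer worth scoring, a single lumped NADPH
source outside the THF route (a proton-translocating transhydrogenase),
and an O2 yield that is pinned by the electron balance over a wide GAM
range under fixed methane uptake (the GAM-fitting machinery is
therefore exercised in its responsive high-GAM regime). Passing tests
on this model demonstrate the correctness of the machinery and the
qualitative phenotype structure, not quantitative agreement with any
organism.

`default_fixtures()` bundles the five standard scenarios (methane,
H2+CO2, propane, isopropanol, acetone) with their expected qualitative
outcomes, each verified by the test suite.

## Numerical choices

* LP pivot/feasibility tolerance $10^{-9}$; steady-state acceptance
  $|Sv| \le 10^{-6}$.
* Bisections (switch fraction, H2 threshold) to $10^{-3}$; GAM fit to
  0.01 on a [0, 100] bracket.
* Sampler: direction components below $10^{-12}$ ignored in the step
  computation; degenerate segments (< $10^{-12}$) skipped; pinned
  coordinates (bound width < $10^{-9}$) folded into the equality rows.
* PageRank: damping 0.85, L1 tolerance $10^{-10}$, hard iteration cap
  10,000 with an error (never a silent truncation).
* SBML and JSON writers emit 17 significant digits so round trips are
  bit-exact; JSON keys are sorted for byte-identical re-serialization.
* Unbounded LPs are reported as such, never clamped.

## Problem sizes used by the tests

The suite runs entirely on generated inputs: the mini-model
(~50 reactions), hand-built toys of 2–6 reactions with enumeration
oracles, 10,000-row sampling chains (thinning 100) for the validity
check, 200–500-row chains for distributional comparisons, 21-point
scan grids for monotonicity, and 10–200-row subsets for per-sample
centrality. These sizes keep the full suite within a few minutes on a
single core while leaving each statistical check enough power (e.g. the
uniform-moment check at 10,000 samples uses a 3-standard-error band).

## Known limitations

* The simplex is dense; it is intended for models up to a few hundred
  reactions (genome-scale models with ~1000 reactions solve, but
  slowly). No warm starts between scan points.
* Parsimonious fluxes are a tie-break convention, not a biological
  claim; comparisons of individual fluxes across conditions inherit it.
* The KS/log2FC screen is descriptive; with 10,000 highly
  autocorrelated samples, tiny distributional differences can exceed
  the cutoffs, which is why the fixed thresholds (0.2 / 0.5), not
  p-values, define significance.
* Gene rules are stored and round-tripped as strings; no gene-deletion
  analysis is performed.
* Loopless FBA, integer/quadratic programming and convergence
  diagnostics beyond the documented sanity checks are out of scope.
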