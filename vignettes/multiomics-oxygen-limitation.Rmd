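---
title: "Flux, metabolome and transcriptome analysis of an oxygen-limited fed-batch: methods"
author: "fluxomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics analysis of oxygen-limited fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxomix)
```

fluxomix analyses fed-batch fermentations of a strictly aerobic fungus in
which the oxygen supply becomes limiting partway through the run — the
regime used industrially to boost enzyme (glucoamylase) yield in
*Aspergillus niger*. It combines three layers: constraint-based flux
prediction from measured exchange rates, a multivariate screen of
intracellular metabolite pools against the specific oxygen uptake rate,
and soft clustering plus directional gene-set statistics on expression
time courses. This vignette records the models, the tunable parameters,
the numerical choices, and what the synthetic benchmark does and does not
establish.

## Flux balance analysis and its parsimonious refinement

At pseudo-steady state the reaction rate vector $v$ of a metabolic
network with stoichiometric matrix $S$ ($m$ metabolites $\times$ $n$
reactions) satisfies

$$\max / \min \; Z = C^{\mathsf T} v
\quad \text{s.t.} \quad S\,v = 0, \qquad lb \le v \le ub,$$

with growth maximization as the objective ($C$ selects the biomass
reaction). Unmeasured reactions carry the conventional open bounds
$\pm 1000$ mmol/gDCW/h (irreversible reactions have $lb = 0$). Because
the growth optimum rarely pins down every internal flux, a second stage
(parsimonious FBA) fixes $Z$ at its optimum, splits every reversible
reaction into non-negative forward/backward halves, and minimizes
$\sum_i |v_i|$ — the enzymatically cheapest optimal distribution. The
reported `total_absolute_flux` is that minimum.

**Measured-rate constraints.** Each fermentation phase (a time point,
treated as an independent snapshot; no dynamic FBA) supplies specific
rates for glucose uptake ($q_S$), oxygen uptake ($q_{O_2}$), product
secretion ($q_P$), by-product secretion and non-growth ATP maintenance
($m_{ATP}$), all entered as positive magnitudes. Uptakes are negated
internally (exchange flux $<0$ = uptake). Rates are imposed as relative
bands $[q(1-\delta),\, q(1+\delta)]$ rather than equalities: measured
rates carry error, and a closed carbon/ATP balance can make exact
equalities jointly infeasible. The band half-width $\delta$ defaults to
0.05 and is configurable per phase; whether the original analysis used
equalities or bands (and which $\delta$) is not derivable from the study
text, so the package exposes it. $m_{ATP}$ is held in a fixed band, not
merely lower-bounded, for the same reason.

**Validation.** Predictions are judged by per-phase absolute and
relative errors of the growth rate $\mu$ (biomass flux, 1/h) and the CO2
evolution rate $q_{CO_2}$ against their measured values, plus the means
over phases. Relative fluxes are reported as mol per 100 mol glucose
uptake, the scale on which pathway shifts (EMP share, glyoxylate:TCA
ratio) are read.

**The LP engine.** No dedicated linear-programming package is declared
by this package; the solves are backed by an internal dense two-phase
bounded-variable primal simplex with Bland's anti-cycling rule. That is
a deliberate fit to the problem sizes here (a few dozen variables),
where determinism and exactness matter more than speed. Its contract is
the one the flux layer needs — an optimal basic solution with the
objective reproducible to ~1e-9 — and the test suite holds it to that
contract against an exhaustive vertex-enumeration oracle on every small
network. Only solver-independent quantities (objective value, total
absolute flux, uniquely determined fluxes) are ever asserted, so any
compliant LP engine could be substituted. Feasibility of reported optima
is checked as $\lVert S v\rVert_\infty \le 10^{-6}$ and bound violations
$\le 10^{-9}$. A flux-variability diagnostic (per-reaction min/max at
the optimum) is included because a single pFBA vector hides degeneracy.

## Metabolomics: PCA and the PLS-VIP screen

Pool sizes (µmol/gDCW, metabolites × samples with replicates) are
imputed (missing cell → half the metabolite's minimum observed value, a
limit-of-detection surrogate; metabolites missing in ≥50% of samples are
rejected), optionally log-transformed (off by default), centered and
autoscaled (unit variance; Pareto scaling available). The original study
does not state its scaling — autoscaling is this package's default and
the choice is exposed.

PCA is the SVD of the centered sample matrix; scores, loadings and
explained-variance fractions follow the usual conventions and are tested
against the covariance eigendecomposition. The metabolite screen is
single-response NIPALS PLS of the pool matrix against $q_{O_2}$
(regression on the continuous rate is the primary mode; PLS-DA with
dummy-coded phase labels is provided as the categorical alternative).
Per component $a$: $w_a \propto X^{\mathsf T}y$ (unit norm),
$t_a = X w_a$, deflation of $X$ and $y$; $SS_a = q_a^2\,t_a^{\mathsf T}t_a$
is the response sum of squares captured. Variable importance is

$$\mathrm{VIP}_j = \sqrt{\,p \sum_a SS_a\, w_{ja}^2 \Big/ \sum_a SS_a\,},$$

whose squares average to exactly 1 over the $p$ metabolites (asserted to
1e-8 on every fit), so VIP > 1 flags metabolites contributing more than
average — the selection rule. The number of components defaults to
leave-one-out $Q^2$ maximization, with a fixed override. Replicates are
kept as separate samples; averaging is optional. Hierarchical ordering
for heatmaps uses Euclidean distance with complete linkage, with rows
and columns pre-sorted by id so ties break deterministically.

## Transcriptomics: filtering, fuzzy clustering, gene-set classes

Genes with replicate-mean FPKM below 1 at two or more time points are
removed before clustering ("little expression" has no published
numeric threshold; 1 FPKM at ≥2 time points is this package's default
and both knobs are exposed and logged). Surviving profiles are collapsed
to time-point means and z-scored per gene, so shapes, not levels, are
clustered.

Fuzzy c-means alternates membership and center updates
($u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}$, centers = $u^m$-weighted
means) until the largest center shift is below 1e-6 (cap 200
iterations; non-convergence is reported, not fatal). The fuzzifier
defaults to the standard data-shape heuristic
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}$.
Initialization draws $k$ distinct profiles with a fixed seed; because a
single start can settle on a local optimum that splits one coherent
pattern while leaving diffuse profiles without a center, the default
runs 5 seeded restarts and keeps the lowest objective (the objective is
asserted non-increasing within each run). Hard assignments use the
customary cluster-core rule: a gene joins its argmax cluster only when
that membership reaches $\alpha = 0.7$; genes below the threshold stay
unassigned rather than contaminating cluster summaries. The cluster
count is a plain knob (the original presentation used $k = 20$ on 6,662
genes; the synthetic benchmark plants 4 patterns and is analysed with
$k = 4$); no automatic $k$ selection is attempted. Per-cluster
annotation against an externally supplied gene list (e.g. transcription
factors) is a generic cross-tabulation — no list is hard-coded.

Two-phase differential statistics are the log2 fold change of phase
means on the FPKM+1 scale and a Welch t-test across replicates of
log2(FPKM+1). With the few replicates typical of such designs the
Satterthwaite approximation makes the p-values mildly conservative
(null simulations show a KS distance of about 0.03 from uniform at
2,000 genes — quantified in the test suite, and verified against
`stats::t.test`); they are never anti-conservative there, which is the
property that matters for the downstream screens.

Gene-set analysis scores each set's mean gene-level t statistic in five
directionality classes: non-directional (mean $|t|$), distinct-
directional up/down (mean signed $t$, two one-sided p-values), and
mixed-directional up/down (mean $|t|$ over the up- and down-regulated
subsets separately, so a set split half-up/half-down is detected by the
mixed classes while the distinct classes stay null). Significance is
empirical against a size-matched gene-sampling null (draws without
replacement from the analysed background; sample permutation would be
degenerate at two replicates per phase): $p = (1 + \#\{null \ge
obs\})/(n_{perm}+1)$ with $n_{perm} = 1999$ by default, BH-adjusted per
class. The gene-level statistic fed in is the Welch t by default
(configurable to log2FC). Over-representation analysis is the exact
hypergeometric tail via `phyper` — no normal approximation — with BH
adjustment.

## The synthetic-data layer

Nothing in the published study's omics tables is deposited, so the
package carries generators that emulate the study's structure; they are
first-class, tested code, and every generator is a pure function of its
parameters and seed.

* **Toy networks.** `chain` and `diamond` have hand-checkable optima
  (the diamond's two equal-yield routes exercise pFBA's parsimony).
  `core` is a 21-reaction lumped central-carbon network: glucose uptake,
  EMP glycolysis (2 ATP + 2 NADH per hexose), an oxidative
  pentose-phosphate branch (2 NADPH, with a non-oxidative transketolase
  return so the branch can cycle for NADPH alone), pyruvate
  dehydrogenase, a fully oxidative TCA lump (4 NADH + 1 ATP per
  acetyl-CoA), a glyoxylate bypass (1 oxaloacetate + 1 NADH from 2
  acetyl-CoA — the low-NADH route to C4 precursors), oxidative
  phosphorylation at P/O = 2, a reduced polyol by-product outlet that
  reoxidizes NADH at a carbon cost, fixed ATP maintenance plus a
  dissipation outlet (without one, a measured $q_{O_2}$ applied as a
  near-equality over-determines the ATP balance), biomass (100 ATP, 5
  NADPH and precursor draws per unit — scaled so aerobic $\mu \approx
  0.22$ 1/h and late-limitation $\mu$ falls below 0.03 1/h, matching
  the physiology of a filamentous fungus), and a glucoamylase drain
  whose precursor stoichiometry is derived from the bundled amino-acid
  composition table (mass% → mole fractions → pyruvate/oxaloacetate/
  pentose family draws; the mean residue mass converts gravimetric
  secretion rates to mmol residues). These yields make the
  oxygen-limitation response provable: tightening $q_{O_2}$ shifts
  oxaloacetate supply toward the glyoxylate bypass and raises the EMP
  share of glucose, and the enumeration oracle verifies the optimum.
* **Fermentation scenario.** A declarative rate schedule (no kinetic
  ODE): aerobic plateaus $q_S = 2.0$, $q_{O_2} = 5.0$ mmol/gDCW/h
  before the 20 h switch, then a sharp drop (about 3.5-fold in
  $q_{O_2}$) with slow exponential decay (1.2%/h), product secretion
  doubling under limitation (0.04 → 0.08 mmol residue/gDCW/h) and
  $m_{ATP} = 0.8$ mmol/gDCW/h throughout. The generator solves the true
  pFBA at each time point, emits measured rates with multiplicative
  Gaussian noise (default 5% relative), and keeps the true $\mu$ and
  $q_{CO_2}$ for validation. The emitted constraint band defaults to
  twice the noise sd (≈95% coverage), so noise-free runs collapse to
  equalities and close the loop exactly. Under 5% noise, growth
  maximization inside the ±10% band biases $\mu$ upward with an
  elasticity of about 2 (maintenance subtraction amplifies the effect
  of the binding rates), which pre-registers 0.25 as the bound on the
  mean relative $\mu$ error used by the tests; simulation puts the
  observed mean near 0.16.
* **Pools.** Planted blocks vary log-linearly with standardized
  $q_{O_2}$ (the VIP truth; default 5 of 50, slope 0.8, log-noise 0.1)
  or step with the three phase groups (aerobic / early / late
  limitation; half accumulating, half depleting — the organic-acid
  pattern), the rest are lognormal noise. The group-recovery benchmark
  uses 15+15 planted metabolites because a 5-metabolite axis sits below
  the noise-eigenvalue floor of a 14-sample autoscaled matrix — a
  fact worth remembering when reading real PCA plots of small designs.
* **Expression.** Four temporal patterns (up, down, transient, flat;
  default 50 genes each on a 16/24/42/66 h grid, 2 replicates,
  log-noise 0.2), a planted low-expression block for the filter, and
  planted gene sets (all-up, all-down, mixed, null) for the directional
  classes.

**What passing these benchmarks shows — and what it does not.** The
synthetic layer proves internal correctness: the solver finds true
optima, the screens recover planted structure at realistic noise, the
set statistics are calibrated against their own null. It does not
establish performance on real data, where pools are correlated through
shared pathways, expression noise is heteroskedastic and burst-like,
measured rates drift systematically rather than independently, and the
genome-scale model brings thousands of degenerate routes that a
21-reaction lump cannot represent. Conclusions about the real organism
require the original measurements and model.

## Numerical choices and degenerate inputs

* LP pivot/feasibility tolerance 1e-9; pFBA holds the stage-1 optimum
  by an equality row (always feasible — the stage-1 vertex satisfies
  it); mass-balance residual asserted at 1e-6.
* Vertex enumeration (the oracle) folds variables fixed by equal
  bounds into the right-hand side first, keeping the basis count
  tractable; it is exponential and restricted to networks of about a
  dozen free reactions.
* PCA truncates requested components to the numerical rank (singular
  values below 1e-12 of the largest) with a message. NIPALS stops early
  when the residual covariance norm falls below 1e-12 of the response
  scale.
* Zero-variance rows: dropped with a warning (autoscaling), a notice
  (profile standardization), or an error (PLS response).
* Welch t with two zero variances: t = 0 and p = 1 for equal means,
  p clamped into (0, 1] otherwise; infinite t is capped at 1e6 to keep
  downstream rank statistics finite.
* Fuzzy memberships at a coincident center: membership 1 there, 0
  elsewhere (the $d \to 0$ limit).
* Mean over an empty up/down subset in the mixed GSA classes is defined
  as 0, which makes an all-zero input return p = 1 in every class.
* Hierarchical ordering pre-sorts by id so distance ties cannot make
  leaf orders depend on input order.
* All problem sizes in the tests and the acceptance script (20 random
  networks, 6-phase time courses, 50-metabolite pools, 220-gene
  expression sets, 1999 permutations) were chosen as the smallest
  designs at which each property is stably observable across seeds.

## Known limitations

* Snapshot FBA only; no dynamic integration between phases and no
  ¹³C-constrained fluxes, thermodynamic constraints or gene deletions.
* The SBML support targets the Level 3 + fbc subset the package writes;
  it is not a general-purpose SBML parser.
* The product drain lumps amino-acid biosynthesis into three precursor
  families; it conserves composition, not atom-level stoichiometry.
* PLS-DA uses a plain dummy-coded NIPALS without the class-balanced
  refinements of dedicated implementations.
* The directional GSA implements the gene-sampling null only; a sample-
  permutation null would need more replicates than the emulated design
  provides.
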