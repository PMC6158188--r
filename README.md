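# fluxomix

Multi-omics analysis of oxygen-limited fed-batch fermentations, built
around the regime used industrially to raise enzyme yield in
*Aspergillus niger*: a strictly aerobic fungus is grown fed-batch until
oxygen transfer becomes limiting (around 20 h), growth collapses, and
glucoamylase yield rises. The package is for systems-biology and
bioprocess researchers who want the three analysis layers of that kind
of study as tested, reusable R functions:

1. **Constraint-based flux simulation.** FBA and parsimonious FBA
   (`solve_fba`, `solve_pfba`) on models read from SBML (Level 3 + fbc)
   or a plain TSV dialect:
   max *Z* = *C*ᵀ*v* subject to *S·v* = 0, *lb* ≤ *v* ≤ *ub*,
   then minimize Σ|*v*| at the fixed optimum. Measured specific rates
   (q_S, q_O2, q_P, by-products, m_ATP) are applied per fermentation
   phase as relative bound bands (`apply_phase_constraints`,
   `simulate_phases`), and predictions are validated against measured μ
   and q_CO2 (`validate_predictions`).
2. **Metabolomics screening.** Pool-size preprocessing, PCA, NIPALS PLS
   against q_O2 and VIP scoring with the VIP > 1 selection rule
   (`preprocess_pools`, `run_pca`, `fit_pls`, `compute_vip`), where
   VIPⱼ = √(p Σₐ SSₐ wⱼₐ² / Σₐ SSₐ) and mean(VIP²) = 1 by construction.
3. **Transcriptomics.** Low-expression filtering, fuzzy c-means
   clustering of standardized time courses with the standard fuzzifier
   heuristic (`filter_low_expression`, `fuzzy_cmeans`,
   `estimate_fuzzifier`), Welch differential statistics, directional
   gene-set analysis in five classes (distinct/mixed up/down,
   non-directional) against a size-matched gene-sampling null
   (`gene_set_analysis`), and exact hypergeometric ORA
   (`ora_hypergeometric`).

Because the study's omics tables are not publicly deposited, a seeded
synthetic-data layer (`make_toy_model`, `fermentation_scenario`,
`simulate_fermentation`, `make_synthetic_pools`,
`make_synthetic_expression`) generates every input with known ground
truth, including a 21-reaction central-carbon toy model whose optima are
verifiable by exhaustive vertex enumeration (`enumerate_lp_vertices`).
The methods vignette (`vignettes/multiomics-oxygen-limitation.Rmd`)
documents the models, parameters and numerical choices.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_fermentation.R
Rscript analysis/02_metabolomics.R
Rscript analysis/03_transcriptomics.R
Rscript analysis/04_integrate.R
```

Stage 1 prints, for a 5%-noise fed-batch with the oxygen switch at 20 h:

```
predicted mu: 0.247 1/h (aerobic) -> 0.030 1/h (72 h)
mean relative error vs measured: mu 0.179, q_CO2 0.115
glyoxylate:TCA ratio 0.098 -> 0.194; EMP share 92.4 -> 94.6 per 100 glc
```

Read: growth collapses roughly eight-fold across the switch; predictions
track the (noisy) measurements within the constraint band; and the flux
distribution shifts the way the biology suggests — under oxygen
limitation the glyoxylate bypass gains on the NADH-heavy TCA route and
the EMP share of glucose rises. Stage 2 reports that PC1–2 carry 65% of
pool variance and separate the three phase groups, and that 23 of 50
metabolites pass the VIP > 1 screen, including all 15 planted
q_O2 trackers. Stage 3 removes exactly the 20 planted weakly expressed
genes, recovers the planted temporal patterns as cluster cores, and
calls the planted all-up/all-down gene sets in the correct directional
classes.

A minimal in-session version of the flux layer:

```r
library(fluxomix)
model <- make_toy_model("core")
pc <- phase_constraints(time_h = 24, q_S = 1.0, q_O2 = 1.4, q_P = 0.08,
                        m_ATP = 0.8, tolerance = 0)
sol <- solve_pfba(apply_phase_constraints(model, pc))
sol$fluxes[c("BIOMASS", "TCA", "GLYOX")]
#>    BIOMASS        TCA      GLYOX
#> 0.05744552 0.39035512 0.06437169
```

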