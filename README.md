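# faiselect

Multi-trait genotype selection for replicated clonal breeding trials
with the FAI-BLUP index (factor analysis + ideotype-design on BLUP
breeding values).

Breeders rarely select on one trait: a new cultivar must combine yield,
quality and disease resistance at once, and single-trait truncation
selection gives no guarantee about the other traits. The FAI-BLUP index
ranks genotypes by their distance, in rotated factor-score space, from an
*ideotype* — a hypothetical genotype holding the optimal value of every
trait — avoiding the economic-weight elicitation that classical selection
indices require and the multicollinearity problems of regressing on raw
traits. This package implements the full analysis for a replicated trial
(the motivating case is a 6 × 6 triple-lattice white Guinea yam parental
trial: 36 genotypes × 3 replicates × 18 agronomic and food-quality
traits), plus a synthetic-trial generator used to validate every stage
when real field data are unavailable.

## The method

For each trait, a linear mixed model

    y = Xb + Zu + e,   u ~ N(0, σ²ₐ I),   e ~ N(0, σ²ₑ I)

is fitted with replicate effects fixed (`b`) and genotype effects random
(`u`). Variance components come from EM-REML; `b` and `u` solve
Henderson's mixed-model equations

    [X'X   X'Z      ] [b]   [X'y]
    [Z'X   Z'Z + λI ] [u] = [Z'y],   λ = σ²ₑ/σ²ₐ,

and the entry-mean broad-sense heritability is
h² = σ²ₐ / (σ²ₐ + σ²ₑ/r). The genotype × trait table of predicted
genotypic values (grand mean + BLUP) is then:

1. **Rescaled** per trait onto 0–100 so that 100 is always the desired
   end (column max → 100 for traits desired increased, column min → 100
   for traits desired decreased).
2. **Factor-analyzed**: eigen-decomposition of the trait correlation
   matrix, Kaiser retention (eigenvalue > 1), varimax rotation;
   communality per trait is the row sum of squared retained loadings.
3. **Scored**: regression factor scores `F = Z_std R⁻¹ A` for every
   genotype and for the ideotype `I = [100, …, 100]` (standardized with
   the genotype columns' means/SDs).
4. **Ranked**: genotype–ideotype RMS distance dᵢ over factor scores is
   converted to spatial probabilities Pᵢ = (1/dᵢ)/Σ(1/dₖ); the top
   ⌈intensity · g⌉ genotypes are selected, and each genotype's distance
   is decomposed into per-factor strength/weakness shares.
5. **Gains**: per trait, SG% = (X̄ₛ − X̄ₒ) · h² / X̄ₒ · 100 from the
   selected-set mean X̄ₛ versus the population mean X̄ₒ, classified as
   desired (goal = 100) when the sign of the gain agrees with the trait's
   sense, and totalled by sense over desired rows.

## Worked example

The `analysis/` directory is a numbered workflow over the package —
simulate, fit, index, gains, reference checks — writing its tables to
`results/`. Running it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_blups.R
Rscript analysis/03_factor_index.R
Rscript analysis/04_selection_gains.R
Rscript analysis/05_reference_checks.R
```

prints, for the default simulated trial (seed 2026):

```
Fitted 18 traits; all converged: TRUE
Entry-mean h2: min 0.68, median 0.84, max 0.93
Median |h2 - truth| = 0.050 over 18 traits
Retained 5 factors (Kaiser); eigenvalues: 4.01, 3.4, 3.04, 2.65, 1.44, 0.76, 0.48
Mean communality: 0.81 (specificity 0.19)
Selected at 20% intensity: G010, G015, G008, G011, G014, G032, G020, G018
18 of 18 traits show desired gains (goal = 100)
Total gain, traits desired increased: +56.58%
Total gain, traits desired decreased: -15.00%
```

The generator planted a 5-factor genotypic covariance; the pipeline
recovers all 5 factors by the Kaiser rule and estimates each trait's
heritability to within a few points (median error 0.050). Because the
index maximizes closeness to the all-optimal ideotype, every one of the
18 gains lands in its desired direction on this run — traits desired
increased gain a combined +56.6% and traits desired decreased move a
combined −15.0%. The same computation can be done in one call:

```r
library(faiselect)
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 2026),
                                    intensity = 0.2))
res$fai$selected
res$gains$total_increase
```

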