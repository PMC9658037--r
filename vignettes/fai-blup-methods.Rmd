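---
title: "Methods: mixed-model BLUPs, factor analysis and the FAI-BLUP index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model BLUPs, factor analysis and the FAI-BLUP index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices made where the method leaves room.

## The problem

A clonal breeding program evaluates a panel of candidate genotypes in a
replicated field trial and must pick a small set of parents that are
simultaneously good on many traits — some desired high (yield, dry
matter, starch), some desired low (virus pressure, peel loss). Truncation
selection on single traits ignores the correlation structure; classical
selection indices need economic weights that are hard to elicit. The
FAI-BLUP approach sidesteps both: it summarizes the genetic correlation
structure with a factor model and ranks genotypes by closeness to an
*ideotype* that is optimal on every trait.

## Stage 1: per-trait mixed models

Each trait is analyzed independently with

$$y = Xb + Zu + e, \qquad u \sim N(0, \sigma^2_a I_g), \quad
e \sim N(0, \sigma^2_e I_n),$$

where $b$ holds fixed replicate effects and $u$ the random genotype
effects. This is the simplest G/R structure (no pedigree or genomic
kinship, single environment); traits are fitted independently rather
than by multi-trait REML. Replicates enter as fixed effects; the
incomplete blocks of a lattice layout are not modelled by default — the
simulator can generate them, and they then simply inflate the residual,
which is conservative.

**Henderson solve.** Given variance components, $b$ and $u$ solve the
mixed-model equations with ridge $\lambda = \sigma^2_e/\sigma^2_a$ on
the genotype block. Identifiability of the fixed part uses
drop-first-level reference coding; all reported genotypic values are
*grand mean + BLUP*, where the grand mean is the average fixed-effect
value over plots, so they are invariant to the coding. Numerically, the
fixed effects are absorbed ($M = I - X(X'X)^{-1}X'$) and the absorbed
genotype system $(Z'MZ + \lambda I)$ is handled through a one-time
eigendecomposition of $Z'MZ$: its near-null direction (the intercept /
mean-of-$u$ confounding) is separated exactly, so the solve remains
accurate even in the no-shrinkage limit $\lambda \to 0$, and EM
iterations reduce to cheap re-weightings of fixed eigencomponents.

**EM-REML.** Components are estimated by expectation–maximization:

$$\sigma^2_a \leftarrow \frac{\hat u'\hat u +
\sigma^2_e\,\mathrm{tr}(C^{uu})}{g}, \qquad
\sigma^2_e \leftarrow \frac{y'y - \hat b'X'y - \hat u'Z'y}
{n - \mathrm{rank}(X)},$$

with $C^{uu}$ the $u$-block of the inverse coefficient matrix. Defaults:
relative tolerance $10^{-8}$, at most 500 iterations, updates floored at
$10^{-12}$ (boundary REML). EM is monotone in the restricted likelihood
and safe, but slows near the $\sigma^2_a = 0$ boundary — there it
decays harmonically and the convergence flag reports honestly. On
balanced one-way data the fixed point coincides with the closed-form
ANOVA estimators ($\hat\sigma^2_e = \mathrm{MSE}$,
$\hat\sigma^2_a = (\mathrm{MSG}-\mathrm{MSE})/r$ when positive), which
the tests exploit as an independent oracle; an unbalanced instance is
cross-checked against `lme4`.

**Heritability.** The gain formula needs a heritability; we use
entry-mean broad-sense
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e/r_\mathrm{eff})$ with
$r_\mathrm{eff}$ the harmonic mean of per-genotype replicate counts —
the standard basis for predicting gains from selection on genotype
means in clonal trials. Missing plots are dropped from the design
matrices (MAR assumption), never imputed.

## Stage 2: rescaling

Each column of the genotype × trait table of predicted genotypic values
is mapped affinely onto $[0, 100]$, reversing traits whose desired
direction is *decrease*, so that after rescaling **larger is always
better** and the ideotype is the vector of 100s. A constant column is a
hard error (a trait with no genotypic signal cannot be rescaled and
should be dropped by the user). Rescaling is affine per column, so it
preserves the correlation structure up to the sign flips it
deliberately introduces.

## Stage 3: factor analysis

The trait correlation matrix of the rescaled table is
eigen-decomposed; factors with eigenvalue $> 1$ (strict Kaiser rule) are
retained, with a floor of one factor and a cap of $g - 1$ (with more
traits than genotypes the correlation matrix is rank-deficient and a
saturated factor solution is meaningless). Initial loadings are
$\mathrm{eigvec}_k\sqrt{\mathrm{eigval}_k}$, rotated by varimax with
Kaiser row-normalization (`stats::varimax`, tolerance $10^{-10}$); each
rotated column's sign is set so its largest-magnitude loading is
positive. Communality is the row sum of squared retained loadings —
invariant under the rotation — and specificity its complement.

Factor scores use the regression method, $F = Z_\mathrm{std} R^{-1} A$.
The scoring input is standardized per column (mean 0, SD 1 over
genotypes) because regression scoring is defined on the correlation
scale; the ideotype row of 100s is standardized with the *same* genotype
means and SDs, so a genotype that attains the per-trait optimum on every
trait gets exactly the ideotype's scores. If $R$ is computationally
singular a ridge of $10^{-8}$ is added (logged). Maximum-likelihood
extraction, oblique rotations and retention heuristics other than Kaiser
are out of scope.

## Stage 4: the index

The genotype–ideotype distance is the root-mean-square difference over
factor scores, $d_i = \sqrt{\tfrac1f\sum_k (F_{ik} - I_k)^2}$. A plain
Euclidean option is provided; the two differ by the constant $\sqrt f$
and give identical rankings and probabilities. Distances become spatial
probabilities $P_i = (1/d_i)/\sum_k (1/d_k)$; a genotype at distance
exactly zero receives $P = 1$ (limit convention, logged). Selection
takes the top $\lceil \alpha g\rceil$ genotypes at intensity $\alpha$,
ties broken by ascending genotype label; the intensity is an explicit
parameter with no hidden default. Each genotype's squared score
differences, normalized to sum to one across factors, give its
strength/weakness profile, with $1/f$ as the equal-contribution
reference. A single ideotype is supported: the direction-aware
rescaling already encodes "minimum desired" traits, so the all-100
ideotype covers both senses.

## Stage 5: selection gains

Per trait, $SG\% = (\bar X_s - \bar X_o)\,h^2/\bar X_o \times 100$,
where $\bar X_s$ and $\bar X_o$ are means of the selected set and the
whole panel. Both are taken on the BLUP genotypic-value scale by
default (a `"raw"` plot-mean mode is provided); the default keeps the
gain consistent with selection operating on predicted genotypic values.
The *goal* flag is defined as sign–sense agreement: 100 when an
increase-trait gains or a decrease-trait loses, else 0 — the only
interpretation consistent with the published reference table, whose 15/3
split and desired-sense totals the package reproduces from the printed
per-trait values alone. Trait-to-factor attribution uses the maximum
absolute rotated loading. Totals are sums of desired-row gains by
sense.

## The synthetic-trial generator

No raw data accompany the published trial, so validation rests on a
generator that emulates its statistical structure: $g$ genotypes ×
$r$ replicates × $p$ traits with genotypic effects
$U = F\Lambda' + E$ (factor scores standard normal, uniqueness noise
diagonal), replicate-level fixed effects, and Gaussian residuals whose
variance is derived from the target *entry-mean* heritability,
$\sigma^2_e = \sigma^2_a (1 - h^2) r / h^2$ — controlling $h^2$ on the
basis the gain formula uses.

Defaults (36 × 3 × 18, five factors in trait blocks of 4/4/4/3/3) were
fixed once, on realism grounds: primary genotypic loadings 0.9 and
$h^2 = 0.85$ for all traits. The published factor structure (mean
communality 0.77) is observed on the BLUP scale, where correlations are
attenuated by roughly $h^2$ ($\mathrm{cor} \approx \lambda^2 h^2$
within a block); genotypic loadings of 0.9 with $h^2 = 0.85$ land the
analyzed table at a BLUP-scale communality near 0.7–0.8, i.e. in the
regime the real trial occupies, and clonal yam trials do show
entry-mean heritabilities in the 0.7–0.9 range. Trait means are spread
over 20–105 (positive, away from zero, so percentage gains are
well-defined) with genotypic CV 10%; replicate effects have SD half a
genotypic SD. An option adds random incomplete blocks
($\sqrt g$ per replicate) to exercise the lattice layout, and
`delete_plots()` produces unbalanced data for the solver.

What the generator does *not* emulate: spatial field trends,
genotype × environment interaction, non-Gaussian traits (disease scores
are ordinal in the field; the generator treats the derived AUDPC-like
quantity as Gaussian), and trait-specific heritability differences
unless configured. Passing recovery tests therefore shows the pipeline
is correct under its own model assumptions, not that those assumptions
hold for any particular field dataset.

## Derived-trait formulas

Severity scores (ordinal 1–5) convert to percent by the affine map
anchored at 1 → 0% and 5 → 100%; the anchor choice is a documented
convention (the field protocol defines score 1 as symptom-free but does
not print the map). AUDPC is the trapezoidal integral of percent
severity over assessment days; starch content and flour yield are the
standard gravimetric ratios. Duplicate plot records are averaged with a
warning rather than rejected.

## Problem sizes and numerical choices

The test suite and acceptance script run the default 36 × 3 × 18 trial
(20 seeds for recovery summaries) and a single 200-genotype trial for
loading-structure recovery — sizes chosen to match the study design
while keeping a full validation run in the order of seconds. Tolerances:
EM-REML $10^{-8}$ relative (tightened to $10^{-12}$ where tests compare
against closed forms), varimax $10^{-10}$, probability normalization
checked to $10^{-10}$. Tie-breaks in selection are lexicographic by
genotype label. Degenerate inputs (constant trait columns, zero
distances, $\sigma^2_a = 0$) follow the documented conventions above
rather than erroring where a well-defined limit exists.

## Known limitations

- Single environment, identity kinship: no GxE, no pedigree/genomic
  relationship matrices.
- The Kaiser rule is the only retention heuristic; on white-noise data
  it retains whatever clears 1 by sampling noise (the floor of one
  factor applies).
- EM-REML converges slowly near the variance boundary; the convergence
  flag must be checked for traits with very low genotypic signal.
- With more traits than genotypes the factor solution saturates; the
  cap $f \le g - 1$ makes the behaviour defined but such analyses are
  not recommended.
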