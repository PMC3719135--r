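# grseval

Simulation framework for evaluating **genetic risk score (GRS)** models in
case-control studies when the genetic architecture is not simple — when loci
interact (epistasis) or when a scored marker is in linkage disequilibrium
(LD) with a causal locus. It is aimed at statistical geneticists who want to
know *which weighting scheme to trust* when building a risk score from
previously discovered variants.

## The three scores

For subject *s* with risk-allele counts `G_si ∈ {0,1,2}` at loci
`i = 1, …, I`, disease status is modelled as
`logit P(D=1) = α + β·GRS` and the candidate scores are

| method | weight `w_i` | score |
|---|---|---|
| SC (simple count) | 1 | `Σ_i G_si` |
| OR (odds-ratio weighted) | `log OR_i` | `Σ_i w_i G_si` |
| EV (explained-variance weighted) | `(log OR_i)² · 2·MAF_i(1−MAF_i)` | `Σ_i w_i G_si` |

Weighted scores may be rescaled by `I / Σ_i w_i` to the allele-count scale;
rescaling is affine, so the likelihood-ratio test (LRT), C-statistic and AIC
are unchanged. Weights are estimated from training replicates (pooled
univariate logistic regressions); performance is measured on disjoint test
replicates as power / type-I error (fraction of replicates with LRT p <
0.05), mean C-statistic and mean AIC, with Tukey-adjusted pairwise method
contrasts.

## The two generators

* **Liability threshold with epistasis** — genotypes under Hardy-Weinberg
  equilibrium; latent trait
  `Y = β₀ + Σ βᵢGᵢ + Σ_T c_T Π_{i∈T} Gᵢ + e`, `e ~ N(0, σ²)`
  (defaults β₀ = 20, σ² = 10, 250 cases + 250 controls, 100 replicates);
  case status `D = 1` iff `Y > median(Y)`, so prevalence is exactly 50%.
  Product terms of any order encode two-way and higher interactions.
* **Two-locus additive penetrance with LD** — disease drawn directly from a
  3×3 penetrance table `P(D|g_a,g_b) = k + r(θ_a,g_a) + r(θ_b,g_b)`
  (baseline `k = 0.1`, relative risks θ ∈ {1.25, 1.5, 1.75}), plus a third
  non-causal marker drawn from a genotype-conditional table in strong or
  weak LD with locus 2. Balanced samples of 400 by rejection sampling.

An analytic **heritability decomposition** for the binary trait accompanies
the liability generator: penetrances by genotype enumeration against the
population-median threshold, single-locus `H²_A`, joint `H²_AB`, marginal
`H²_M,A` and interaction `H²_I,AB = H²_AB − H²_M,A − H²_M,B` components,
with a Monte-Carlo oracle for cross-checking.

## Worked example

Heritability of the lowest-signal four-SNP design (all MAF 0.4, all main
effects 0.2, no interaction):

```r
library(grseval)
spec <- liability_presets()[["scenario1_common_equal_none"]]
h2_decompose(spec, groups = list(G1G2 = c(1, 2), G3G4 = c(3, 4)))
#> Heritability decomposition (prevalence 0.5000)
#>   per-locus marginal (%): G1=0.1214 G2=0.1214 G3=0.1214 G4=0.1214
#>  group loci     h2 h2_marginals h2_interaction
#>   G1G2  1,2 0.2427       0.2427      2.579e-07
#>   G3G4  3,4 0.2427       0.2427      2.579e-07
#>   H2_total = 0.4855%
```

Each locus explains ~0.12% of the binary-trait variance; the pair groups
round to 0.2% each and the model total to 0.5% — deliberately low, realistic
GWAS-scale signal. End-to-end comparison on a design with two noise SNPs and
a strong 3×4 interaction (weights trained on 100 separate replicates):

```r
cfg <- study_config(preset = "scenario2_common_unequal_strong",
                    seed = 2026, replicates = 100)
cmd_evaluate(cfg, n_train = 100)
#> GRS evaluation over 100 replicates (alpha = 0.05)
#>  method rejection_rate ci_low ci_high mean_c mean_aic n_replicates n_flagged
#>      EV           0.96 0.9007  0.9890 0.5995    679.9          100         0
#>      OR           0.98 0.9296  0.9976 0.6017    679.2          100         0
#>      SC           0.86 0.7763  0.9213 0.5707    688.1          100         0
```

The weighted scores down-weight the noise SNPs (their estimated EV weights
are ~3 orders of magnitude below the causal ones) and gain ~10–12 points of
power over the simple count, with higher discrimination (mean C) and lower
AIC — the qualitative pattern this framework is designed to quantify.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at the given seed: the analytic group
heritabilities of the four-SNP reference models (percent, one decimal), the
empirical type-I error of the SC-GRS likelihood-ratio test over 2000 null
replicates, the interaction component of a zero-interaction rare-variant
pair, and the SC-GRS power over 100 replicates of the lowest-heritability
design, writing one JSON object keyed by target id.
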