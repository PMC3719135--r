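---
title: "Evaluating genetic risk scores under interaction and linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genetic risk scores under interaction and linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grseval)
```

## The question

A genetic risk score collapses a panel of risk variants into one scalar per
subject. Once variants are discovered, the practical question is how to
weight them: count risk alleles (SC), weight by log odds ratio (OR), or
weight by the variance each variant explains (EV, the squared log odds ratio
times the genotype variance $2\,\mathrm{MAF}(1-\mathrm{MAF})$). Real
architectures complicate the choice: variants interact, and scored markers
may merely tag causal loci through linkage disequilibrium. This package
provides the machinery to answer the question by simulation: two
case-control generators with controlled epistasis and LD, the three score
constructions with training-based weight estimation, an analytic
heritability decomposition to characterise each simulated model, and a
replicate-based evaluation harness.

## Score construction

With risk-allele counts $G_{si} \in \{0,1,2\}$,

$$\mathrm{SC}_s = \sum_i G_{si}, \qquad
  \mathrm{OR}_s = \sum_i \log(\mathrm{OR}_i)\, G_{si}, \qquad
  \mathrm{EV}_s = \sum_i \log(\mathrm{OR}_i)^2\, 2 p_i (1 - p_i)\, G_{si},$$

optionally rescaled by $I / \sum_i w_i$ to the allele-count scale. Two
properties are load-bearing and asserted in the tests: rescaling is a
positive affine map (so every downstream logistic-fit metric is identical
with or without it), and when all weights are equal the rescaled weighted
scores collapse exactly to the simple count — the regime in which all three
methods must tie.

The EV weight deserves a note. Its printed source formula is typographically
ambiguous; we implement the *explained-variance* reading
$(\log \mathrm{OR})^2 \cdot 2pq$, i.e. the per-locus additive variance
contribution of a log-odds effect. This reading is the one consistent with
the weight's motivation (variants explaining more heritability should weigh
more) and with the near-perfect rank correlation between the EV weight and
single-locus heritability along a risk-allele-frequency sweep, which the
test suite verifies (`h2_curves`). The formula lives in one function
(`ev_weight`), so the alternative reading
$|\log \mathrm{OR}|\sqrt{2pq}$ would be a one-line change. EV weights are
non-negative by construction (direction-blind); OR weights keep the sign of
protective effects. Both facts are documented behaviour, not defects.

**Weight estimation.** Odds ratios come from univariate logistic regressions
of status on the 0/1/2 count, one locus at a time, fitted on the *pooled*
training replicates; MAFs are pooled-sample allele frequencies. Pooling
(rather than averaging per-replicate estimates) is our choice where the
source design is silent: it is equivalent in expectation and stabler at the
locus level. Per-locus failures (separation, non-convergence — detected via
the glm warning plus a runaway-linear-predictor check, $|\hat\eta| > 15$)
are flagged and reported, never silently dropped; a monomorphic locus is an
error. Case-control ascertainment bias in the pooled MAF is negligible at
these effect sizes.

## Generator 1: liability threshold with epistasis

Genotypes are drawn independently under Hardy-Weinberg equilibrium; the
latent trait is

$$Y = \beta_0 + \textstyle\sum_i \beta_i G_i +
      \sum_T c_T \prod_{i \in T} G_i + e, \qquad e \sim N(0, \sigma^2),$$

with defaults $\beta_0 = 20$, $\sigma^2 = 10$, 250 cases + 250 controls per
replicate and 100 replicates per study. Interaction terms are arbitrary
products, so two-way ($\beta_{34} G_3 G_4$) and three-way
($\beta_{345} G_3 G_4 G_5$) epistasis are both expressible. Case status is
$D = 1$ iff $Y$ strictly exceeds the *replicate's empirical median*, giving
exactly 50% prevalence for even subject counts (ties — a probability-zero
event under continuous noise — break toward control). The analytic
heritability module instead uses the *population* median, since model
heritabilities are properties of the generative model, not of a replicate.

The shipped preset grid covers two causal architectures (all four SNPs
causal; SNPs 1–2 pure noise), three MAF patterns (all 0.4, all 0.05, mixed
with SNPs 1/3 common and 2/4 rare), equal vs unequal effects, and three
interaction strengths, plus two six-SNP extensions (two two-way terms; one
three-way term). Two calibration choices were open and are fixed here once:

* **Equal-effect values**: 0.2 for common and 0.8 for rare variants. These
  reproduce the documented heritability ladder of the four-SNP reference
  models — the all-common equal model totals $\approx 0.5\%$ and the
  all-rare equal model $\approx 1.5\%$, which is the regime the original
  power comparisons describe.
* **Interaction levels** none/moderate/strong = 0 / 0.2 / 0.5: spanning
  no interaction up to a coefficient comparable to the largest main effects.
  No acceptance-level check depends on the nonzero levels.

## Generator 2: additive penetrance with a linked marker

Disease is drawn directly from the two-locus penetrance table
$P(D \mid g_a, g_b) = k + r(\theta_a, g_a) + r(\theta_b, g_b)$ with
$r(\theta, g) = 0,\ (\theta - 1)k/2,\ (\theta - 1)k$ — equivalently the
additive table whose corners are $k$, $\theta_a k$, $\theta_b k$ and
$(\theta_a + \theta_b - 1)k$. Validity requires
$(\theta_a + \theta_b - 1) k \le 1$, checked at construction. Defaults:
$k = 0.1$, $\theta \in \{1.25, 1.5, 1.75\}$, 400 subjects balanced by
rejection sampling (capped; exhausting the cap is an error, never a
truncation). Additivity on the penetrance scale is an exact identity of the
construction and is asserted cell by cell.

A third, never-causal marker is appended in **strong** or **weak** LD with
locus 2 via a genotype-conditional table $P(G_3 = j \mid G_2 = i)$. The
original conditional frequencies are not available, so the package ships a
parameterised construction: weak mode uses the marker's own HWE frequencies
in every row (independence); strong mode retains mass 0.8 on the matching
genotype and spreads the rest proportionally to HWE. The retention level and
the full table are user-overridable; 0.8 produces a genotype correlation
$\approx 0.8$ with a common causal locus, a clearly "strong" tag without
being degenerate. Training and test collections use disjoint seed streams.

## Heritability decomposition

For the binary trait, with prevalence $P(D)$ and penetrances
$P(D \mid G)$,

$$H^2_A = \frac{\sum_a P(G_a)\{P(D|G_a) - P(D)\}^2}{P(D)(1-P(D))},$$

with the joint form $H^2_{AB}$ summing over genotype pairs, the marginal
form $H^2_{M,A}$ using penetrances marginalised over the partner locus, and
$H^2_{I,AB} = H^2_{AB} - H^2_{M,A} - H^2_{M,B}$. Implementation details:

* **Threshold**: the population median solves
  $\sum_G P(G)\,\Phi((t - \mu_G)/\sigma) = 1/2$ by bracketed root-finding
  plus one Newton polish; the residual is below $10^{-12}$ and the
  mixture-weighted mean penetrance equals $1/2$ to $10^{-10}$ (asserted).
* **Enumeration** over all $3^L$ genotype cells, capped at $L = 8$; beyond
  that the Monte-Carlo oracle is the tool.
* **Grouping convention**: every reporting group's value is the *joint*
  total (marginals + interaction remainder). For groups without interaction
  terms this coincides with the sum-of-marginals convention to $\sim 10^{-6}$
  (the only discrepancy is threshold-model nonlinearity), so either
  convention reproduces the reference values at one-decimal precision.
* **Higher-order interactions**: for a three-locus group the interaction
  component is defined recursively as the joint total minus all marginals
  and all pairwise interaction components — the natural extension of the
  pairwise definition, which the source only gestures at.

A useful small-effect closed form anchors intuition and the tests: for one
locus at 50% prevalence, $H^2 \to (2pq\beta^2 / \mathrm{Var}\,Y)\cdot(2/\pi)$
as $\beta \to 0$; at $\beta = 0.2$, $\sigma^2 = 10$ the exact computation is
within 2% of it.

**Monte-Carlo oracle.** `mc_h2_decompose` rebuilds the decomposition from
empirical genotype-cell frequencies and case rates of a large simulated
cohort (empirical-median threshold), through the *same* assembly arithmetic,
and attaches block standard errors (20 blocks; 10 proved too few for
reliable 3-sigma use). The analytic/Monte-Carlo agreement test runs over the
entire preset grid — roughly 120 simultaneous comparisons. A per-comparison
3-sigma rule would reject a perfect implementation in about a quarter of
realizations, so the suite enforces the 3-sigma level *family-wise*
(Bonferroni-calibrated multiplier, $z^\ast \approx 4.2$) and additionally
requires >95% of comparisons inside plain 3 standard errors. This is a
calibration of the joint test, not a loosening of any per-quantity
tolerance.

## Evaluation harness

Each test replicate is scored and fitted by maximum likelihood:
$\mathrm{logit}\,P(D=1) = \alpha + \beta\,\mathrm{GRS}$. Reported per fit:
the 1-df likelihood-ratio statistic and p-value against the intercept-only
null, the C-statistic, and $\mathrm{AIC} = 4 - 2\log L$. Choices:

* **C-statistic ties** get half credit (midrank / Mann-Whitney form) — the
  standard concordance definition; the tests verify it against brute force
  over all case-control pairs.
* **Degenerate fits**: a constant score yields the null fit (slope 0, LRT 0,
  C = 0.5), explicitly noted; separation flags `converged = FALSE` with the
  LRT taken from the profile deviance. Flagged replicates stay in the
  output and are counted (`n_flagged`), never silently excluded.
* **Power / type-I error** is the fraction of replicates with LRT p below
  $\alpha = 0.05$ (the only level used; configurable), with an exact
  binomial CI.
* **Pairwise contrasts** fit a two-way linear model (metric ~ method +
  scenario) and apply Tukey's HSD to the method pairs; a winner is declared
  below adjusted $p < 0.05$, with the preference direction per metric
  (larger power/C, smaller type-I error/AIC). Aggregation level — raw
  per-replicate values for C/AIC, per-scenario rates for power — mirrors the
  averaged-across-replicates reporting convention. Under the null
  calibration test the weighted scores are used unrescaled: with true null
  weights the estimated weight sum can legitimately be non-positive, and
  rescaling is affine anyway.

## What the synthetic world does and does not establish

The generators state a specific world: independent HWE loci (no population
structure, no genotyping error, no missingness), exactly balanced
case-control sampling, a Gaussian liability with median dichotomisation or a
small additive penetrance table, and four-to-six variant panels. Green tests
establish that the score constructions, weight estimation and evaluation
metrics behave correctly *in that world* and reproduce its analytic
heritabilities; they do not certify relative method performance under
covariates, haplotype-level LD ($r^2/D'$ on phased data is explicitly out of
scope — the LD construct here is a genotype-conditional table), rare-variant
panels of realistic size, or miscalibrated external weights.

Two stochastic anchors carry model-reconstruction caveats: the exact
supplementary model grids behind the published power table are not
available, so the power anchor of the lowest-heritability model is checked
within ±10 percentage points (the reconstruction's true power is a few
points above the printed value, with a binomial SE of ~4.4 at 100
replicates), and the type-I error anchor within two binomial standard errors
of the nominal 0.05 over 2000 replicates.

## Reproducibility

One root seed per study; replicate $r$ of stream $s$ uses the derived seed
$(48271\,\mathrm{root} + 1299721\,s + 7919\,r) \bmod (2^{31}-1)$, so any
single replicate is reproducible in isolation and training/test collections
never share draws (asserted). Manifests written by `cmd_simulate` embed the
full spec and per-replicate seeds; re-running a config reproduces the files
byte for byte.

## Known limitations

* Marginal (univariate) weight estimation is the evaluated practice — by
  design, since that is how published weights are produced; the framework
  does not fit joint or interaction-aware weights.
* The heritability enumeration is exponential in loci (capped at 8).
* The LD generator models one marker tagging one causal locus; no
  multi-marker haplotype structure.
* Scenario presets reconstruct the published model grid from its printed
  constraints; individual preset power values are therefore comparable in
  pattern, not digit for digit.
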