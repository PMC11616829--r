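---
title: "Joint common and rare variant selection from case-parent trios: models and methods"
author: "trioEMVS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint common and rare variant selection from case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Family-based designs are the standard defence against population
stratification in genetic association studies of early-onset disease. In the
case-parent trio design an affected child and both parents are genotyped and
phased; conditioning on the parental haplotypes, the only randomness left
under Mendelian transmission is *which* haplotype each parent transmitted.
Classical transmission-disequilibrium and burden/kernel tests exploit this,
but they either test one variant at a time (hopeless for rare variants) or
collapse a whole region into a single score (losing the identity of the
driving variants). `trioEMVS` fits one joint sparse regression over all
common and rare variants in a set of candidate regions and reports which
individual variants carry the signal.

# The likelihood

Let $g_{0n}$ be the affected child's additive genotype vector in family $n$
and $g_{in}$, $i = 1,2,3$, the three *pseudo-siblings* — the alternative
children obtainable from the untransmitted parental haplotypes. Conditional
on the parents and on the child being affected, a logistic disease model
with coefficient vector $\omega = (\beta', \alpha')'$ (common-variant
effects $\beta$, rare-variant effects $\alpha$) gives the 1:3 matched
conditional likelihood

$$
\ell(\omega) \;=\; \sum_{n=1}^{N}
  \log \frac{e^{g_{0n}\omega}}{\sum_{i=0}^{3} e^{g_{in}\omega}}
 \;=\; -\sum_{n=1}^{N}
  \log\Bigl(1 + \sum_{i=1}^{3} e^{-x_{in}\omega}\Bigr),
  \qquad x_{in} = g_{0n} - g_{in}.
$$

Parental genotype frequencies cancel out of this likelihood, which is what
makes the design robust to stratification and admixture. The package
reduces each phased trio to its three contrast rows $x_{in}$
(`enumeratePseudoSiblings()`, `buildContrasts()`); families whose four
configurations coincide contribute a constant and are retained.
Mendelian-inconsistent trios are dropped with a warning naming the variants,
never repaired — phase is taken as given. Genotypes are additive minor
allele counts; the minor allele is defined per dataset from the parental
haplotype pool, with ties at frequency $0.5$ kept on the original (ALT)
coding.

# Priors

Selection is encoded by spike-and-slab mixtures. Each common variant $s$
carries an indicator $\gamma_s \sim \mathrm{Ber}(\pi_1)$ and
$\beta_s \mid \gamma_s \sim N(0,\; \gamma_s v_1 + (1-\gamma_s) v_0)$ with
spike (exclusion) variance $v_0$ and slab (inclusion) variance $v_1$. Rare
variants use a dual indicator: a region-level gate
$\eta_r \sim \mathrm{Ber}(\pi_2)$ and, only when the gate is open,
within-region indicators $\lambda_{rj} \sim \mathrm{Ber}(\pi_3)$;
$\alpha_{rj}$ is slab-distributed ($v_3$) only when
$\eta_r \lambda_{rj} = 1$ and spike-distributed ($v_2$) otherwise. The
mixing weights get Beta priors $\pi_i \sim \mathrm{Beta}(a_i, b_i)$ with
$a_i = 1$ and $b_1 = S$, $b_2 = R$, $b_3 = L$ (the counts of common
variants, regions and rare variants), the usual multiplicity-balancing
choice; other hyper-parameters are accepted and the closed-form updates
generalize accordingly.

Parameter defaults, with units (all variances are on the squared log
odds-ratio scale):

| parameter | default | role |
|---|---|---|
| $v_1$ | 0.4 | common slab; 95% prior odds-ratio coverage ≈ 0.29–3.45 |
| $v_3$ | 0.5 | rare slab; 95% prior odds-ratio coverage ≈ 0.27–4.3 |
| $v_0, v_2$ | 0.003 | exclusion scales, the tuning targets; the default is the central value of the default tuning grid |
| $a_i, b_i$ | $1$; $S, R, L$ | multiplicity control |
| threshold | 0.5 | posterior-mode selection rule |

# The EM algorithm

The indicators are treated as missing data. The E-step has closed forms:
$p_s = \Pr(\gamma_s = 1 \mid \cdot)$ by a two-density Bayes rule,
$q_{rj} = \Pr(\lambda_{rj} = 1 \mid \eta_r = 1, \cdot)$, and the region
probability $g_r = \Pr(\eta_r = 1 \mid \cdot)$, whose numerator multiplies
the per-member two-component mixtures (all density ratios are formed in log
space; probabilities are never clipped inside updates). The M-step
minimizes the strongly convex penalized loss

$$
\sum_n \log\bigl(1 + \textstyle\sum_i e^{-x_{in}\omega}\bigr)
  + \tfrac12\, \omega' P^{(k)} \omega,
$$

where $P^{(k)}$ is diagonal with entries $(1-p_s)/v_0 + p_s/v_1$ for common
variants and, by default, $(1 - g_r q_{rj})/v_2 + g_r q_{rj}/v_3$ for rare
variants — the *joint* expectation $E[\eta_r \lambda_{rj}] = g_r q_{rj}$,
which is the exact conditional expectation in the complete-data objective
and therefore preserves the EM ascent guarantee; it also lets a closed
region gate keep its members shrunk. The variant that uses $q_{rj}$ alone
(conditional on the gate being open) is available as
`penaltyExpectation = "conditional"`; on the simulation conditions studied
here the two are nearly indistinguishable. The mixing weights have
closed-form updates, e.g. $\pi_1 = \sum_s p_s / (2S - 1)$ at the default
hyper-parameters.

Two M-step solvers are provided and cross-checked against each other in the
test suite: a damped Newton method with Armijo backtracking (default;
deterministic), and a randomized coordinate-descent solver with exact
one-dimensional Newton steps and a seeded coordinate order. Both stop on a
relative gradient norm of $10^{-8}$; a stalled line search at machine
precision counts as converged. The unique minimizer makes the choice of
solver irrelevant to the result.

Convergence of the EM loop is declared when the observed-data log-posterior
(the likelihood plus the indicator-marginalized priors — the indicators
integrate out in closed form) changes by less than $\epsilon = 10^{-4}$
between iterations; the iteration cap is 500 and hitting it flags the fit
as unconverged. The trace of this objective is stored per iteration; at
$t = 1$ it is non-decreasing, which the tests assert to $10^{-9}$.

## Initialization and annealing

Every coefficient starts at $0.5$, deep inside the slab: the first E-step
places each variant in the model, the first M-step is then a lightly
penalized (ridge-like) fit, and subsequent iterations prune the variants
whose likelihood information cannot hold their coefficients against the
spike. This "start dense, prune" schedule is what gives the method its
characteristic behaviour: a variant survives when its nearly-unpenalized
estimate carries more evidence for the slab than the multiplicity-adjusted
prior odds against it, so well-informed variants with moderate effects are
kept while poorly-informed variants with wildly noisy estimates are crushed
early.

A deterministic-annealing schedule (E-step probabilities tempered by an
exponent $t$ raised from 0.1 to 1 in steps of 0.1, one EM sweep per
temperature) is implemented and available through the `anneal` argument,
but is *off by default*. On panels with tens of rare variants per region
the tempered sweeps hold every rare-variant penalty near
$\tfrac12(1/v_2 + 1/v_3)$ for the whole ramp; that is enough shrinkage to
push even strongly supported rare coefficients below their evidence
threshold before the temperature rises, after which the rare side of the
model collapses into the degenerate empty mode for every exclusion variance
in the tuning range. The t = 1 schedule from the dense start does not
suffer from this and is the default; the mixing weights start at their
prior means in either case (configurable via `initPi`).

## Final selection

A common variant is selected when $p_s \ge 0.5$; a rare variant when the
joint probability $g_r q_{rj} \ge 0.5$, so a closed region suppresses its
members; a region when $g_r \ge 0.5$ or any member variant is selected.
The 0.5 threshold is the posterior-mode rule and is configurable
everywhere it appears.

# Tuning the exclusion variances

The slabs are fixed ($v_1 = 0.4$, $v_3 = 0.5$); selection is controlled by
the exclusion variances, chosen from the stability of regularization paths
(`regularizationPath()`, `stableWindow()`, `tunePriors()`):

1. **Stage 1** moves $v_0 = v_2$ jointly along a grid and fixes $v_0$
   where the *selected set of common variants* is stable — at least three
   consecutive grid points with identical selected sets and selected
   coefficients changing by under 10% ("no shrinkage").
2. **Stage 2** holds $v_0$ and re-tunes $v_2$ along a grid, judging
   stability on the *selected rare variants*.

Design choices that were genuinely open, and how they were resolved:

* *Stability scope.* Each stage is judged on the variants its parameter
  governs. Judging stage 1 jointly on all variants couples the common
  exclusion scale to rare-variant noise, whose selected sets churn along
  the whole path, and no window is ever found.
* *Grids.* The default grid is log-spaced,
  $\{10^{-4}, 3\cdot10^{-4}, \dots, 0.1\}$; stage 1 stops at $0.01$
  because a common "exclusion" standard deviation of $0.1$ on a log
  odds-ratio is no longer small against the slab ($\sqrt{0.4}$), and
  plateaus there reflect overshrinkage of individually well-informed
  common variants rather than stability.
* *Fallback.* When no three-point window exists, the longest run is used,
  with ties resolved toward the *larger* grid values: vanishingly small
  exclusion variances admit saturated solutions (everything in the slab)
  that are trivially stable, so the low end must not win ties. A warning
  marks the fallback.
* *Cold paths.* Each grid point is fitted cold by default so the points
  are comparable; warm-starting along the path (faster, but it drags one
  grid point's mode into the next) is available via `warmStart = TRUE`.

# The synthetic-trio generator

`buildPool()`, `assignEffects()` and `simulateTrios()` generate phased
case-parent trios from a parametric admixed haplotype pool, standing in for
a coalescent simulation at desk scale. The defaults define the study
conditions used throughout the tests and the acceptance script:

* two subpopulations mixed 25% / 75%; each family is drawn wholly from one
  subpopulation (within-race pairing implies admixture between, not
  within, families);
* 12 gene regions of 2,700 bp, each with 2 common sites (weighted MAF
  uniform on 0.1–0.4) and 8 rare sites from a bottom-heavy spectrum (5
  sites with weighted MAF in $[10^{-4}, 10^{-3})$, 2 in $[10^{-3}, 0.01)$,
  1 in $[0.01, 0.04)$), reflecting that most rare variation in sequencing
  panels is very rare;
* subpopulation frequencies scattered around each weighted MAF
  (`divergence = 0.5`) and renormalized so the admixture-weighted average
  is exact;
* a designated *sentinel* rare site of weighted MAF 0.026 in region 1,
  always causal and risk-increasing — the benchmark for individual
  rare-variant detection;
* two causal common variants of effects $+0.9$ and $-0.9$ in regions 3
  and 6; causal rare variants confined to regions 1–6 with per-region
  counts $(3,1,2,2,1,2)$ among sites of weighted MAF $< 0.03$, effect
  magnitudes $0.4\,|\log_{10}\mathrm{MAF}|$ (rarer acts stronger), signs
  split evenly with a seeded coin for odd counts. A causal-fraction rule
  (5% of eligible sites) is available via `causalFraction`;
* disease risk $\mathrm{logit}\,P(y=1) = -2.2 + \sum_c \beta_c G_c$ on the
  child's causal genotypes; trios are accepted by rejection sampling with
  exactly this probability, reproducing ascertainment through the affected
  child (null acceptance rate $1/(1+e^{2.2}) \approx 0.0998$, which the
  tests check against the realized rate);
* analysis excludes sites with parental minor-allele count at most 3
  (`minMAC = 3`), the usual omission of singletons, doubletons and
  tripletons from individual-variant analysis; the truth table keeps every
  site with its polymorphism flag, so evaluation denominators are
  unaffected.

What the generator does *not* emulate: linkage disequilibrium (sites are
drawn independently per haplotype; an ultra-rare site in real data shares
its carrier haplotypes with neighbours, so independent sites somewhat
overstate the number of independent noise opportunities), recombination,
genotyping or phasing error, and the full site density of a sequenced
region. Passing tests therefore demonstrate correct behaviour of the
machinery and calibration under the stated spectrum, not performance on LD
structured data.

Determinism: a single seed fixes a dataset byte-for-byte; the pool and the
causal model are built once from their own seed and act as the fixed study
design, with replicate datasets drawn from per-replicate seeds.

# Evaluation metrics

Over replicate analyses the package computes the region-level weighted
average correct association percentage
$\tfrac12[\overline{P}(\mathrm{selected} \mid \mathrm{associated}) +
\overline{P}(\mathrm{unselected} \mid \mathrm{unassociated})]$ (`wacap()`),
and variant-level average true/false positive rates whose per-dataset
denominators count only variants polymorphic in that dataset — or only
variants polymorphic in *every* dataset with
`restrict = "allPolymorphic"` (`atprAfpr()`), plus a MAF-stratified table
(`mafStratifiedReport()`). Replicates with an empty denominator are
skipped for the affected rate with a warning.

# Problem sizes

The shipped tests and the acceptance script use the default 120-site pool
with replicate counts of 10–25 at 350 and 1,500 trios — sizes chosen so a
full run of the statistical suite completes in a few minutes on one core
while the Monte Carlo error of the reported rates stays within a few
percentage points. Single fits at these sizes take well under a second;
two-stage tuning adds twelve path fits.

# Known limitations

* Phase is assumed correct; phasing uncertainty is not propagated.
* No covariates, gene-environment interactions, quantitative traits, or
  missing genotypes within a retained trio.
* Posterior modes only — no MCMC, so no posterior credible intervals.
* The dense-start EM finds a good mode, not a certified global one; on
  panels with heavy LD the selected representative of a correlated block
  may be arbitrary (real-data analyses in this field show exactly this).
* The region gate weakens when a region holds very few rare variants;
  single-variant "regions" reduce the dual indicator to an ordinary
  spike-and-slab.
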