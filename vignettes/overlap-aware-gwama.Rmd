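---
title: "Overlap-aware multivariate GWAMA: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-aware multivariate GWAMA: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggmeta)
```

## The problem

Childhood-behaviour consortia collect many partially redundant GWASs of the
same trait: within a cohort the same children may be scored by their mother,
father, teacher, or themselves, with several instruments, at several ages.
Each cohort-by-rater-by-instrument-by-age cell ("stratum") yields one
univariate GWAS. A meta-analysis that treats these strata as independent
overstates the evidence: when two strata share individuals, their Z
statistics are correlated *under the null*, and the naive combined statistic
has variance above one — its test is anti-conservative and every downstream
quantity (effective sample size, heritability, genetic correlations)
inherits the distortion.

`aggmeta` implements a sample-overlap-aware multivariate meta-analysis for
this setting, together with the stratum-admission rules, post-meta filters,
and a minimal LD-score-regression (LDSC) toolkit used to evaluate the
products. A synthetic multi-cohort, multi-rater generator stands in for
consortium data and drives calibration and recovery studies.

## The model

For SNP $j$ observed in $P$ strata with Z scores $Z_{ji}$, per-SNP sample
sizes $N_{ji}$ and weights $w_{ji} = \sqrt{N_{ji} h^2_{\mathrm{SNP},i}}$,
the combined statistic is the generalized-least-squares form

$$
Z_{\mathrm{multi},j} \;=\;
\frac{\sum_i w_{ji} Z_{ji}}
     {\sqrt{\sum_i \sum_k w_{ji} w_{jk}\, \mathrm{CTI}_{ik}}},
$$

where the cross-trait intercept (CTI) matrix holds the expected null
covariance between the strata's Z statistics. Rather than estimating the
CTI by bivariate LDSC — unstable at stratum-level sample sizes — it is
computed analytically from the observed overlap:

$$
\mathrm{CTI}_{ik} \;=\; \frac{N_s\, r_p}{\sqrt{N_{ji} N_{jk}}},
$$

with $N_s$ the number of shared individuals and $r_p$ their phenotypic
correlation; the diagonal is 1 and cross-cohort entries are 0. The
effective sample size of the combined analysis is

$$
N_{\mathrm{eff}} \;=\; \sqrt{N}^{\!\top} \,\mathrm{CTI}^{-1} \sqrt{N},
$$

which equals $\sum_i N_i$ exactly when the CTI is the identity and shrinks
toward a single stratum's $N$ as two strata approach duplication.

Under a correct CTI, $Z_{\mathrm{multi}}$ has unit variance under the null;
this is the property the calibration study verifies, and the reason the
quadratic (`form = "gls"`) denominator is the default. The denominator as
typeset in the source method table — linear in $w$ with
$\sqrt{w_i w_k}$ cross terms — is dimensionally inconsistent with its own
numerator; it is preserved verbatim behind `form = "as_printed"` for
comparison, and coincides with the quadratic form at unit weights.

Two modelling conventions matter in practice:

* **Weights.** Per-stratum $h^2$ is rarely estimable at stratum sizes, so
  a single uniform value (default 0.03, the scale typically reported for
  this class of childhood-behaviour phenotypes) is used, under which the
  weights reduce to $\sqrt{N}$ — classic sample-size weighting. The gls
  statistic is invariant to rescaling all weights, so the uniform value's
  magnitude is irrelevant; only *relative* per-stratum values matter, and
  those are user-configurable.
* **Per-SNP overlap.** Consortia report one $N_s$ per stratum pair, but a
  SNP genotyped in only part of a stratum cannot share more individuals
  than it has: $N_s$ is capped at $\min(N_{ji}, N_{jk})$ per SNP. This is
  conservative — the cap can only lower the claimed overlap.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `h2` (weights) | 0.03 | assumed per-stratum SNP-heritability; uniform value ⇒ $\sqrt{N}$ weighting |
| `min_obs` | 450 | minimum observations for a stratum to enter any meta-analysis (inclusive) |
| `min_bin_obs` | 15 000 | strict lower bound for an age bin's or instrument subset's total observations |
| `min_maf`, `min_neff`, `min_cohorts` | 0.01, 15 000, 2 | post-meta SNP filters |
| QC tiers | 0.05 / 0.03 / 0.01 | MAF floor for strata with fewer than 5 000 / 15 000 / more observations |
| palindromic window | EAF ∈ [0.4, 0.6] | strand-ambiguous A/T and C/G SNPs dropped everywhere |
| `rg_gate` | $h^2/\mathrm{SE} \ge 4$ | heritability Z needed before a stratum enters genetic-correlation analyses |
| `n_blocks` | 200 | contiguous delete-a-block jackknife blocks in LDSC |

The admission, binning, filter and gate thresholds reproduce the decision
rules of the consortium analysis this pipeline operationalizes; the QC
tiers are configurable stand-ins for supplementary-level per-cohort tiers
and are recorded with the output.

## Harmonization rules

Strata are matched by rsID, not chromosome–position, because cohorts may
sit on different genome builds; coordinates are carried as annotation only.
Against the reference orientation (first table by default): identical
pairs pass; swapped pairs flip ($z \to -z$, $\mathrm{EAF} \to
1-\mathrm{EAF}$); strand-complemented pairs are complemented and then the
swap rule applies; irreconcilable pairs are dropped. For palindromic SNPs
a strand flip is indistinguishable from an allele swap by the letters
alone, so inside the ambiguity window [0.4, 0.6] the SNP is dropped from
*all* tables, and outside it orientation is resolved by whichever choice
brings the allele frequency closer to the reference's (a strict-inequality
rule, which keeps harmonization idempotent).

## Age-bin construction

The published constraint is that each rater-specific age bin must exceed
15 000 observations; the binning algorithm itself is not published. The
planner uses greedy left-to-right accumulation over strata sorted by mean
age: pool adjacent strata until the running total exceeds the floor, close
the bin, and merge a trailing underweight remainder into the previous bin.
Greedy contiguous bins keep the age axis interpretable, and the realized
boundaries are reported rather than assumed. "Exceeds" is read strictly:
a rater totalling exactly 15 000 gets no bins.

## LDSC-lite

The evaluation layer regresses per-SNP $\chi^2 = z^2$ on
$N \ell_j / M$ (univariate) or $z_1 z_2$ on
$\sqrt{N_1 N_2}\,\ell_j / M$ (cross-trait), with a free intercept that
captures confounding inflation (univariate) or the sample-overlap term
(cross-trait). It is deliberately the smallest faithful version of the
cited estimator:

* heteroscedasticity weights $1/(2 (1 + N h^2_0 \ell / M)^2)$ from a
  one-step pre-fit (not fully iterated, no $1/\ell$ over-counting
  weights);
* standard errors by delete-a-block jackknife over 200 contiguous blocks,
  jointly over the genetic-covariance slope and the companion univariate
  $h^2$ fits so that the genetic correlation
  $r_g = \rho_g/\sqrt{h^2_1 h^2_2}$ is jackknifed as the ratio it is;
* $r_g$ and intercepts reported untruncated (estimates may exceed $|1|$).

Computing LD scores from a genotype panel is out of scope: profiles are
supplied as files or simulated (`simulate_ld_profile()`, a shifted-gamma
shape with a long right tail). Intervals from the ratio jackknife are
accurate to a few percent of nominal coverage (measured 88–95% for
2·SE intervals across the regimes exercised in the tests) — adequate for
the gating and recovery decisions they support, but not exact.

## The synthetic generator

`sim_config()` declares the study: by default 2 cohorts × 2 000
individuals × 5 000 independent SNPs with allele frequencies uniform on
[0.05, 0.5], two raters each assessing a random half of every cohort
(giving ~50% pairwise overlap), per-rater $h^2 = 0.03$, cross-rater
$r_g = 0.8$ and a target phenotypic correlation of 0.29 in shared
individuals — the median reported for within-cohort stratum pairs, whose
published range (≈0.1–0.4) the sampling variability of the per-cohort
empirical correlations naturally spans. Cross-rater residual correlations
are solved from the phenotypic target via

$$
r_p \;=\; r_g \sqrt{h^2_i h^2_k} \;+\; r_e \sqrt{(1-h^2_i)(1-h^2_k)},
$$

erroring when the implied $r_e$ leaves $[-1, 1]$. True per-SNP effects are
drawn once per study (shared across cohorts) from a zero-mean multivariate
normal across raters with correlation $r_g$; genotypes are
$\mathrm{Binomial}(2, \mathrm{maf})$ dosages; every operation is
bit-reproducible from the single config seed.

Deliberate simplifications, and what they imply about the tests:

* **No LD between SNPs.** The meta-analysis layer never uses LD, so its
  calibration results transfer directly. LDSC, however, sees its
  regressor only through the *effect-variance profile*: when a config
  carries an LD profile, per-SNP effect variances are drawn proportional
  to scores normalised to mean 1, which reproduces the canonical
  $E[\chi^2_j] = 1 + N h^2 \ell_j / M$ regression while keeping total
  SNP-heritability at $h^2$. LD-dependent behaviour beyond that relation
  (attenuation from long-range LD, MAF-dependent architecture) is not
  emulated — LDSC recovery tests therefore validate the estimator, not
  robustness to real LD.
* **No relatedness, ascertainment or rater bias** beyond the
  assessed-subset masks; overlap is the only dependence mechanism, which
  is exactly the mechanism the CTI models.
* **Infinitesimal architecture by default** (every SNP causal), matching
  the polygenicity assumption of both the weighting scheme and LDSC; a
  sparse mode (`k_causal`) exists for power and ranking checks.

## Numerical choices

* **PSD repair.** User-supplied overlap/correlation tables are often
  slightly inconsistent; a non-positive-semi-definite CTI has its
  eigenvalues clipped at $10^{-8}$ and is rescaled to unit diagonal, with
  a message. Perfect duplication (reciprocal condition number below
  $10^{-7}$ after repair) is an error instructing the caller to merge the
  strata — silently pseudo-inverting would fabricate information.
* **Degenerate GWAS inputs.** A constant phenotype or monomorphic SNP
  yields $z = 0$ rather than NaN; meta-level P values are floored at the
  smallest positive double so $p \in (0, 1]$ holds exactly.
* **Tie-breaks.** Strata are sorted by id within equal mean ages, making
  the planner order-independent; jackknife blocks are contiguous in input
  order.
* **Problem sizes.** The test and acceptance runs use the desk-scale
  defaults above (100 000 pooled null SNP tests for calibration across 20
  replicate studies; $M = 10\,000$, $N = 50\,000$, 50 replicates for LDSC
  recovery) — sizes chosen so every formula is exercised with informative
  Monte-Carlo precision on a single CPU.

## Known limitations

* The expected-CTI approach assumes the reported $N_s$ and $r_p$ are
  accurate; misreported overlap surfaces as residual intercept inflation
  in LDSC (the pipeline reports, but does not correct, that intercept).
* The `as_printed` statistic is provided for comparison only; it is not
  scale-invariant in the weights and is not null-calibrated except at
  unit weights.
* Jackknife intervals from LDSC-lite are approximate (see above); for
  publication-grade intervals the full estimator with its complete
  weighting scheme should be used.
* QC tiers default to plausible stand-ins; consortium-specific tiers
  should be supplied via `qc_tiers()` when known.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
library(aggmeta)

cfg <- sim_config(h2 = 0.03, rg = 0.8, rp_target = 0.29, seed = 1)
sim <- simulate_study(cfg)

harm <- harmonize_sumstats(sim$tables)
plan <- build_plan(sim$meta)

overall <- run_meta(harm, sim$meta, sim$spec, subset = plan$subsets$overall)
autoplot(overall)

ld  <- simulate_ld_profile(cfg$m_snps, mean_one = TRUE)
fit <- univariate_ldsc(overall, ld)
tidy(fit)

calib <- calibration_study(sim_config(h2 = 0, seed = 1), n_replicates = 20)
calib$summary
autoplot(calib)
```
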