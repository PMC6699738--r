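---
title: "Rare-variant gene-level association and interpretation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene-level association and interpretation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rvassoc)
```

## The problem

Strong-effect protein-coding variants for common diseases such as type 2
diabetes are mostly rare (minor allele frequency below 0.5%), so
single-variant tests are underpowered and signal must be aggregated across
the qualifying alleles of a gene. `rvassoc` implements the full aggregation
and interpretation workflow of a large case-control exome study — severity
masks, burden and SKAT tests with principled consolidation, matched-gene
set enrichment, direction-of-effect evaluation, liability-variance and
power planning, and an empirically calibrated posterior probability of
association — together with a seeded synthetic-cohort generator, so every
stage is testable without controlled-access genotype data.

## The synthetic cohort generator

The generator draws, per gene, a negative-binomial number of variants whose
minor allele frequencies follow a three-bin spectrum (defaults: 2.3% common
with MAF > 5%, 4.2% low-frequency, 93.5% rare with MAF < 0.5%, log-uniform
within bins — the composition of a deeply sequenced multi-ancestry exome
dataset). Genotypes are Hardy–Weinberg draws, independent across variants:
rare alleles carry essentially no linkage disequilibrium, which is the one
major simplification relative to real exomes, and means that passing tests
here says nothing about confounding by LD with nearby common variants (the
package's causal-fraction parameter exists precisely because real data do
have LD proxies). Disease status comes from a logistic model, additive in
dosage on the log-odds scale, with per-subgroup intercepts calibrated by
root-finding so the expected population prevalence equals K = 0.08 before
ascertainment; the requested case/control counts are then sampled from a
population pool of 20 times the requested size. Odds-ratio
parameterization was chosen over a liability-threshold generative model
because every downstream test is odds-ratio based; the liability model
appears only as the oracle for variance-explained calculations.

Gene architectures mirror the patterns that motivate gene-level testing:
an `allelic_series` rescales its qualifying rare alleles to a target
aggregate carrier frequency (for example 1.4% with per-variant OR near
0.4, a protective series), `single_driver` plants one low-frequency
variant over a null background, and `mixed_direction` alternates signs —
the configuration in which a variance-component test should beat a burden
test. Five binary deleteriousness predictor calls are conditionally
independent Bernoulli draws given a latent damaging state (agreement
parameter 0.8 by default), and protein-truncating variants are flagged
high-confidence with probability 0.95. Missingness is injected completely
at random (default rate 0.005), with an optional per-subgroup multiplier
as a differential-missingness stressor. A single master seed is expanded
into named substreams (annotations, genotypes, phenotypes, ascertainment,
missingness, replication) so adding a stage never perturbs earlier draws
and identical configurations are byte-identical.

## Masks and gene-level tests

A mask is a predicate on consequence class, the number of damaging
predictor calls, the allele frequency (strict "<" ceilings computed from
the combined analysis cohort), and the PTV-confidence flag. The seven
defaults run from high-confidence PTVs only to all nonsynonymous variants
under a 0.5% ceiling, using the standard "x/5 y%" naming; published mask
definitions live in supplementary material that varies between studies, so
these defaults are documented reconstructions and fully overridable.
Groupings are built per gene, transcript set (up to three), and mask;
identical transcript-set groupings are collapsed with their multiplicity
recorded so they never multiple-count downstream.

The burden test regresses status on the per-sample weighted allele count.
Missing genotypes count as reference in burden scores — conservative for
rare alleles — whereas single-variant tests mean-impute within subgroup;
the asymmetry is deliberate and documented. The regression is
Firth-penalized (Jeffreys prior) whenever the carrier count is below 50,
otherwise plain maximum likelihood for speed; P values are (penalized)
likelihood-ratio tests, with the restricted model profiled on the full
design so the statistic is the proper penalized LRT. Newton iterations
stop at score norm 1e-8 or 50 iterations, and non-convergence is flagged,
never dropped. SKAT is the variance-component score statistic under the
logistic null, with uniform kernel weights within a mask (masks already
encode severity; frequency weighting is a config option); the tail is Liu
moment matching, refined by exact Imhof numeric integration whenever the
moment-matched P falls below 0.2 — the region where the approximation
error is material for decisions (moment matching alone proved measurably
conservative at the 5% level). The weighted (haploinsufficiency) test enters all
nonsynonymous variants with inactivation weights: 1.0 for high-confidence
PTVs, 0.5 for low-confidence PTVs, and 0.5 x (damaging calls)/5 for
missense and splice variants.

## Consolidation and the effective number of masks

Per-gene results are consolidated by correcting the smallest P value with
a Šidák-type adjustment `1 - (1 - p_min)^m_eff`, where
`m_eff = (Σ√λ)² / Σλ` from the eigenvalues of the correlation matrix of
the per-sample grouping scores. Several design choices required empirical
arbitration, and all were settled by the package's own oracles rather
than by assumption:

* The eigenvalue estimator was chosen over integer-snapping alternatives
  because it tracks the permutation min-P oracle (`permutation_meff`, the
  exact null minimum-P distribution over fresh Gaussian phenotypes) to a
  few percent on nested-mask structures, where integer-valued estimators
  deviate by ~18%. The oracle remains the arbiter in the test suite
  (agreement within 15% required).
* All distinct groupings (mask x transcript set) enter one consolidation
  step with a single `m_eff`, rather than a mask-level step followed by a
  transcript-set-level count correction. Near-identical transcript sets
  then contribute almost nothing to the exponent, which a count-based
  second correction would overstate; the two-stage variant proved
  measurably conservative under the simulating null.
* The SKAT minimum-P correction uses its own effective-test count: SKAT
  statistics across nested masks are more strongly dependent than the
  burden scores (they share squared score components), so the burden
  `m_eff` over-corrects them. The count is estimated by drawing the
  per-variant score vector from its exact null covariance `G'P0G`,
  computing each grouping's SKAT P, and inverting `E[min P] = 1/(1+m)`.
* Groupings with fewer than `min_carriers = 20` carriers are excluded from
  consolidation (kept in the per-mask output). Their test statistics are
  so discrete that they cannot produce small P values, yet they would
  still inflate `m_eff`; dropping them is the usual minimum-count rule of
  aggregate testing and restores null calibration at desk-scale sample
  sizes (at biobank scale the filter is inert).

The four consolidated statistics are required to be calibrated at the 5%
level within exact-binomial 99% intervals over 2,000 simulated null genes
at 2,500 cases / 2,500 controls.

## Single-variant tests and meta-analysis

The score test defaults to the logistic-model score statistic; a gaussian
family implements the quantitative-scale (Armitage-style) statistic, and
the two coincide exactly without covariates. The kinship-adjusted test is
a deliberately simplified EMMAX: the binary trait is treated as
quantitative, variance components are estimated once by maximum likelihood
on the kinship eigenbasis, and a generalized-least-squares score test
follows; with a scaled-identity kinship the components are jointly
unidentifiable, the working covariance is proportional to the identity for
any estimate, and the test reduces exactly to the gaussian score test.
Stratified scans run per subgroup and combine by fixed-effect
inverse-variance meta-analysis; a pooled mega-analysis mode exists as a
cross-check, and sample-size-weighted z meta-analysis supports combining
with external studies that report only directions and P values.

## Gene sets, directions, LVE, and power

Matched comparison genes are sampled per set gene from the same
(log2 variant count, width 1) x (log10 aggregate frequency, width 0.5)
bin — per-gene matching, which reproduces the set's bin profile exactly
when bins are adequate, with a nearest-bin fallback that warns. Enrichment
is a one-sided rank-sum on the burden minimum-P statistic (midranks,
continuity-corrected normal approximation; complete enumeration when both
groups have at most 10 members). Direction concordance uses the one-sided
exact binomial test throughout.

Liability variance explained follows the classical liability-threshold
construction: solve the baseline risk so the genotype-frequency-weighted
risk equals K, map genotype risks to mean liability shifts through the
normal quantile at threshold `qnorm(1 - K)`, and take the between-genotype
variance over total variance. Gene-level LVE treats the gene as one
biallelic pseudo-variant with multiplicative risks, converting OR to RR
via `RR = OR / (1 - K + K OR)` (switchable to the rare-outcome identity).
Because the exact published variance-explained equations are in
supplementary material, a Monte-Carlo liability oracle — not printed
gene-level values — is the correctness arbiter, on a 27-point grid within
two Monte-Carlo standard errors at 1e6 draws per point. The exponential
rank model `LVE_n = exp(a n + b)` is fitted by least squares on the log
scale, and top-N extrapolation uses the geometric closed form (asserted
equal to term-wise summation). Power uses expected case/control allele
frequencies under the prevalence-K disease model and the two-proportion
normal approximation; the published power method is not printed in full,
so ordering claims, not equalities, are tested against it. The
balanced-to-population conversion uses the binomial-information convention
`N = n_eff / (4 K (1 - K))`, which is documented here precisely because
printed population equivalents are not exactly recoverable.

## Posterior probability of association

For each discovery P stratum the replication direction concordance C is
inverted through the two-component identity `C = pi d + (1 - pi)/2`, where
the direction power `d = E[Phi(|beta|/se_rep)]` is estimated from
discovery effects shrunk by a factor 0.8 to counter winner's curse (a
documented reconstruction; the exact published conversion equation is
supplementary). Bootstrap intervals propagate from C to pi. Causal
posteriors scale by a causal-fraction grid {0.25, 0.40, 0.55} (0.40 as the
headline, matching a mid-range choice), Bayes factors are calibrated
against a user-supplied training prior (no silent default), and
gene-specific priors re-weight through exact odds algebra. The
beta-uniform mixture `f(p) = lambda + (1 - lambda) alpha p^(alpha - 1)` is
fitted by bounded maximum likelihood, with the uniform model enforced as a
lower bound via its nesting. Default strata are {5e-4, 5e-3, 0.05, 0.5, 1}.
These posteriors apply to single-variant associations only; gene-level
posteriors would need gene-level replication and are out of scope.

## Numerical choices and problem sizes

Degenerate inputs error early and explicitly: monomorphic dosages,
all-case phenotypes, all-zero weights, empty masks, non-PSD kinship,
multiallelic variant ids. Genotype matrices are sparse end to end
(memory proportional to carrier count), with per-gene submatrices
densified for the small linear algebra. Test-suite simulation sizes are
the package's own choices balancing Monte-Carlo resolution against
desk-scale runtime: 2,000-unit null calibrations at 4,000–5,000 samples,
recovery studies of 100–300 replicates (the protective allelic series at
1,500/1,500 with aggregate carrier frequency 1.4% and OR 0.40; the
allele-removal phenomenon at the ~43,000-sample scale where such series
are actually detected), 1e6-draw LVE oracles with stratified-antithetic
variance reduction, and 10,000-draw min-P oracles. The `analysis/`
drivers run the same stages at a 20,000-sample, 300-gene scale.

## Known limitations

No linkage disequilibrium, relatedness, or sequencing artefacts in the
generator; the simplified mixed model estimates variance components once
and is not full EMMAX/REML; mask defaults are reconstructions; the
concordance-to-PPA inversion is a linear two-component model validated by
simulation, not against printed study-specific posterior percentages,
which are functions of the original controlled-access data.
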