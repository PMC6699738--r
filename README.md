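# rvassoc

Rare-variant gene-level association testing and interpretation for
case-control exome studies, with a seeded synthetic-cohort generator so the
whole workflow runs and is tested without controlled-access genotype data.

## The problem

Strong-effect coding variants for common diseases such as type 2 diabetes
are mostly rare (MAF < 0.5%), so evidence must be aggregated across the
qualifying alleles of a gene. The aggregation pipeline implemented here:

* **Severity masks** — per gene and transcript set, variants are grouped by
  predicted severity: consequence class, number of damaging in-silico
  predictor calls, a strict MAF ceiling, and PTV confidence (the usual
  "x/5 y%" naming). Identical transcript-set groupings are collapsed.
* **Gene-level tests** — a burden test (Firth-penalized logistic regression
  of status on the weighted allele count; finite under separation) and
  SKAT (variance-component score statistic, mixture-of-chi-squares tail by
  moment matching with exact Imhof integration where it matters), plus a
  haploinsufficiency-weighted version where every nonsynonymous variant
  enters with its estimated probability of gene inactivation.
* **Minimum-P consolidation** — the smallest P over a gene's groupings is
  corrected as `1 - (1 - p_min)^m_eff`, where the effective number of
  masks `m_eff = (Σ√λ)²/Σλ` comes from the eigenvalues of the mask-score
  correlation matrix (a permutation min-P oracle is the in-package
  arbiter), giving four statistics per gene: burden/SKAT × min-P/weighted,
  with the exome-wide threshold `0.05/(2·2·19020) = 6.57e-7`.
* **Dissection** — progressive allele removal and per-allele conditional
  tests distinguish an allelic series from a single-driver gene.
* **Single-variant tests** — Firth, score, and a simplified kinship-adjusted
  (EMMAX-style) score test, run per subgroup and combined by fixed-effect
  inverse-variance or sample-size-weighted meta-analysis.
* **Gene sets and directions** — matched-gene construction (same variant
  count × aggregate frequency bins), one-sided rank-sum enrichment, and
  one-sided exact binomial direction-of-effect concordance.
* **Planning** — liability variance explained (LVE) under the
  liability-threshold model at prevalence K, the exponential rank model
  `LVE_n = exp(a·n + b)` with top-N extrapolation, case-control power, and
  effective/population-equivalent sample sizes.
* **Interpretation** — replication direction concordance per discovery-P
  stratum inverted to a posterior probability of association via
  `C = π·d + (1-π)/2`, causal scaling, Bayes-factor gene priors, and a
  beta-uniform mixture estimate of the non-null proportion.

## Worked example

The numbered drivers under `analysis/` run the full study on a synthetic
cohort of 10,000 cases / 10,000 controls across 25 subgroups and 5
ancestries, with four planted gene architectures among 300 genes
(protective allelic series at aggregate carrier frequency 1.4% and
per-variant OR ≈ 0.4; a risk series; a low-frequency single driver; a
mixed-direction gene):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_single_variant.R
Rscript analysis/03_gene_level.R
Rscript analysis/04_gene_sets.R
Rscript analysis/05_heritability_power.R
Rscript analysis/06_ppa.R
```

Output actually printed by this chain (seed 20240901):

```
frequency spectrum: 2.0% common, 3.8% low, 94.2% rare (targets 2.3/4.2/93.5)
pool prevalence before ascertainment: 0.0802 (target 0.08)
planted rare alleles reaching P < 0.05 individually: 9/18
  G0010  P = 5.09e-09  OR = 0.42  mask = 0/5 0.5%  m_eff = 3.4
planted genes among the top 10 by burden min-P: 4/4
mixed-direction gene G0040: burden min-P = 5.24e-05 vs SKAT min-P = 1.6e-08
G0010 burden signal (P = 1.48e-09 over 9 alleles) stays nominally
  significant after removing its 5 strongest alleles
driver gene G0050: burden P = 3.66e-06 drops to P = 0.45 conditional on the driver
candidate set enrichment: one-sided rank-sum P = 0.0165; random control P = 0.895
effective sample size 20,791/24,440: 44937; population equivalent at K=0.08: 152638
top-100 LVE extrapolation (published coefficients): 1.91%
```

Reading it: individually, half the planted rare alleles are invisible
(9/18 at P < 0.05) while every planted gene tops the gene-level scan —
the aggregation argument in one line. The protective series keeps its
signal after losing its strongest alleles (an allelic series), whereas the
driver gene's signal vanishes when its one driver is conditioned on. The
planning numbers convert an unbalanced 20,791/24,440 design into its
balanced (44,937) and population (≈152,600 at 8% prevalence) equivalents.

`run_pipeline()` orchestrates the same stages from a single YAML
configuration with a manifest and byte-identical reruns; see
`?pipeline_config`.

## Vignette

`vignettes/rare-variant-association.Rmd` documents the models, the
synthetic-cohort generator and what it does and does not emulate, the
numerical choices (penalized likelihood, tail approximations, effective
test counts, carrier floors), and known limitations.
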