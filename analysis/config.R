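## Shared study configuration for the analysis stages.
##
## The cohort generator is fully deterministic given this configuration, so
## each numbered stage regenerates the cohort from here instead of passing
## a multi-hundred-megabyte genotype file between stages; the small sample,
## annotation, and truth tables are still written to results/cohort/ by
## stage 01 for inspection. 10,000 cases / 10,000 controls keeps the
## desk-scale run within minutes while sitting near the effective scale at
## which rare-variant allelic series become detectable.

library(rvassoc)

study_seed <- 20240901L

study_config <- simulation_config(
  n_cases = 10000, n_controls = 10000,
  n_subgroups = 25, n_ancestries = 5,
  n_genes = 300,
  variants_per_gene = list(mean = 15, dispersion = 5),
  gene_effect_specs = list(
    ## protective rare-variant series: aggregate carrier frequency 1.4%,
    ## per-variant OR ~ 0.4
    gene_effect_spec("G0010", "allelic_series", beta_mean = 0.92, beta_sd = 0.15,
                     carrier_freq = 0.014, direction = "protective"),
    ## risk series at aggregate MAF ~ 0.8%
    gene_effect_spec("G0020", "allelic_series", beta_mean = 0.73, beta_sd = 0.15,
                     carrier_freq = 0.008, direction = "risk"),
    ## one low-frequency driver over a null background
    gene_effect_spec("G0050", "single_driver", beta_mean = 0.77,
                     carrier_freq = 0.016, direction = "risk"),
    ## mixed-direction gene: burden dilutes, SKAT should not
    gene_effect_spec("G0040", "mixed_direction", beta_mean = 0.9,
                     carrier_freq = 0.015)),
  pool_multiplier = 20, seed = study_seed)

study_cohort <- function() simulate_cohort(study_config)

planted_genes <- c("G0010", "G0020", "G0050", "G0040")
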