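## Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

## Small mixed-architecture cohort used across modules.
small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- simulation_config(
      n_cases = 400, n_controls = 400, n_genes = 40, n_subgroups = 5,
      variants_per_gene = list(mean = 12, dispersion = 5),
      gene_effect_specs = list(
        gene_effect_spec("G0003", "allelic_series", beta_mean = 0.9,
                         carrier_freq = 0.02, direction = "protective"),
        gene_effect_spec("G0005", "single_driver", beta_mean = 1.2,
                         carrier_freq = 0.02),
        gene_effect_spec("G0007", "mixed_direction", beta_mean = 0.9,
                         carrier_freq = 0.02)),
      pool_multiplier = 15, seed = 2024L)
    simulate_cohort(cfg)
  })
}

## Simulate a raw genotype matrix (independent HWE variants).
sim_geno <- function(n, maf) {
  vapply(maf, function(q) stats::rbinom(n, 2L, q), integer(n))
}

## Case-control sample of size (n1, n0) from a logistic disease model with
## per-variant log odds ratios `beta`, prevalence K; returns y and dosages.
sim_case_control <- function(n1, n0, maf, beta, K = 0.08, pool_mult = 15) {
  n_pool <- pool_mult * (n1 + n0)
  G <- sim_geno(n_pool, maf)
  eta <- as.numeric(G %*% beta)
  alpha <- stats::uniroot(function(a) mean(1 / (1 + exp(-(a + eta)))) - K,
                          c(-30, 10))$root
  y <- stats::rbinom(n_pool, 1L, 1 / (1 + exp(-(alpha + eta))))
  idx <- c(sample(which(y == 1), n1), sample(which(y == 0), n0))
  list(y = y[idx], G = G[idx, , drop = FALSE])
}

## Minimal annotation table builder for mask tests.
make_ann <- function(variant_id, gene, consequence, maf,
                     ptv_confidence = NA, calls = 0L, transcript_set = 1L,
                     pos = seq_along(variant_id)) {
  n <- length(variant_id)
  ## `calls` is the per-variant number of damaging predictor calls (0..5)
  calls <- t(vapply(rep_len(calls, n),
                    function(k) c(rep(1L, k), rep(0L, 5L - k)), integer(5)))
  df <- data.frame(variant_id = variant_id, gene = gene, pos = pos,
                   consequence = consequence,
                   ptv_confidence = rep_len(ptv_confidence, n),
                   maf = maf, transcript_set = rep_len(transcript_set, n),
                   stringsAsFactors = FALSE)
  df[paste0("pred", 1:5)] <- as.data.frame(calls)
  df
}

expect_binomial_calibrated <- function(hits, trials, rate = 0.05, level = 0.99) {
  half <- stats::qnorm(1 - (1 - level) / 2)
  lo <- rate - half * sqrt(rate * (1 - rate) / trials)
  hi <- rate + half * sqrt(rate * (1 - rate) / trials)
  expect_gte(hits / trials, lo)
  expect_lte(hits / trials, hi)
}
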