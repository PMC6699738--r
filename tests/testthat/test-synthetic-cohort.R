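test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_cases = 0), "counts")
  expect_error(simulation_config(missing_rate = 1.5), "missing_rate")
  expect_error(simulation_config(maf_spectrum = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(gene_effect_spec("G1", "allelic_series", carrier_freq = 0.2),
               "carrier_freq")
  expect_error(gene_effect_spec("G1", "weird"), "arg")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_cases = 150, n_controls = 150, n_genes = 15,
                           n_subgroups = 3, pool_multiplier = 10, seed = 7L)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1, b2)
  ## a different seed perturbs the draws
  cfg2 <- simulation_config(n_cases = 150, n_controls = 150, n_genes = 15,
                            n_subgroups = 3, pool_multiplier = 10, seed = 8L)
  expect_false(identical(simulate_cohort(cfg2)$truth$variants$maf,
                         b1$truth$variants$maf))
})

test_that("bundle internal consistency: ids, dimensions, truth coverage", {
  b <- small_cohort()
  expect_false(any(duplicated(b$samples$sample_id)))
  expect_equal(nrow(b$samples), nrow(b$genotypes$dosage))
  expect_equal(length(b$genotypes$variant_ids), ncol(b$genotypes$dosage))
  expect_setequal(b$truth$variants$variant_id, b$genotypes$variant_ids)
  expect_true(all(b$annotations$variant_id %in% b$truth$variants$variant_id))
  expect_true(all(b$samples$status %in% 0:1))
  expect_true(all(b$samples$subgroup %in% 1:5))
})

test_that("population prevalence is calibrated to K before ascertainment", {
  b <- small_cohort()
  K <- b$meta$prevalence
  mc_se <- sqrt(K * (1 - K) / b$meta$pool_size)
  expect_lt(abs(b$meta$pool_prevalence - K), 2 * mc_se)
})

test_that("generated genotypes are Hardy-Weinberg consistent", {
  set.seed(31)
  n <- 5000
  maf <- exp(stats::runif(300, log(5e-3), log(0.3)))
  G <- sim_geno(n, maf)
  rejected <- vapply(seq_along(maf), function(j) {
    q <- mean(G[, j]) / 2
    exp_counts <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(G[, j] + 1L, 3L)
    ok <- exp_counts > 0
    stat <- sum((obs[ok] - exp_counts[ok])^2 / exp_counts[ok])
    stats::pchisq(stat, df = 1) > 0.999
  }, logical(1))
  expect_gte(mean(!rejected), 0.99)
})

test_that("empirical MAF spectrum approaches the configured bin targets", {
  ## frequency structure: 2.3% common / 4.2% low / 93.5% rare
  cfg <- simulation_config(n_cases = 50, n_controls = 50, n_genes = 2000,
                           variants_per_gene = list(mean = 26, dispersion = 10),
                           n_subgroups = 2, pool_multiplier = 5, seed = 99L)
  b <- simulate_cohort(cfg)
  expect_gte(nrow(b$truth$variants), 50000)
  frac <- maf_spectrum_summary(b)
  expect_lt(abs(frac[["common"]] - 0.023), 0.01)
  expect_lt(abs(frac[["low"]] - 0.042), 0.01)
  expect_lt(abs(frac[["rare"]] - 0.935), 0.01)
})

test_that("all-null cohort has allele-frequency differences centred on zero", {
  cfg <- simulation_config(n_cases = 500, n_controls = 500, n_genes = 120,
                           variants_per_gene = list(mean = 20, dispersion = 10),
                           maf_spectrum = c(0.2, 0.5, 0.3),
                           n_subgroups = 4, pool_multiplier = 10,
                           missing_rate = 0, seed = 5L)
  b <- simulate_cohort(cfg)
  D <- as.matrix(b$genotypes$dosage)
  y <- b$samples$status
  dif <- colMeans(D[y == 1, , drop = FALSE]) - colMeans(D[y == 0, , drop = FALSE])
  keep <- colSums(D) >= 10
  expect_gte(sum(keep), 500)
  ## mean standardized difference ~ 0
  se <- apply(D[, keep, drop = FALSE], 2, stats::sd) * sqrt(2 / 500)
  z <- dif[keep] / se
  expect_lt(abs(mean(z)), 3 / sqrt(sum(keep)) + 0.15)
})

test_that("infeasible aggregate carrier frequency names the offending gene", {
  cfg <- simulation_config(
    n_cases = 60, n_controls = 60, n_genes = 5,
    variants_per_gene = list(mean = 1, dispersion = 100),
    gene_effect_specs = list(gene_effect_spec("G0002", "allelic_series",
                                              carrier_freq = 0.05)),
    n_subgroups = 2, pool_multiplier = 10, seed = 3L)
  expect_error(simulate_cohort(cfg), "G0002")
})

test_that("missingness is injected at the configured rate", {
  cfg <- simulation_config(n_cases = 300, n_controls = 300, n_genes = 60,
                           variants_per_gene = list(mean = 15, dispersion = 10),
                           n_subgroups = 3, missing_rate = 0.02,
                           pool_multiplier = 10, seed = 13L)
  b <- simulate_cohort(cfg)
  rate <- Matrix::nnzero(b$genotypes$missing) /
    prod(dim(b$genotypes$missing))
  expect_lt(abs(rate - 0.02), 0.005)
})

test_that("replication directions are symmetric for null variants", {
  b <- memo("null_rep_cohort", function() {
    cfg <- simulation_config(n_cases = 100, n_controls = 100, n_genes = 250,
                             variants_per_gene = list(mean = 10, dispersion = 10),
                             n_subgroups = 2, pool_multiplier = 8, seed = 21L)
    simulate_cohort(cfg)
  })
  rep1 <- simulate_replication(b, 5000, 5000, seed = 4L)
  expect_gte(nrow(rep1), 2000)
  ## all true effects are zero: concordance with an arbitrary reference
  ## direction is a fair coin
  ref <- rep_len(c(1, -1), nrow(rep1))
  k <- sum(rep1$direction == ref)
  n <- nrow(rep1)
  expect_binomial_calibrated(k, n, rate = 0.5)
  expect_error(simulate_replication(b, 0, 100), "positive")
})

test_that("replication concordance approaches 1 for strong effects at large n", {
  b <- small_cohort()
  tv <- b$truth$variants
  strong <- tv$beta != 0
  skip_if(sum(strong) < 5)
  rep_big <- simulate_replication(b, 5e5, 5e5, seed = 6L)
  expect_true(all(rep_big$direction[strong] == sign(tv$beta[strong])))
})

test_that("replication concordance matches the analytic direction power", {
  ## E[concordance with the true direction] = mean Phi(|beta|/se_rep);
  ## Monte-Carlo over repeated replication draws from the generator itself
  set.seed(8)
  beta <- stats::rnorm(300, 0.4, 0.1)
  maf <- exp(stats::runif(300, log(2e-3), log(2e-2)))
  fake <- structure(list(truth = list(variants = data.frame(
    variant_id = sprintf("1:%d:A:C", 1:300), gene = "G0001",
    maf = maf, beta = beta))), class = "cohort_bundle")
  se <- rvassoc:::replication_se(maf, 4000, 4000)
  analytic <- mean(stats::pnorm(abs(beta) / se))
  mc <- mean(vapply(1:40, function(s) {
    r <- simulate_replication(fake, 4000, 4000, seed = s)
    mean(r$direction == sign(beta))
  }, numeric(1)))
  mc_se <- sqrt(analytic * (1 - analytic) / (40 * 300))
  expect_lt(abs(mc - analytic), 4 * mc_se + 0.005)
})
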