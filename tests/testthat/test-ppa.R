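## Summary-statistic generator for a two-component discovery/replication
## pair: a fraction pi_true of variants carry real effects.
sim_two_study <- function(n_var = 3000, pi_true = 0.2, beta_sd = 0.25,
                          se_disc = 0.08, se_rep = 0.1, seed = 1) {
  set.seed(seed)
  truth <- stats::rbinom(n_var, 1, pi_true)
  beta <- ifelse(truth == 1, stats::rnorm(n_var, 0, beta_sd), 0)
  bd <- stats::rnorm(n_var, beta, se_disc)
  br <- stats::rnorm(n_var, beta, se_rep)
  list(
    discovery = data.frame(variant_id = sprintf("1:%d:A:C", seq_len(n_var)),
                           beta = bd, se = se_disc,
                           p = 2 * stats::pnorm(-abs(bd / se_disc)),
                           direction = sign(bd)),
    replication = data.frame(variant_id = sprintf("1:%d:A:C", seq_len(n_var)),
                             beta = br, se = se_rep,
                             p = 2 * stats::pnorm(-abs(br / se_rep)),
                             direction = sign(br)),
    truth = truth, beta = beta)
}

test_that("concordance is a fair coin under the null and near 1 for strong signals", {
  null <- sim_two_study(2500, pi_true = 0, seed = 2)
  cf <- concordance_fraction(null$discovery, null$replication, p_threshold = 1.1)
  expect_binomial_calibrated(round(cf$C * cf$n), cf$n, rate = 0.5)
  strong <- sim_two_study(500, pi_true = 1, beta_sd = 1, se_rep = 0.05, seed = 3)
  cf2 <- concordance_fraction(strong$discovery, strong$replication,
                              p_threshold = 0.05)
  expect_gt(cf2$C, 0.95)
  expect_error(concordance_fraction(null$discovery[1:10, ], null$replication),
               "qualifying")
})

test_that("bootstrap interval for the concordance has near-nominal coverage", {
  covered <- vapply(1:120, function(i) {
    s <- sim_two_study(800, pi_true = 0.3, seed = 100 + i)
    ## population concordance for this mixture
    d_true <- mean(stats::pnorm(abs(s$beta[s$truth == 1]) / 0.1))
    C_true <- mean(s$truth) * d_true + (1 - mean(s$truth)) * 0.5
    cf <- concordance_fraction(s$discovery, s$replication, p_threshold = 1.1,
                               n_boot = 300, seed = i)
    C_true >= cf$ci[1] && C_true <= cf$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.87)
})

test_that("direction power behaves at the limits and matches Monte-Carlo", {
  expect_equal(direction_power(0, 0.1), 0.5)
  expect_gt(direction_power(10, 0.01), 1 - 1e-10)
  set.seed(4)
  beta <- abs(stats::rnorm(500, 0.3, 0.1)); se <- 0.15
  d <- direction_power(beta, se)
  mc <- mean(replicate(50, mean(sign(stats::rnorm(500, beta, se)) == 1)))
  expect_lt(abs(d - mc), 2 * sqrt(d * (1 - d) / (50 * 500)) + 0.01)
  expect_error(direction_power(0.5, -1), "positive")
})

test_that("concordance inversion hits its endpoints", {
  expect_equal(concordance_to_ppa(0.5, 0.9), 0)
  expect_equal(concordance_to_ppa(0.9, 0.9), 1)
  expect_equal(concordance_to_ppa(0.7, 0.9), 0.5)
  expect_equal(concordance_to_ppa(0.3, 0.9), 0)   # clipped
  expect_error(concordance_to_ppa(0.6, 0.5), "exceed")
})

test_that("causal scaling and odds algebra round-trip exactly", {
  expect_equal(ppa_to_causal(0.4, 1), 0.4)
  expect_equal(ppa_to_causal(0, 0.4), 0)
  grid <- c(0.25, 0.40, 0.55)
  vals <- ppa_to_causal(0.3, grid)
  expect_true(all(diff(vals) > 0))
  expect_error(ppa_to_causal(0.3, 0), "fraction_causal")
  ## BF calibration: training prior equal to the gene prior is the identity
  ppa_c <- c(0.05, 0.2, 0.6)
  bf <- calibrate_bayes_factors(ppa_c, training_prior = 0.1)
  expect_equal(apply_gene_prior(bf, 0.1), ppa_c, tolerance = 1e-12)
  ## round trip recovers the Bayes factor to machine tolerance
  post <- apply_gene_prior(bf, 0.37)
  bf_back <- (post / (1 - post)) / (0.37 / (1 - 0.37))
  expect_equal(bf_back, bf, tolerance = 1e-12)
  expect_warning(one <- apply_gene_prior(bf, 1), "forces")
  expect_equal(one, rep(1, 3))
  expect_error(calibrate_bayes_factors(ppa_c, 1), "strictly")
})

test_that("beta-uniform mixture: uniform limit, nesting, and recovery", {
  set.seed(5)
  u <- stats::runif(5000)
  fit_u <- bum_fit(u)
  expect_lte(fit_u$nonnull_proportion, 0.05)
  expect_gte(fit_u$loglik, fit_u$loglik_uniform)
  expect_error(bum_fit(c(0.5, -0.1, rep(0.5, 100))), "0, 1")
  expect_error(bum_fit(stats::runif(10)), "at least 50")
})

test_that("beta-uniform mixture recovers the non-null proportion within 0.07", {
  set.seed(6)
  lambda <- 0.77; alpha <- 0.3; n <- 5000
  err <- vapply(1:100, function(i) {
    isnull <- stats::rbinom(n, 1, lambda)
    p <- ifelse(isnull == 1, stats::runif(n), stats::runif(n)^(1 / alpha))
    fit <- bum_fit(p)
    fit$nonnull_proportion - (1 - lambda)
  }, numeric(1))
  expect_gte(mean(abs(err) <= 0.07), 0.9)
  expect_lt(abs(mean(err)), 0.03)
})

test_that("expected true counts multiply and add up", {
  expect_equal(expected_true_count(c(100, 200), c(0, 0))$expected, 0)
  one <- expected_true_count(36604, 0.0148)
  expect_equal(one$expected, 541.7, tolerance = 1e-3)
  split <- expected_true_count(c(10000, 26604), c(0.0148, 0.0148))
  expect_equal(split$expected, one$expected, tolerance = 1e-9)
  both <- expected_true_count(c(100, 50), c(0.1, 0.2), c(0.05, 0.1), c(0.2, 0.3))
  expect_equal(both$lo, 10)
  expect_equal(both$hi, 35)
})

test_that("calibration table strata behave monotonically on a fixed dataset", {
  s <- sim_two_study(4000, pi_true = 0.25, seed = 7)
  cal <- ppa_calibration(s$discovery, s$replication, n_boot = 200, seed = 8)
  tab <- cal$table
  expect_equal(nrow(tab), 5)
  ## PPA non-increasing as the threshold loosens
  expect_true(all(diff(tab$ppa) <= 1e-9))
  expect_true(all(tab$ppa >= 0 & tab$ppa <= 1))
  expect_true(all(tab$ppa_c_0.25 <= tab$ppa + 1e-12))
  expect_true(all(tab$C >= 0 & tab$C <= 1))
})

test_that("the pipeline recovers the per-stratum proportion of true associations", {
  ## end-to-end: a 20% true mixture; within the P < 0.05 stratum the
  ## realized fraction of true variants (the quantity the concordance
  ## inversion estimates) must be covered by the bootstrap 95% CI
  covered <- vapply(1:60, function(i) {
    s <- sim_two_study(2500, pi_true = 0.2, beta_sd = 0.3, seed = 300 + i)
    cal <- ppa_calibration(s$discovery, s$replication, thresholds = 0.05,
                           n_boot = 300, seed = i, shrinkage = 0.8)
    sel <- s$discovery$p < 0.05
    pi_real <- mean(s$truth[sel] == 1)
    row <- cal$table[1, ]
    pi_real >= row$ppa_lo - 1e-9 && pi_real <= row$ppa_hi + 1e-9
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
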