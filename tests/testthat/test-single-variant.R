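test_that("Firth regression stays finite under complete separation", {
  y <- c(rep(1, 60), rep(0, 60))
  g <- c(rep(1, 6), rep(0, 114))  # carriers only among cases
  r <- firth_logistic(y, g)
  expect_true(is.finite(r$effect))
  expect_true(is.finite(r$se))
  expect_gt(r$effect, 0)
  expect_gt(r$p, 0)
  expect_lte(r$p, 1)
  expect_true(r$converged)
})

test_that("Firth agrees with maximum likelihood on a common variant", {
  set.seed(10)
  n <- 4000
  g <- stats::rbinom(n, 2, 0.3)
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, 1 / (1 + exp(-(0.2 * g - 0.1 * x))))
  r <- firth_logistic(y, g, cbind(x))
  ml <- stats::glm(y ~ x + g, family = stats::binomial())
  expect_lt(abs(r$effect - stats::coef(ml)[["g"]]),
            3 * summary(ml)$coefficients["g", 2])
  ## and much closer than that in practice
  expect_lt(abs(r$effect - stats::coef(ml)[["g"]]), 0.02)
})

test_that("phenotype and dosage degeneracies are rejected", {
  expect_error(firth_logistic(rep(1, 10), stats::rbinom(10, 2, 0.3)),
               "degenerate phenotype")
  expect_error(firth_logistic(rep(0:1, 5), rep(1, 10)), "monomorphic")
  expect_error(score_test(rep(0:1, 5), rep(0, 10)), "monomorphic")
})

test_that("score test on a 2x2 allele table matches the hand-computed chi-square", {
  ## 40 cases (12 carriers), 60 controls (8 carriers), dosage 0/1
  y <- c(rep(1, 40), rep(0, 60))
  g <- c(rep(1, 12), rep(0, 28), rep(1, 8), rep(0, 52))
  ## hand computation: U = sum g(y - ybar); V = ybar(1-ybar) * sum(g - gbar)^2
  ybar <- 0.4; gbar <- 0.2
  U <- sum(g * (y - ybar))
  V <- ybar * (1 - ybar) * sum((g - gbar)^2)
  p_hand <- stats::pchisq(U^2 / V, 1, lower.tail = FALSE)
  r <- score_test(y, g)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
})

test_that("dosage orthogonal to the residual gives statistic 0, P = 1", {
  y <- rep(c(0, 1), each = 20)
  g <- rep(c(0, 1, 2, 1, 0), 8)   # same mean dosage in cases and controls
  r <- score_test(y, g)
  expect_equal(unname(r$p), 1, tolerance = 1e-12)
})

test_that("score and Firth P values agree within 2x for moderate signals", {
  set.seed(12)
  n <- 2500
  bad <- 0
  for (i in 1:30) {
    g <- stats::rbinom(n, 2, stats::runif(1, 0.05, 0.4))
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-(stats::rnorm(1, 0, 0.1) * g))))
    rs <- score_test(y, g)
    z <- abs(rs$effect / rs$se)
    if (z < 4) {
      rf <- firth_logistic(y, g)
      ratio <- rf$p / rs$p
      if (ratio > 2 || ratio < 0.5) bad <- bad + 1
    }
  }
  expect_equal(bad, 0)
})

test_that("direction signs agree between firth and score for clear signals", {
  set.seed(13)
  n <- 2000
  agree <- vapply(1:50, function(i) {
    g <- stats::rbinom(n, 2, 0.1)
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-0.25 * (g - 0.2))))
    rs <- score_test(y, g)
    if (abs(rs$effect / rs$se) <= 1) return(NA)
    rf <- firth_logistic(y, g)
    rf$direction == rs$direction
  }, logical(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
})

test_that("mixed-model score test reduces exactly to the score test under identity kinship", {
  set.seed(14)
  n <- 300
  g <- stats::rbinom(n, 2, 0.2)
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, 0.4)
  for (s in c(1, 2.5)) {
    rm_ <- mixed_score_test(y, g, cbind(x), kinship = diag(s, n))
    rs <- score_test(y, g, cbind(x), family = "gaussian")
    expect_equal(rm_$p, rs$p, tolerance = 1e-10)
    expect_equal(rm_$effect, rs$effect, tolerance = 1e-8)
  }
  ## without covariates the gaussian and binomial score tests coincide
  expect_equal(score_test(y, g)$p, score_test(y, g, family = "gaussian")$p,
               tolerance = 1e-12)
})

test_that("non-PSD or asymmetric kinship is rejected", {
  n <- 50
  y <- rep(0:1, 25); g <- stats::rbinom(n, 2, 0.3)
  K <- diag(n); K[1, 2] <- 0.5           # asymmetric
  expect_error(mixed_score_test(y, g, kinship = K), "symmetric")
  K2 <- matrix(0.9, n, n); diag(K2) <- 0.5  # negative eigenvalues
  expect_error(mixed_score_test(y, g, kinship = K2), "semidefinite")
})

test_that("mixed model stays calibrated under family structure while naive score inflates", {
  set.seed(15)
  n_fam <- 150; fam_size <- 4; n <- n_fam * fam_size
  fam <- rep(seq_len(n_fam), each = fam_size)
  K <- matrix(0, n, n)
  for (f in seq_len(n_fam)) K[fam == f, fam == f] <- 0.5
  diag(K) <- 1
  n_var <- 120
  p_naive <- p_mixed <- numeric(n_var)
  ## polygenic family effect on the liability; variants are null
  for (i in seq_len(n_var)) {
    u <- rep(stats::rnorm(n_fam, 0, 1), each = fam_size)
    y <- as.integer(stats::rnorm(n, u, 1) > 0)
    if (length(unique(y)) < 2) { p_naive[i] <- p_mixed[i] <- NA; next }
    g <- rep(stats::rbinom(n_fam * 2, 1, 0.3), each = 2)[seq_len(n)] +
      rep(stats::rbinom(n_fam * 2, 1, 0.3), each = 2)[seq_len(n)]
    if (stats::var(g) == 0) { p_naive[i] <- p_mixed[i] <- NA; next }
    p_naive[i] <- score_test(y, g, family = "gaussian")$p
    p_mixed[i] <- mixed_score_test(y, g, kinship = K)$p
  }
  lambda_gc <- function(p) stats::median(stats::qchisq(p, 1, lower.tail = FALSE),
                                         na.rm = TRUE) / stats::qchisq(0.5, 1)
  expect_gt(lambda_gc(p_naive), lambda_gc(p_mixed))
  ## mixed-model type-I error at 0.05 within the 99% binomial interval
  ok <- !is.na(p_mixed)
  hits <- sum(p_mixed[ok] < 0.05)
  exp_hi <- 0.05 + stats::qnorm(0.995) * sqrt(0.05 * 0.95 / sum(ok))
  expect_lte(hits / sum(ok), exp_hi + 0.02)
})

test_that("inverse-variance meta-analysis identities and random oracle", {
  one <- meta_fixed_ivw(0.4, 0.1)
  expect_equal(one$effect, 0.4)
  expect_equal(one$se, 0.1)
  two <- meta_fixed_ivw(c(0.3, 0.3), c(0.12, 0.12))
  expect_equal(two$effect, 0.3)
  expect_equal(two$se, 0.12 / sqrt(2), tolerance = 1e-12)
  set.seed(16)
  beta <- stats::rnorm(25); se <- stats::runif(25, 0.05, 0.5)
  m <- meta_fixed_ivw(beta, se)
  w <- 1 / se^2
  expect_equal(m$effect, sum(w * beta) / sum(w), tolerance = 1e-12)
  expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(sum(m$weights), 1)
  expect_lte(m$se, min(se))
  expect_error(meta_fixed_ivw(numeric(0), numeric(0)), "no estimable")
})

test_that("meta-analysis of K identical studies shrinks the se by sqrt(K)", {
  for (K in c(2, 5, 10)) {
    m <- meta_fixed_ivw(rep(0.2, K), rep(0.3, K))
    expect_equal(m$se, 0.3 / sqrt(K), tolerance = 1e-12)
  }
})

test_that("sample-size weighted meta-analysis formula and cancellation", {
  expect_equal(meta_sample_weighted(1.7, 500, 1)$z, 1.7)
  opp <- meta_sample_weighted(c(2, 2), c(300, 300), c(1, -1))
  expect_equal(opp$z, 0)
  expect_equal(opp$p, 1)
  set.seed(17)
  for (i in 1:20) {
    z <- stats::runif(3, 0, 3); n <- stats::runif(3, 50, 5000)
    d <- sample(c(-1, 1), 3, replace = TRUE)
    got <- meta_sample_weighted(z, n, d)
    expect_equal(got$z, sum(sqrt(n) * z * d) / sqrt(sum(n)), tolerance = 1e-12)
  }
  expect_error(meta_sample_weighted(c(1, 2), c(10, -1), c(1, 1)), "positive")
  expect_error(meta_sample_weighted(c(1, 2), c(10), c(1, 1)), "equal length")
})

test_that("stratified scan matches the pooled mega analysis broadly", {
  b <- small_cohort()
  meta <- sv_scan(b)
  mega <- sv_scan(b, mode = "mega")
  ok <- is.finite(meta$z) & is.finite(mega$z) & meta$n_studies >= 3
  skip_if(sum(ok) < 50)
  expect_gt(stats::cor(meta$z[ok], mega$z[ok]), 0.8)
})
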