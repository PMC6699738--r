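test_that("single-variant mask reduces the burden test to Firth logistic", {
  set.seed(20)
  res <- sim_case_control(400, 400, maf = 0.02, beta = 0.5, pool_mult = 10)
  b <- burden_test(res$y, res$G, firth = "always")
  f <- firth_logistic(res$y, as.numeric(res$G))
  expect_equal(b$effect, f$effect, tolerance = 1e-8)
  expect_equal(b$p, f$p, tolerance = 1e-8)
})

test_that("burden degenerate inputs are handled per contract", {
  y <- rep(0:1, 50)
  G <- matrix(stats::rbinom(200, 1, 0.05), 100, 2)
  expect_error(burden_test(y, G, weights = c(0, 0)), "degenerate score")
  r <- burden_test(y, matrix(0L, 100, 2))
  expect_true(is.na(r$p))
  expect_true(isTRUE(r$no_carriers))
})

test_that("burden recovers a protective allelic series odds ratio", {
  ## one replicate of the series architecture; the full coverage study is
  ## part of the calibration suite
  set.seed(21)
  m <- 40
  maf <- rep(0.014 / (2 * m), m)      # aggregate carrier frequency ~1.4%
  res <- sim_case_control(1500, 1500, maf, rep(log(0.4), m))
  r <- burden_test(res$y, res$G)
  expect_lt(r$effect, 0)
  expect_gt(r$effect + 2.3 * r$se, log(0.4) - 0.6)
})

test_that("SKAT on one variant equals the score test", {
  set.seed(22)
  n <- 2000
  g <- matrix(stats::rbinom(n, 2, 0.01), ncol = 1)
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, 0.5)
  s <- skat_test(y, g, cbind(x), method = "imhof")
  sc <- score_test(y, as.numeric(g), cbind(x))
  expect_equal(s$p, sc$p, tolerance = 5e-4)
  s2 <- skat_test(y, g, cbind(x), method = "liu")
  expect_equal(signif(s2$p, 3), signif(sc$p, 3), tolerance = 1e-2)
})

test_that("SKAT beats burden on mixed-direction genes", {
  set.seed(23)
  reps <- 60
  pb <- ps <- numeric(reps)
  for (i in seq_len(reps)) {
    m <- 10
    maf <- rep(0.004, m)
    beta <- rep(c(0.9, -0.9), m / 2)
    res <- sim_case_control(500, 500, maf, beta, pool_mult = 8)
    pb[i] <- burden_test(res$y, res$G)$p
    ps[i] <- skat_test(res$y, res$G)$p
  }
  expect_lt(stats::median(ps), stats::median(pb))
})

test_that("Imhof and Liu tails agree for moderate mixtures", {
  lambda <- c(3, 2, 1, 0.5)
  for (q in c(2, 6, 12, 20)) {
    expect_equal(rvassoc:::liu_pvalue(q, lambda),
                 rvassoc:::imhof_pvalue(q, lambda), tolerance = 0.02)
  }
  ## single chi-square: both are exact
  expect_equal(rvassoc:::imhof_pvalue(3.84, 1),
               stats::pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("inactivation weights follow the documented scheme", {
  ann <- make_ann(
    c("1:1:A:T", "1:2:A:T", "1:3:A:T", "1:4:A:T"), "G1",
    c("protein_truncating", "missense", "missense", "protein_truncating"),
    maf = rep(0.001, 4), ptv_confidence = c("high", NA, NA, "low"),
    calls = c(0L, 5L, 0L, 0L))
  w <- inactivation_weights(ann)
  expect_equal(unname(w), c(1, 0.5, 0, 0.5))
  syn <- make_ann("1:9:A:T", "G1", "synonymous", 0.001)
  expect_error(inactivation_weights(syn), "nonsynonymous")
})

test_that("effective mask count hits the correlation limits", {
  set.seed(24)
  base <- stats::rbinom(4000, 3, 0.1)
  identical_masks <- cbind(base, base, base, base)
  expect_equal(effective_mask_count(identical_masks), 1)
  indep <- matrix(stats::rbinom(4000 * 5, 3, 0.1), 4000, 5)
  expect_lt(abs(effective_mask_count(indep) - 5), 0.1)
  expect_equal(effective_mask_count(cbind(base)), 1)
  expect_error(effective_mask_count(matrix(0, 10, 2)), "constant")
})

test_that("eigenvalue m_eff tracks the permutation min-P oracle on nested masks", {
  set.seed(25)
  for (rep in 1:6) {
    n <- 1500
    G <- sim_geno(n, exp(stats::runif(12, log(1e-3), log(1e-2))))
    sets <- list(1:2, 1:4, 1:8, 1:12)   # nested masks
    S <- vapply(sets, function(s) rowSums(G[, s, drop = FALSE]), numeric(n))
    m_eig <- effective_mask_count(S)
    m_perm <- permutation_meff(S, n_perm = 4000L, seed = rep)
    expect_lt(abs(m_eig - m_perm) / m_perm, 0.15)
  }
})

test_that("minimum-P consolidation evaluates the Sidak form", {
  expect_equal(min_p_consolidate(0.01, 1), 0.01, tolerance = 1e-12)
  expect_equal(min_p_consolidate(c(0.5, 0), 2.7), 0)
  expect_equal(min_p_consolidate(0.01, 3.6), 1 - 0.99^3.6, tolerance = 1e-12)
  expect_equal(round(min_p_consolidate(0.01, 3.6), 5), 0.03553)
  expect_equal(min_p_consolidate(c(0.9, 0.95), 5), 1 - (1 - 0.9)^5)
  expect_error(min_p_consolidate(NA_real_, 2), "no finite")
})

test_that("weighted test equals unweighted burden when all weights are 1", {
  set.seed(26)
  m <- 6
  res <- sim_case_control(400, 400, rep(0.005, m), rep(0, m), pool_mult = 8)
  ann <- make_ann(sprintf("1:%d:A:T", 1:m), "G1",
                  rep("protein_truncating", m), rep(0.005, m),
                  ptv_confidence = "high")
  colnames(res$G) <- ann$variant_id
  wt <- weighted_gene_test(res$y, res$G, ann)
  plain <- burden_test(res$y, res$G)
  expect_equal(wt$burden$p, plain$p, tolerance = 1e-10)
  expect_equal(wt$burden$effect, plain$effect, tolerance = 1e-10)
  expect_equal(unname(wt$weights), rep(1, m))
})

test_that("halving all weights doubles the burden effect, P unchanged", {
  set.seed(27)
  m <- 8
  res <- sim_case_control(500, 500, rep(0.01, m), rep(0.3, m), pool_mult = 8)
  full <- burden_test(res$y, res$G, weights = rep(1, m), firth = "never")
  half <- burden_test(res$y, res$G, weights = rep(0.5, m), firth = "never")
  expect_equal(half$effect, 2 * full$effect, tolerance = 1e-6)
  expect_equal(half$p, full$p, tolerance = 1e-9)
})

test_that("consolidated P never undercuts the smallest per-mask P", {
  set.seed(28)
  for (i in 1:200) {
    K <- sample(2:7, 1)
    ps <- stats::runif(K)^2
    meff <- stats::runif(1, 1, K)
    expect_gte(min_p_consolidate(ps, meff), min(ps))
  }
})

test_that("consolidation is invariant to mask order and duplicated transcript sets", {
  set.seed(29)
  n <- 800
  G <- sim_geno(n, rep(0.01, 6))
  y <- stats::rbinom(n, 1, 0.5)
  null <- rvassoc:::gene_null_model(y, NULL)
  mk <- function(cols, ts, mask) {
    sc <- rowSums(G[, cols, drop = FALSE])
    b <- rvassoc:::burden_with_null(null, sc)
    s <- rvassoc:::skat_with_null(G[, cols, drop = FALSE], rep(1, length(cols)),
                                  null$skat)
    list(row = data.frame(transcript_set = ts, mask = mask, burden_p = b$p,
                          burden_effect = b$effect, burden_se = b$se,
                          skat_p = s$p, n_variants = length(cols),
                          carrier_freq = b$carrier_freq),
         score = sc)
  }
  a <- mk(1:4, 1L, "m1"); b2 <- mk(1:6, 1L, "m2")
  res1 <- consolidate_gene(rbind(a$row, b2$row), cbind(a$score, b2$score))
  res2 <- consolidate_gene(rbind(b2$row, a$row), cbind(b2$score, a$score))
  expect_equal(res1$p_burden_minp, res2$p_burden_minp, tolerance = 1e-12)
  expect_equal(res1$p_skat_minp, res2$p_skat_minp, tolerance = 1e-12)
  ## a single mask and transcript set passes through with m_eff 1
  solo <- consolidate_gene(a$row, cbind(a$score))
  expect_equal(solo$p_burden_minp, a$row$burden_p, tolerance = 1e-12)
  expect_equal(solo$m_eff, 1)
})

test_that("progressive removal matches from-scratch burden runs and ends in NA", {
  set.seed(30)
  m <- 5
  res <- sim_case_control(300, 300, rep(0.01, m), rep(0.5, m), pool_mult = 8)
  colnames(res$G) <- sprintf("v%d", 1:m)
  curve <- progressive_removal(res$y, res$G, order = c(3, 1, 5, 2, 4))
  expect_equal(nrow(curve), m + 1L)
  expect_true(is.na(curve$p[m + 1L]))
  for (k in c(1L, 3L)) {
    keep <- setdiff(1:m, c(3, 1, 5, 2, 4)[seq_len(k)])
    ref <- burden_test(res$y, res$G[, keep, drop = FALSE])
    expect_equal(curve$p[k + 1L], ref$p, tolerance = 1e-10)
    expect_equal(curve$effect[k + 1L], ref$effect, tolerance = 1e-10)
  }
})

test_that("an allelic series survives removal of its strongest variants", {
  ## the uniform-effect protective series keeps a nominally significant
  ## burden signal after dropping its 10 individually strongest alleles --
  ## a property of the aggregate signal at the sample size where such
  ## series are actually found (~43,000 individuals), not of any single
  ## driver variant
  set.seed(301)
  hits <- 0
  reps <- 15
  for (i in seq_len(reps)) {
    m <- 40
    res <- sim_case_control(21500, 21500, rep(0.014 / (2 * m), m),
                            rep(log(0.4), m), pool_mult = 8)
    sv <- rvassoc:::score_scan_block(res$y, res$G, covs = NULL)
    sv_p <- ifelse(is.finite(sv$p), sv$p, 1)
    keep <- order(sv_p)[-(1:10)]   # drop the 10 strongest
    r <- burden_test(res$y, res$G[, keep, drop = FALSE])
    if (is.finite(r$p) && r$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("conditioning on the driver of a single-driver gene removes the signal", {
  set.seed(31)
  ps <- numeric(25)
  for (i in seq_along(ps)) {
    m <- 8
    maf <- c(0.01, rep(0.001, m - 1))
    beta <- c(0.9, rep(0, m - 1))      # variant 1 drives everything
    res <- sim_case_control(1000, 1000, maf, beta, pool_mult = 8)
    colnames(res$G) <- sprintf("v%d", 1:m)
    ps[i] <- conditional_on_allele(res$y, res$G, variant = "v1")$p
  }
  expect_gt(stats::median(ps, na.rm = TRUE), 0.05)
})

test_that("conditioning on an uncorrelated outside variant leaves P unchanged", {
  set.seed(32)
  m <- 6
  res <- sim_case_control(800, 800, rep(0.01, m), rep(0.4, m), pool_mult = 8)
  outside <- stats::rbinom(1600, 2, 0.05)
  plain <- burden_test(res$y, res$G)
  cond <- conditional_on_allele(res$y, res$G, variant = NA, in_mask = FALSE,
                                conditioning_dosage = outside)
  expect_lt(abs(log(cond$p) - log(plain$p)), 1)
  expect_error(conditional_on_allele(res$y, res$G[, 1, drop = FALSE],
                                     variant = 1), "degenerate")
  expect_error(conditional_on_allele(res$y, res$G, variant = "nope"), "absent")
})
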