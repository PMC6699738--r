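#' Liability variance explained by a biallelic variant
#'
#' Liability-threshold computation for a variant with genotypes AA, Aa, aa
#' at Hardy-Weinberg frequencies and relative risks (1, RR1, RR2): the
#' baseline risk is solved so the genotype-frequency-weighted risk equals
#' the population prevalence K; each genotype's disease risk is mapped to a
#' mean liability shift through the inverse standard-normal transform at
#' the threshold `qnorm(1 - K)`; the LVE is the variance of the genotype
#' liability means over the total liability variance (between-genotype
#' plus unit within-genotype).
#'
#' @param freq Risk-allele (or aggregate carrier-equivalent) frequency in
#'   (0, 0.5].
#' @param rr1,rr2 Relative risks of the heterozygote and rare homozygote
#'   versus the common homozygote; both > 0.
#' @param K Population prevalence in (0, 1).
#' @return LVE fraction in `[0, 1)`.
#' @export
lve_variant <- function(freq, rr1, rr2 = rr1^2, K = 0.08) {
  stopifnot(freq > 0, freq <= 0.5, rr1 > 0, rr2 > 0, K > 0, K < 1)
  p <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  rr <- c(1, rr1, rr2)
  f0 <- K / sum(p * rr)
  risk <- f0 * rr
  if (any(risk >= 1)) stop("genotype risk >= 1 under this RR model", call. = FALSE)
  thr <- stats::qnorm(1 - K)
  mu <- thr - stats::qnorm(1 - risk)    # mean liability shift per genotype
  mbar <- sum(p * mu)
  vg <- sum(p * (mu - mbar)^2)
  vg / (vg + 1)
}

#' Monte-Carlo liability-scale oracle for [lve_variant()]
#'
#' Simulates individuals on the liability scale (genotype at
#' Hardy-Weinberg frequencies, liability normal around the genotype mean)
#' and regresses liability on genotype class, returning the empirical
#' variance explained. Genotype counts are allocated proportionally
#' (stratified sampling) and the normal residuals are drawn in antithetic
#' pairs, which removes the dominant sources of Monte-Carlo noise; the
#' reported `se` is the simple-sampling delta-method bound for `n` draws
#' and is therefore conservative for this estimator.
#'
#' @inheritParams lve_variant
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @return List: `lve`, `se` (conservative Monte-Carlo s.e.).
#' @export
lve_variant_mc <- function(freq, rr1, rr2 = rr1^2, K = 0.08, n = 1e6, seed = 1L) {
  p <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  rr <- c(1, rr1, rr2)
  f0 <- K / sum(p * rr)
  thr <- stats::qnorm(1 - K)
  mu <- thr - stats::qnorm(1 - f0 * rr)
  ## proportional allocation, at least one pair per genotype class
  n_g <- pmax(2L, 2L * round(n * p / 2))
  with_substream(seed, "lve_mc", {
    g <- rep.int(1:3, n_g)
    e <- stats::rnorm(sum(n_g) / 2)
    resid <- as.numeric(rbind(e, -e))   # antithetic pairs
    liab <- mu[g] + resid
    fit <- stats::lm(liab ~ factor(g))
    r2 <- summary(fit)$r.squared
    list(lve = r2, se = sqrt(max(4 * r2 * (1 - r2)^2, 1e-12) / n))
  })
}

#' Convert an odds ratio to a relative risk at prevalence K
#'
#' `RR = OR / (1 - K + K * OR)`; with `method = "identity"` the odds ratio
#' is used as the relative risk directly (rare-outcome approximation).
#'
#' @param or Odds ratio.
#' @param K Population prevalence.
#' @param method `"standard"` (default) or `"identity"`.
#' @return Relative risk.
#' @export
or_to_rr <- function(or, K = 0.08, method = c("standard", "identity")) {
  method <- match.arg(method)
  if (method == "identity") return(or)
  or / (1 - K + K * or)
}

#' Liability variance explained by a gene-level signal
#'
#' Treats the gene's qualifying alleles as a single biallelic
#' pseudo-variant at the aggregate carrier-allele frequency with
#' multiplicative genotype risks, converts the gene-level odds ratio to a
#' relative risk at prevalence K, and delegates to [lve_variant()].
#'
#' @param aggregate_freq Aggregate allele frequency of the qualifying
#'   variants.
#' @param or Gene-level odds ratio.
#' @param K Population prevalence.
#' @param or_method Passed to [or_to_rr()].
#' @return LVE fraction.
#' @export
lve_gene <- function(aggregate_freq, or, K = 0.08, or_method = "standard") {
  rr <- or_to_rr(or, K, or_method)
  lve_variant(aggregate_freq, rr, rr^2, K)
}

#' Fit the exponential rank model of liability variance explained
#'
#' Fits `LVE_n = exp(a * n + b)` -- the LVE of the gene with the n-th
#' smallest gene-level P value -- by ordinary least squares of `log(LVE_n)`
#' on rank n over the fit range.
#'
#' @param lve LVE values ordered by rank (rank 1 = strongest signal).
#' @param ranks Ranks of the supplied values (default `seq_along(lve)`).
#' @param fit_range Ranks to use in the fit (default all supplied).
#' @return Object of class `"lve_rank_model"`: `a`, `b`, `fit_range`,
#'   `fitted` per-rank predictions.
#' @export
fit_lve_rank_model <- function(lve, ranks = seq_along(lve), fit_range = ranks) {
  use <- ranks %in% fit_range
  if (sum(use) < 3L) stop("need at least 3 LVE values to fit", call. = FALSE)
  if (any(lve[use] <= 0)) stop("non-positive LVE in fit range", call. = FALSE)
  fit <- stats::lm(log(lve[use]) ~ ranks[use])
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  structure(list(a = a, b = b, fit_range = range(fit_range),
                 fitted = exp(a * ranks + b)),
            class = "lve_rank_model")
}

#' Total LVE of the top N signals under the exponential rank model
#'
#' Sums the actually observed LVEs (ranks 1..m, contiguous from 1) with the
#' model prediction `exp(a n + b)` for ranks m+1..N; the tail is evaluated
#' by the geometric-series closed form, which equals term-by-term summation
#' exactly.
#'
#' @param model An [fit_lve_rank_model()] object or a list with `a`, `b`.
#' @param observed LVEs observed at ranks `1..length(observed)`.
#' @param N Extrapolation horizon (> number observed).
#' @param method `"closed_form"` (default) or `"termwise"`.
#' @return Total LVE fraction.
#' @export
extrapolate_top_n <- function(model, observed, N,
                              method = c("closed_form", "termwise")) {
  method <- match.arg(method)
  m <- length(observed)
  if (N <= m) {
    if (N == m) return(sum(observed))
    stop("N must be at least the number of observed ranks", call. = FALSE)
  }
  a <- model$a; b <- model$b
  tail_sum <- if (method == "termwise") {
    sum(exp(a * ((m + 1):N) + b))
  } else {
    ## geometric series: sum_{n=m+1}^{N} e^{an+b}
    if (a == 0) exp(b) * (N - m) else
      exp(b) * exp(a * (m + 1)) * (1 - exp(a * (N - m))) / (1 - exp(a))
  }
  sum(observed) + tail_sum
}

#' Expected case/control allele frequencies under a disease model
#'
#' @param freq Population risk-allele frequency.
#' @param or Allelic odds ratio.
#' @param K Population prevalence.
#' @return List with `q_case`, `q_control`.
#' @export
case_control_freqs <- function(freq, or, K = 0.08) {
  rr <- or_to_rr(or, K)
  p <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  risk <- K / sum(p * c(1, rr, rr^2)) * c(1, rr, rr^2)
  if (any(risk >= 1)) stop("degenerate frequencies: genotype risk >= 1", call. = FALSE)
  p_case <- p * risk / K
  p_ctrl <- p * (1 - risk) / (1 - K)
  list(q_case = p_case[2] / 2 + p_case[3], q_control = p_ctrl[2] / 2 + p_ctrl[3])
}

#' Power of a case-control single- or aggregate-variant test
#'
#' Expected case and control allele frequencies are derived from the
#' population frequency, odds ratio, and prevalence K; power comes from
#' the normal approximation to the two-proportion (allele-count) test at
#' two-sided significance level alpha.
#'
#' @param n_cases,n_controls Sample sizes.
#' @param freq Population risk-allele (or aggregate) frequency.
#' @param or Odds ratio (gene-level aggregate or single-variant).
#' @param alpha Two-sided significance level.
#' @param K Population prevalence.
#' @return Power in `[0, 1]`.
#' @export
power_case_control <- function(n_cases, n_controls, freq, or,
                               alpha = 1.25e-7, K = 0.08) {
  stopifnot(n_cases > 0, n_controls > 0, alpha > 0, alpha < 1, or > 0)
  qq <- case_control_freqs(freq, or, K)
  delta <- qq$q_case - qq$q_control
  se <- sqrt(qq$q_case * (1 - qq$q_case) / (2 * n_cases) +
               qq$q_control * (1 - qq$q_control) / (2 * n_controls))
  z_crit <- stats::qnorm(1 - alpha / 2)
  z <- abs(delta) / se
  stats::pnorm(z - z_crit) + stats::pnorm(-z - z_crit)
}

#' Effective sample size of an unbalanced case-control study
#'
#' `n_eff = 4 / (1/n_cases + 1/n_controls)`: the size of the balanced study
#' with equivalent statistical power.
#'
#' @param n_cases,n_controls Counts, positive.
#' @return Effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  stopifnot(n_cases > 0, n_controls > 0)
  4 / (1 / n_cases + 1 / n_controls)
}

#' Population-study equivalent of a balanced case-control sample
#'
#' Converts an effective (balanced-equivalent) sample size to the size of
#' an unascertained population study with the same information about a
#' binary trait of prevalence K, using the binomial-information convention
#' `N = n_eff * 0.25 / (K * (1 - K))` (a balanced study has case fraction
#' 1/2, hence information factor 1/4 per individual).
#'
#' @param n_eff Effective sample size.
#' @param K Population prevalence.
#' @return Population study size N.
#' @export
population_equivalent <- function(n_eff, K = 0.08) {
  stopifnot(K > 0, K < 1)
  n_eff * 0.25 / (K * (1 - K))
}

#' Bonferroni exome-wide gene-level significance threshold
#'
#' `alpha_family / (n_tests * n_methods * n_genes)`; with the defaults
#' (two tests, two consolidation methods, 19,020 genes) this is the
#' conservative exome-wide gene-level threshold 6.57e-7.
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param n_tests Number of gene-level tests (burden, SKAT).
#' @param n_methods Number of consolidation methods (minimum-P, weighted).
#' @param n_genes Number of genes tested.
#' @return Per-gene threshold.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_tests = 2L,
                                 n_methods = 2L, n_genes = 19020L) {
  stopifnot(alpha_family > 0, n_tests > 0, n_methods > 0, n_genes > 0)
  alpha_family / (n_tests * n_methods * n_genes)
}

#' Minimum case count achieving a target power
#'
#' Smallest case count whose [power_case_control()] meets the target, by
#' bisection; controls scale with the case:control ratio.
#'
#' @param target Target power in (alpha, 1).
#' @param freq,or,alpha,K As in [power_case_control()].
#' @param control_ratio Controls per case (default 1, a balanced study).
#' @param max_cases Upper search bound.
#' @return Minimum integer case count.
#' @export
required_cases_for_power <- function(target, freq, or, alpha = 1.25e-7,
                                     K = 0.08, control_ratio = 1,
                                     max_cases = 1e8) {
  stopifnot(target > alpha, target < 1)
  pw <- function(n) power_case_control(n, n * control_ratio, freq, or, alpha, K)
  if (pw(max_cases) < target) stop("target power unreachable", call. = FALSE)
  lo <- 1; hi <- max_cases
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pw(mid) >= target) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
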