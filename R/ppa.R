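#' Direction-of-effect concordance fraction with bootstrap CI
#'
#' Among variants passing the filter and the discovery P-value threshold,
#' the fraction whose replication direction of effect agrees with the
#' discovery direction, with a seeded nonparametric bootstrap interval
#' over variants.
#'
#' @param discovery Data frame with `variant_id`, `p`, `direction` (and
#'   any filter columns).
#' @param replication Data frame with `variant_id`, `direction`.
#' @param p_threshold Discovery P-value ceiling (inclusive stratum
#'   `p < p_threshold`).
#' @param p_floor Optional lower bound (`p >= p_floor`) for banded strata.
#' @param filter Optional logical vector over discovery rows.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param min_variants Refuse with fewer qualifying variants than this.
#' @return List: `C`, `ci` (2.5/97.5% bootstrap percentiles), `n`.
#' @export
concordance_fraction <- function(discovery, replication, p_threshold = 0.05,
                                 p_floor = 0, filter = NULL, n_boot = 1000L,
                                 seed = 1L, min_variants = 20L) {
  keep <- discovery$p < p_threshold & discovery$p >= p_floor
  if (!is.null(filter)) keep <- keep & filter
  d <- discovery[keep & is.finite(discovery$p), , drop = FALSE]
  m <- match(d$variant_id, replication$variant_id)
  ok <- !is.na(m) & d$direction != 0
  d <- d[ok, , drop = FALSE]; m <- m[ok]
  n <- nrow(d)
  if (n < min_variants) {
    stop(sprintf("only %d qualifying variants (need >= %d)", n, min_variants),
         call. = FALSE)
  }
  conc <- d$direction == replication$direction[m]
  C <- mean(conc)
  ci <- with_substream(seed, "concordance_boot", {
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(conc[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  list(C = C, ci = ci, n = n)
}

#' Expected direction power of a replication study
#'
#' Probability that the replication estimate of a truly associated variant
#' has the same sign as its true effect: `d = E[ Phi(|beta| / se_rep) ]`
#' averaged over the supplied effect-size distribution.
#'
#' @param beta True (or shrunken discovery) effect magnitudes.
#' @param se_rep Replication standard errors (recycled).
#' @return `d` in (0.5, 1] (0.5 exactly only for all-zero effects).
#' @export
direction_power <- function(beta, se_rep) {
  if (any(se_rep <= 0)) stop("standard errors must be positive", call. = FALSE)
  mean(stats::pnorm(abs(beta) / se_rep))
}

#' Invert a concordance fraction to a proportion of true associations
#'
#' Under a two-component model, the observed concordance is
#' `C = pi * d + (1 - pi) / 2`: truly associated variants replicate in
#' direction with power d, null ones by coin flip. Hence
#' `pi = (C - 1/2) / (d - 1/2)`, clipped to `[0, 1]` -- the posterior
#' probability of (true) association for a variant in the stratum.
#'
#' @param C Concordance fraction.
#' @param d Direction power, > 0.5.
#' @return Estimated proportion of true associations `pi`.
#' @export
concordance_to_ppa <- function(C, d) {
  if (d <= 0.5) stop("direction power must exceed 0.5", call. = FALSE)
  min(max((C - 0.5) / (d - 0.5), 0), 1)
}

#' Posterior probability of causal association
#'
#' Scales the probability of true association by the assumed fraction of
#' coding-variant associations that are causal rather than
#' linkage-disequilibrium proxies: `PPA_c = pi * fraction_causal`.
#'
#' @param ppa Probability of true association.
#' @param fraction_causal Fraction in (0, 1].
#' @return `PPA_c`.
#' @export
ppa_to_causal <- function(ppa, fraction_causal) {
  if (any(fraction_causal <= 0 | fraction_causal > 1)) {
    stop("fraction_causal must lie in (0, 1]", call. = FALSE)
  }
  ppa * fraction_causal
}

odds <- function(p) p / (1 - p)
inv_odds <- function(o) o / (1 + o)

#' Map posterior probabilities to Bayes factors via a training prior
#'
#' `BF_c = PO_c / prior_odds(training)` where `PO_c` are the posterior
#' odds of causal association in the training variant set. The Bayes
#' factor then transfers to genes with different priors through
#' [apply_gene_prior()].
#'
#' @param ppa_c Posterior probabilities of causal association (per
#'   stratum), each < 1.
#' @param training_prior Prior probability of the training set, in (0, 1).
#' @return Numeric vector of Bayes factors `BF_c >= 0`.
#' @export
calibrate_bayes_factors <- function(ppa_c, training_prior) {
  if (training_prior <= 0 || training_prior >= 1) {
    stop("training prior must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(ppa_c >= 1)) stop("PPA_c must be < 1 to form posterior odds", call. = FALSE)
  odds(ppa_c) / odds(training_prior)
}

#' Update a causal posterior with a gene-specific prior
#'
#' New posterior odds are `BF_c * prior_odds(gene prior)`; a prior of 1
#' forces the posterior to 1 regardless of the Bayes factor (degenerate,
#' warned).
#'
#' @param bf_c Bayes factor(s) for causal association.
#' @param gene_prior Gene prior probability in (0, 1].
#' @return Updated posterior probability `PPA_c'`.
#' @export
apply_gene_prior <- function(bf_c, gene_prior) {
  if (gene_prior <= 0 || gene_prior > 1) {
    stop("gene prior must lie in (0, 1]", call. = FALSE)
  }
  if (gene_prior == 1) {
    warning("gene prior of 1 forces the posterior to 1", call. = FALSE)
    return(rep(1, length(bf_c)))
  }
  inv_odds(bf_c * odds(gene_prior))
}

#' Beta-uniform mixture fit to a P-value distribution
#'
#' Maximum-likelihood fit of `f(p) = lambda + (1 - lambda) alpha
#' p^(alpha-1)` (uniform null component plus a Beta(alpha, 1) non-null
#' component) by bounded optimization; `1 - lambda` is reported as the
#' non-null proportion, usable as an objective set-level prior.
#'
#' @param p P values in (0, 1], at least `min_n` of them.
#' @param min_n Minimum sample size (default 50).
#' @return Object of class `"bum_fit"`: `lambda`, `alpha`,
#'   `nonnull_proportion`, `loglik`, `loglik_uniform`.
#' @export
bum_fit <- function(p, min_n = 50L) {
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]", call. = FALSE)
  if (length(p) < min_n) {
    stop(sprintf("need at least %d P values", min_n), call. = FALSE)
  }
  nll <- function(par) {
    lambda <- expit(par[1]); alpha <- expit(par[2])
    -sum(log(lambda + (1 - lambda) * alpha * p^(alpha - 1)))
  }
  op <- stats::optim(c(1, -1), nll, method = "L-BFGS-B",
                     lower = c(-12, -12), upper = c(12, 12))
  lambda <- expit(op$par[1]); alpha <- expit(op$par[2])
  ll <- -op$value
  ## the pure-uniform model (loglik 0) is nested at lambda = 1: if the
  ## optimizer lands below it, report the uniform fit instead
  if (ll < 0) { lambda <- 1; alpha <- 1; ll <- 0 }
  structure(list(lambda = lambda, alpha = alpha,
                 nonnull_proportion = 1 - lambda,
                 loglik = ll, loglik_uniform = 0),
            class = "bum_fit")
}

#' Expected number of true associations across strata
#'
#' `sum(count * ppa)` per stratum, with the interval propagated from the
#' per-stratum PPA bounds.
#'
#' @param counts Variant counts per stratum.
#' @param ppa Per-stratum PPA point estimates.
#' @param ppa_lo,ppa_hi Optional per-stratum interval bounds.
#' @return List: `expected`, and `lo`/`hi` when bounds are given.
#' @export
expected_true_count <- function(counts, ppa, ppa_lo = NULL, ppa_hi = NULL) {
  stopifnot(all(counts >= 0), length(counts) == length(ppa))
  out <- list(expected = sum(counts * ppa))
  if (!is.null(ppa_lo)) out$lo <- sum(counts * ppa_lo)
  if (!is.null(ppa_hi)) out$hi <- sum(counts * ppa_hi)
  out
}

#' Concordance-calibrated PPA table over P-value strata
#'
#' End-to-end calibration: for each discovery P-value stratum, computes
#' the replication direction concordance with bootstrap CI, the direction
#' power d from the stratum's (shrunken) discovery effects and replication
#' standard errors, the implied proportion of true associations pi, and
#' causal posteriors over the `fraction_causal` grid.
#'
#' @param discovery Data frame: `variant_id`, `beta`, `se`, `p`,
#'   `direction`.
#' @param replication Data frame: `variant_id`, `se`, `direction`.
#' @param thresholds Stratum boundaries (upper P limits; default
#'   `c(5e-4, 5e-3, 0.05, 0.5, 1)`). Strata are nested (`p < t`).
#' @param fraction_causal Grid of causal fractions (default
#'   `c(0.25, 0.40, 0.55)`).
#' @param shrinkage Multiplier < 1 applied to discovery effect magnitudes
#'   when estimating d, countering winner's curse (default 0.8).
#' @param filter Optional logical filter over discovery rows.
#' @param n_boot,seed Bootstrap controls.
#' @return Object of class `"ppa_calibration"`: a data frame with one row
#'   per stratum (C, CI, d, pi with CI, and one `ppa_c_*` column per causal
#'   fraction) plus the parameters used.
#' @export
ppa_calibration <- function(discovery, replication,
                            thresholds = c(5e-4, 5e-3, 0.05, 0.5, 1),
                            fraction_causal = c(0.25, 0.40, 0.55),
                            shrinkage = 0.8, filter = NULL,
                            n_boot = 1000L, seed = 1L) {
  m <- match(discovery$variant_id, replication$variant_id)
  rows <- lapply(seq_along(thresholds), function(i) {
    thr <- thresholds[i]
    cf <- concordance_fraction(discovery, replication, p_threshold = thr,
                               filter = filter, n_boot = n_boot,
                               seed = substream_seed(seed, paste0("stratum", i)))
    keep <- discovery$p < thr & !is.na(m)
    if (!is.null(filter)) keep <- keep & filter
    d <- direction_power(shrinkage * abs(discovery$beta[keep]),
                         replication$se[m[keep]])
    d <- max(d, 0.5 + 1e-6)
    pi_hat <- concordance_to_ppa(cf$C, d)
    pi_lo <- concordance_to_ppa(cf$ci[1], d)
    pi_hi <- concordance_to_ppa(cf$ci[2], d)
    row <- data.frame(p_threshold = thr, n = cf$n, C = cf$C,
                      C_lo = cf$ci[1], C_hi = cf$ci[2], d = d,
                      ppa = pi_hat, ppa_lo = pi_lo, ppa_hi = pi_hi)
    for (fc in fraction_causal) {
      row[[sprintf("ppa_c_%g", fc)]] <- ppa_to_causal(pi_hat, fc)
    }
    row
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, thresholds = thresholds,
                 fraction_causal = fraction_causal, shrinkage = shrinkage),
            class = "ppa_calibration")
}
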