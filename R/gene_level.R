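#' Burden test of a variant grouping
#'
#' Regresses case status on the per-sample (weighted) qualifying-allele
#' count plus covariates. Missing genotypes count as reference (dosage 0)
#' in the burden score -- conservative for rare variants and deliberately
#' different from the within-subgroup mean imputation used by
#' single-variant tests. The regression is Firth-penalized whenever the
#' carrier count is below `firth_threshold` (always/never overridable);
#' the P value is a likelihood-ratio test either way.
#'
#' @param status Binary phenotype vector.
#' @param dosage Matrix (samples x qualifying variants) of allele dosages
#'   with missing genotypes zero-coded.
#' @param covariates Optional covariate matrix.
#' @param weights Optional per-variant weights in `[0, 1]` (unit weights if
#'   absent). All-zero weights are an error.
#' @param firth `"auto"` (default), `"always"`, or `"never"`.
#' @param firth_threshold Carrier count below which `"auto"` penalizes.
#' @return An `assoc_result` with `n_variants`, `n_carriers`, and
#'   `carrier_freq` attached; if the grouping has no carriers the result
#'   carries `p = NA` and is flagged `no_carriers`.
#' @export
burden_test <- function(status, dosage, covariates = NULL, weights = NULL,
                        firth = c("auto", "always", "never"),
                        firth_threshold = 50L) {
  firth <- match.arg(firth)
  check_phenotype(status)
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("one weight per variant required", call. = FALSE)
  if (all(weights == 0)) stop("degenerate score: all weights are zero", call. = FALSE)
  score <- as.numeric(dosage %*% weights)
  carriers <- sum(score > 0)
  res_base <- function(r) {
    r$n_variants <- m
    r$n_carriers <- carriers
    r$carrier_freq <- carriers / length(status)
    r
  }
  if (carriers == 0L) {
    r <- assoc_result(NA_real_, NA_real_, NA_real_, sum(status == 1),
                      sum(status == 0), "burden")
    r$no_carriers <- TRUE
    return(res_base(r))
  }
  use_firth <- firth == "always" || (firth == "auto" && carriers < firth_threshold)
  n <- length(status)
  X0 <- design_matrix(n, covariates)
  X <- cbind(X0, score = score)
  k <- ncol(X)
  if (use_firth) {
    full <- firth_fit(status, X)
    red <- firth_fit(status, X, fixed = k)
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    r <- assoc_result(full$beta[k], full$se[k],
                      stats::pchisq(lrt, 1L, lower.tail = FALSE),
                      sum(status == 1), sum(status == 0), "burden",
                      converged = full$converged)
  } else {
    fit <- stats::glm.fit(X, status, family = stats::binomial())
    fit0 <- stats::glm.fit(X0, status, family = stats::binomial())
    lrt <- max(0, fit0$deviance - fit$deviance)
    w <- fit$weights
    se <- sqrt(diag(solve(crossprod(X * w, X))))[k]
    r <- assoc_result(unname(fit$coefficients[k]), unname(se),
                      stats::pchisq(lrt, 1L, lower.tail = FALSE),
                      sum(status == 1), sum(status == 0), "burden")
  }
  res_base(r)
}

## Liu et al. moment-matching tail probability for a positive linear
## combination of 1-df chi-squares.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- df + delta; sigma_x <- sqrt(2 * (df + 2 * delta))
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = df, ncp = delta, lower.tail = FALSE)
}

## Imhof's numeric inversion of the characteristic function.
imhof_pvalue <- function(q, lambda) {
  f <- function(u) {
    lu <- lambda %o% u
    theta <- 0.5 * .colSums(atan(lu), length(lambda), length(u)) - 0.5 * q * u
    rho <- exp(0.25 * .colSums(log1p(lu * lu), length(lambda), length(u)))
    sin(theta) / (u * rho)
  }
  val <- try(stats::integrate(f, 0, Inf, subdivisions = 500L,
                              rel.tol = 1e-7)$value, silent = TRUE)
  if (inherits(val, "try-error")) return(liu_pvalue(q, lambda))
  min(max(0.5 + val / pi, 0), 1)
}

#' Sequence kernel association test (SKAT) of a variant grouping
#'
#' Variance-component score test robust to mixed effect directions:
#' `Q = sum_j w_j^2 (g_j' (y - p0))^2` under the logistic null model with
#' covariates; the null distribution of `Q` is the weighted mixture of
#' 1-df chi-squares given by the eigenvalues of the projected, weighted
#' genotype kernel. Kernel weights default to uniform within a mask (the
#' masks already encode severity); the tail probability uses
#' moment-matching by default, with exact Imhof numeric integration for
#' small P values or on request.
#'
#' @inheritParams burden_test
#' @param kernel_weights Optional per-variant kernel weights.
#' @param method `"auto"` (moment-matching, refined by integration when
#'   P < 1e-4), `"liu"`, or `"imhof"`.
#' @return List: `p`, statistic `Q`, eigenvalues `lambda`, `n_variants`.
#' @export
skat_test <- function(status, dosage, covariates = NULL, kernel_weights = NULL,
                      method = c("auto", "liu", "imhof")) {
  method <- match.arg(method)
  check_phenotype(status)
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(kernel_weights)) kernel_weights <- rep(1, m)
  n <- length(status)
  X <- design_matrix(n, covariates)
  null <- skat_null(status, X)
  skat_with_null(dosage, kernel_weights, null, method)
}

## Reusable logistic null model for SKAT / score screens.
skat_null <- function(status, X) {
  p0 <- if (ncol(X) == 1L) rep(mean(status), length(status)) else
    stats::glm.fit(X, status, family = stats::binomial())$fitted.values
  w0 <- p0 * (1 - p0)
  list(X = X, p0 = p0, w0 = w0, r = status - p0,
       XtWX_inv = solve(crossprod(X * w0, X)))
}

skat_with_null <- function(dosage, kernel_weights, null, method = "auto") {
  Gk <- as.matrix(dosage) %*% diag(kernel_weights, ncol(dosage))
  Q <- sum(as.numeric(crossprod(Gk, null$r))^2)
  A <- crossprod(Gk * null$w0, Gk)
  B <- crossprod(null$X, Gk * null$w0)
  K <- A - t(B) %*% null$XtWX_inv %*% B
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(abs(lambda), 1e-30)]
  if (!length(lambda)) stop("rank-0 genotype submatrix", call. = FALSE)
  p <- switch(method,
              liu = liu_pvalue(Q, lambda),
              imhof = imhof_pvalue(Q, lambda),
              auto = {
                ## moment matching first; exact inversion where the tail
                ## approximation error matters for decisions
                p0 <- liu_pvalue(Q, lambda)
                if (is.finite(p0) && p0 < 0.2) imhof_pvalue(Q, lambda) else p0
              })
  list(p = p, Q = Q, lambda = lambda, n_variants = ncol(dosage), test = "skat")
}

#' Per-variant gene-inactivation probability weights
#'
#' Default scheme: high-confidence protein-truncating variants weigh 1.0;
#' low-confidence PTVs 0.5; missense and splice variants weigh
#' `0.5 * damaging_calls / 5`. The table is configurable.
#'
#' @param annotations Annotation rows for the nonsynonymous variants of one
#'   gene (columns `consequence`, `ptv_confidence`, `pred1`--`pred5`).
#' @param scheme Named list: `ptv_high`, `ptv_low`, `missense_scale`.
#' @return Named numeric vector of weights in `[0, 1]` (by variant id when
#'   available).
#' @export
inactivation_weights <- function(annotations,
                                 scheme = list(ptv_high = 1, ptv_low = 0.5,
                                               missense_scale = 0.5)) {
  if (any(!annotations$consequence %in% c("protein_truncating", "missense", "splice"))) {
    stop("inactivation weights are defined for nonsynonymous variants only",
         call. = FALSE)
  }
  calls <- rowSums(as.matrix(annotations[, paste0("pred", 1:5)]))
  w <- ifelse(annotations$consequence == "protein_truncating",
              ifelse(!is.na(annotations$ptv_confidence) &
                       annotations$ptv_confidence == "high",
                     scheme$ptv_high, scheme$ptv_low),
              scheme$missense_scale * calls / 5)
  if (!is.null(annotations$variant_id)) names(w) <- annotations$variant_id
  w
}

#' Effective number of independent masks for a gene
#'
#' Eigenvalue-based estimate on the correlation matrix of the per-sample
#' mask burden scores: `m_eff = (sum_i sqrt(lambda_i))^2 / sum_i lambda_i`.
#' This equals 1 for perfectly correlated masks, the mask count for
#' mutually uncorrelated ones, and tracks the permutation minimum-P oracle
#' ([permutation_meff()]) closely on nested mask structures — markedly
#' better than integer-snapping alternatives, which is why it is the
#' default here.
#'
#' @param scores Matrix (samples x masks) of per-sample burden scores.
#' @return `m_eff` in `[1, K]` where `K` is the number of masks with
#'   positive variance.
#' @export
effective_mask_count <- function(scores) {
  scores <- as.matrix(scores)
  v <- apply(scores, 2, stats::var)
  scores <- scores[, v > 0, drop = FALSE]
  if (!ncol(scores)) stop("all masks are empty or constant", call. = FALSE)
  K <- ncol(scores)
  if (K == 1L) return(1)
  lambda <- pmax(eigen(stats::cor(scores), symmetric = TRUE,
                       only.values = TRUE)$values, 0)
  m <- sum(sqrt(lambda))^2 / sum(lambda)
  min(max(m, 1), K)
}

#' Permutation oracle for the effective mask count
#'
#' Estimates the effective number of independent masks from the null
#' distribution of the minimum P value over the masks' score statistics
#' against freshly drawn null phenotypes, via the Sidak-model identity
#' `E[min P] = 1 / (1 + m_eff)`. Used as the arbiter for
#' [effective_mask_count()].
#'
#' @param scores Matrix (samples x masks) of per-sample burden scores.
#' @param n_perm Number of null draws (default 10000).
#' @param seed Integer seed.
#' @return Estimated `m_eff`.
#' @export
permutation_meff <- function(scores, n_perm = 10000L, seed = 1L) {
  scores <- as.matrix(scores)
  v <- apply(scores, 2, stats::var)
  scores <- scores[, v > 0, drop = FALSE]
  K <- ncol(scores)
  if (K == 0L) stop("all masks are empty or constant", call. = FALSE)
  if (K == 1L) return(1)
  S <- scale(scores, center = TRUE, scale = FALSE)
  norms <- sqrt(colSums(S^2))
  with_substream(seed, "permutation_meff", {
    n <- nrow(S)
    minp <- numeric(n_perm)
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      Y <- matrix(stats::rnorm(n * b), n, b)
      Z <- crossprod(S, Y) / norms   # exactly N(0,1) per mask under the null
      P <- 2 * stats::pnorm(-abs(Z))
      minp[done + seq_len(b)] <- apply(P, 2, min)
      done <- done + b
    }
    min(max(1 / mean(minp) - 1, 1), K)
  })
}

## Monte-Carlo effective-test count for the SKAT statistics of one gene's
## groupings: the per-variant score vector u = G'(y - p0) has null
## covariance K = G'P0G, so u is drawn from N(0, K), each grouping's Q is
## the sum of its squared components, P values come from the same
## moment-matching tail as the real test, and the effective count inverts
## E[min P] = 1/(1 + m). SKAT statistics across nested masks are more
## strongly dependent than the burden scores, so they get their own count.
skat_meff_mc <- function(kernel, grouping_idx, n_draws = 500L, seed = 1L) {
  K <- length(grouping_idx)
  if (K <= 1L) return(1)
  eg <- eigen(kernel, symmetric = TRUE)
  pos <- eg$values > 1e-10 * max(eg$values, 1e-30)
  if (!any(pos)) return(1)
  rt <- eg$vectors[, pos, drop = FALSE] %*%
    (sqrt(eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE]))
  lambdas <- lapply(grouping_idx, function(ix) {
    l <- eigen(kernel[ix, ix, drop = FALSE], symmetric = TRUE,
               only.values = TRUE)$values
    l[l > 1e-10 * max(l, 1e-30)]
  })
  with_substream(seed, "skat_meff", {
    U <- rt %*% matrix(stats::rnorm(nrow(kernel) * n_draws), ncol = n_draws)
    P <- vapply(seq_len(K), function(k) {
      if (!length(lambdas[[k]])) return(rep(1, n_draws))
      liu_pvalue(colSums(U[grouping_idx[[k]], , drop = FALSE]^2), lambdas[[k]])
    }, numeric(n_draws))
    minp <- apply(P, 1, min)
    min(max(1 / mean(minp) - 1, 1), K)
  })
}

#' Minimum-P consolidation across masks
#'
#' Corrects the smallest per-mask P value for the effective number of
#' independent masks by a Sidak-type adjustment with fractional exponent:
#' `1 - (1 - p_min)^m_eff`, capped at 1.
#'
#' @param p Per-mask P values (NAs dropped).
#' @param m_eff Effective number of independent masks.
#' @return Corrected P value, never smaller than `min(p)`.
#' @export
min_p_consolidate <- function(p, m_eff) {
  p <- p[is.finite(p)]
  if (!length(p)) stop("no finite P value to consolidate", call. = FALSE)
  pm <- min(p)
  min(1, -expm1(m_eff * log1p(-pm)))
}

#' Haploinsufficiency-weighted gene test
#'
#' Enters every nonsynonymous variant of a gene into burden and SKAT tests
#' with [inactivation_weights()], so the burden effect is interpreted as
#' the log odds ratio per unit of gene inactivation dose.
#'
#' @param status Binary phenotype vector.
#' @param dosage Matrix over the gene's nonsynonymous variants (columns
#'   named by variant id, missing zero-coded).
#' @param annotations Matching annotation rows (one per variant).
#' @param covariates Optional covariate matrix.
#' @param ... Passed to [burden_test()].
#' @return List with `burden` (`assoc_result`) and `skat` components and
#'   the `weights` used.
#' @export
weighted_gene_test <- function(status, dosage, annotations, covariates = NULL, ...) {
  w <- inactivation_weights(annotations)
  keep <- w > 0
  if (!any(keep)) stop("degenerate score: all inactivation weights are zero",
                       call. = FALSE)
  b <- burden_test(status, dosage[, keep, drop = FALSE], covariates,
                   weights = w[keep], ...)
  s <- skat_test(status, dosage[, keep, drop = FALSE], covariates,
                 kernel_weights = w[keep])
  list(burden = b, skat = s, weights = w)
}

#' Consolidate per-mask results into the four gene-level statistics
#'
#' All distinct groupings of a gene (mask by transcript set, after
#' [collapse_transcript_sets()], so duplicate transcript sets never
#' multiple-count) enter a single minimum-P consolidation: the smallest
#' per-grouping P value for each test is corrected by the effective number
#' of independent groupings estimated from the correlation of their
#' per-sample burden scores ([effective_mask_count()]). Near-identical
#' groupings therefore contribute almost nothing to the correction while
#' genuinely distinct masks count fully.
#'
#' @param mask_results Data frame with one row per distinct grouping:
#'   columns `transcript_set`, `mask`, `burden_p`, `burden_effect`,
#'   `burden_se`, `skat_p`, `n_variants`, `carrier_freq`.
#' @param mask_scores Matrix (samples x distinct groupings) of per-sample
#'   burden scores used to estimate `m_eff`.
#' @param weighted Optional [weighted_gene_test()] output.
#' @param threshold Exome-wide gene significance threshold used for the
#'   flag (see [bonferroni_threshold()]).
#' @param skat_m_eff Optional effective-test count for the SKAT minimum-P
#'   correction (the SKAT statistics of nested masks are more dependent
#'   than the burden scores); defaults to the burden-score `m_eff`.
#' @return A one-row data frame: the four consolidated P values, the best
#'   mask's burden effect/se, `m_eff`, `best_mask`, counts, and a
#'   significance flag.
#' @export
consolidate_gene <- function(mask_results, mask_scores, weighted = NULL,
                             threshold = bonferroni_threshold(),
                             skat_m_eff = NULL) {
  stopifnot(nrow(mask_results) >= 1L)
  meff <- if (!is.null(mask_scores)) {
    tryCatch(effective_mask_count(as.matrix(mask_scores)),
             error = function(e) 1)
  } else 1
  if (is.null(skat_m_eff)) skat_m_eff <- meff
  cons <- function(ps, m = meff) {
    if (!any(is.finite(ps))) return(NA_real_)
    min_p_consolidate(ps[is.finite(ps)], m)
  }
  ok_b <- is.finite(mask_results$burden_p)
  best <- if (any(ok_b)) {
    mask_results[ok_b, ][which.min(mask_results$burden_p[ok_b]), ]
  } else mask_results[1, ]
  n_ts <- length(unique(mask_results$transcript_set))
  data.frame(
    p_burden_minp = cons(mask_results$burden_p),
    p_skat_minp = cons(mask_results$skat_p, skat_m_eff),
    p_burden_weighted = if (!is.null(weighted)) weighted$burden$p else NA_real_,
    p_skat_weighted = if (!is.null(weighted)) weighted$skat$p else NA_real_,
    effect_burden = best$burden_effect,
    se_burden = best$burden_se,
    effect_weighted = if (!is.null(weighted)) weighted$burden$effect else NA_real_,
    se_weighted = if (!is.null(weighted)) weighted$burden$se else NA_real_,
    best_mask = best$mask,
    m_eff = meff,
    n_transcript_sets = n_ts,
    n_variants = best$n_variants,
    carrier_freq = best$carrier_freq,
    exome_wide = {
      ps <- c(cons(mask_results$burden_p), cons(mask_results$skat_p),
              if (!is.null(weighted)) c(weighted$burden$p, weighted$skat$p))
      any(is.finite(ps) & ps < threshold)
    },
    stringsAsFactors = FALSE
  )
}

#' Progressive allele removal curve
#'
#' Recomputes the burden test after removing the strongest variants one at
#' a time (in the supplied order, typically increasing single-variant P
#' value), tracing how many alleles carry an aggregate signal.
#'
#' @param status,covariates As in [burden_test()].
#' @param dosage Matrix over the mask's variants (columns named).
#' @param order Column order of removal (indices or column names), best
#'   variant first. Default: none removed first, then column order.
#' @param ... Passed to [burden_test()].
#' @return Data frame: `removed` (0..m), `p`, `effect`, `lo`, `hi` (95%
#'   interval); the terminal all-removed row is `NA`.
#' @export
progressive_removal <- function(status, dosage, covariates = NULL,
                                order = seq_len(ncol(dosage)), ...) {
  dosage <- as.matrix(dosage)
  if (!ncol(dosage)) stop("empty mask", call. = FALSE)
  if (is.character(order)) order <- match(order, colnames(dosage))
  m <- ncol(dosage)
  out <- vector("list", m + 1L)
  for (k in 0:m) {
    keep <- setdiff(seq_len(m), order[seq_len(k)])
    if (!length(keep)) {
      out[[k + 1L]] <- data.frame(removed = k, p = NA_real_, effect = NA_real_,
                                  lo = NA_real_, hi = NA_real_)
      next
    }
    r <- burden_test(status, dosage[, keep, drop = FALSE], covariates, ...)
    out[[k + 1L]] <- data.frame(removed = k, p = r$p, effect = r$effect,
                                lo = r$effect - 1.96 * r$se,
                                hi = r$effect + 1.96 * r$se)
  }
  do.call(rbind, out)
}

#' Burden test conditional on a single allele
#'
#' Re-runs the burden test with the named variant's dosage moved from the
#' aggregate score to the covariates, assessing how much of the gene signal
#' that single allele accounts for.
#'
#' @inheritParams progressive_removal
#' @param variant Column name or index of the allele to condition on.
#' @param in_mask If `TRUE` (default) the variant is removed from the
#'   burden score; if it is not a column of `dosage`, supply its dosage via
#'   `conditioning_dosage` and set `in_mask = FALSE`.
#' @param conditioning_dosage Dosage vector for an out-of-mask variant.
#' @param ... Passed to [burden_test()].
#' @return An `assoc_result` for the conditioned burden score.
#' @export
conditional_on_allele <- function(status, dosage, covariates = NULL, variant,
                                  in_mask = TRUE, conditioning_dosage = NULL, ...) {
  dosage <- as.matrix(dosage)
  if (in_mask) {
    j <- if (is.character(variant)) match(variant, colnames(dosage)) else variant
    if (is.na(j) || j < 1 || j > ncol(dosage)) {
      stop("variant absent from the mask", call. = FALSE)
    }
    if (ncol(dosage) == 1L) {
      stop("degenerate: conditioning on the only allele of the mask", call. = FALSE)
    }
    cond <- dosage[, j]
    dosage <- dosage[, -j, drop = FALSE]
  } else {
    if (is.null(conditioning_dosage)) {
      stop("out-of-mask conditioning requires conditioning_dosage", call. = FALSE)
    }
    cond <- conditioning_dosage
  }
  covs <- if (is.null(covariates)) cbind(cond = cond) else
    cbind(as.matrix(covariates), cond = cond)
  burden_test(status, dosage, covs, ...)
}
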