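## Shared null machinery for looped gene-level testing: the reduced
## (covariates-only) Firth fit, the glm null deviance, and the SKAT null
## depend only on phenotype and covariates, so they are computed once per
## scan rather than once per gene.
gene_null_model <- function(status, covariates = NULL) {
  n <- length(status)
  X0 <- design_matrix(n, covariates)
  glm0 <- stats::glm.fit(X0, status, family = stats::binomial())
  list(status = status, X0 = X0,
       null_deviance = glm0$deviance, skat = skat_null(status, X0))
}

burden_with_null <- function(null, score, weights_total = NULL,
                             firth = "auto", firth_threshold = 50L) {
  status <- null$status
  carriers <- sum(score > 0)
  n_case <- sum(status == 1); n_ctrl <- sum(status == 0)
  if (carriers == 0L) {
    r <- assoc_result(NA_real_, NA_real_, NA_real_, n_case, n_ctrl, "burden")
    r$no_carriers <- TRUE
    r$n_carriers <- 0L
    r$carrier_freq <- 0
    return(r)
  }
  use_firth <- firth == "always" || (firth == "auto" && carriers < firth_threshold)
  X <- cbind(null$X0, score = score)
  k <- ncol(X)
  if (use_firth) {
    full <- firth_fit(status, X)
    red <- firth_fit(status, X, fixed = k)
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    r <- assoc_result(full$beta[k], full$se[k],
                      stats::pchisq(lrt, 1L, lower.tail = FALSE),
                      n_case, n_ctrl, "burden", converged = full$converged)
  } else {
    fit <- stats::glm.fit(X, status, family = stats::binomial())
    lrt <- max(0, null$null_deviance - fit$deviance)
    w <- fit$weights
    se <- sqrt(diag(solve(crossprod(X * w, X))))[k]
    r <- assoc_result(unname(fit$coefficients[k]), unname(se),
                      stats::pchisq(lrt, 1L, lower.tail = FALSE),
                      n_case, n_ctrl, "burden")
  }
  r$n_carriers <- carriers
  r$carrier_freq <- carriers / length(status)
  r
}

#' Gene-level association scan of a cohort
#'
#' Runs the full gene-level stage for every gene: mask assignment per
#' transcript set, collapse of identical transcript-set groupings, burden
#' and SKAT tests per distinct grouping (missing genotypes zero-coded),
#' the haploinsufficiency-weighted tests over all nonsynonymous variants,
#' and consolidation into the four gene-level statistics with the
#' effective-mask-number minimum-P correction.
#'
#' @param bundle A [simulate_cohort()] result (or equivalent bundle).
#' @param defs Mask definitions (default [default_masks()]).
#' @param covariate_cols Columns of `bundle$samples` used as covariates.
#' @param adjust_bmi If `TRUE`, adds the body-mass-index covariate.
#' @param genes Optional subset of gene ids to scan.
#' @param weighted Run the weighted (haploinsufficiency) tests (default
#'   `TRUE`).
#' @param threshold Exome-wide significance threshold for the flag.
#' @param firth Burden penalization policy, see [burden_test()].
#' @param min_carriers Groupings with fewer carriers than this are
#'   excluded from minimum-P consolidation (their test statistics are too
#'   discrete to be comparable and would inflate the effective mask count
#'   without contributing rejection probability); when no grouping of a
#'   gene passes, all its groupings are used. Default 20.
#' @param seed Seed for the Monte-Carlo SKAT effective-test count.
#' @param best_guess If `TRUE`, restrict to the transcript-set-1 ("best
#'   guess") annotation instead of all transcript sets.
#' @return Data frame with one row per gene: the `consolidate_gene()`
#'   columns plus `gene`.
#' @export
gene_scan <- function(bundle, defs = default_masks(),
                      covariate_cols = c("PC1", "PC2"), adjust_bmi = FALSE,
                      genes = NULL, weighted = TRUE,
                      threshold = bonferroni_threshold(), firth = "auto",
                      min_carriers = 20L, seed = 1L, best_guess = FALSE) {
  ann <- bundle$annotations
  if (best_guess) ann <- ann[ann$transcript_set == 1L, , drop = FALSE]
  if (!is.null(genes)) ann <- ann[ann$gene %in% genes, , drop = FALSE]
  if (!nrow(ann)) stop("no annotated variants to scan", call. = FALSE)
  groupings <- assign_masks(ann, defs)
  y <- bundle$samples$status
  covs <- as.matrix(bundle$samples[, covariate_cols, drop = FALSE])
  if (adjust_bmi) covs <- cbind(covs, BMI = bundle$samples$BMI)
  null <- gene_null_model(y, covs)
  D0 <- dosage_for(bundle, unique(ann$variant_id), impute = "zero")

  out <- lapply(unique(groupings$gene), function(g) {
    rows <- collapse_transcript_sets(groupings[groupings$gene == g, , drop = FALSE])
    mask_results <- vector("list", nrow(rows))
    grouping_scores <- matrix(0, length(y), nrow(rows))
    for (i in seq_len(nrow(rows))) {
      vids <- rows$variants[[i]]
      Dm <- as.matrix(D0[, vids, drop = FALSE])
      score <- rowSums(Dm)
      grouping_scores[, i] <- score
      b <- burden_with_null(null, score, firth = firth)
      s <- if (b$n_carriers > 0L) {
        tryCatch(skat_with_null(Dm, rep(1, ncol(Dm)), null$skat),
                 error = function(e) list(p = NA_real_))
      } else list(p = NA_real_)
      mask_results[[i]] <- data.frame(
        transcript_set = rows$transcript_set[i], mask = rows$mask[i],
        burden_p = b$p, burden_effect = b$effect, burden_se = b$se,
        skat_p = s$p, n_variants = length(vids),
        carrier_freq = b$carrier_freq, stringsAsFactors = FALSE)
    }
    mask_results <- do.call(rbind, mask_results)
    carriers <- colSums(grouping_scores > 0)
    pass <- carriers >= min_carriers
    if (any(pass)) {
      mask_results <- mask_results[pass, , drop = FALSE]
      grouping_scores <- grouping_scores[, pass, drop = FALSE]
      rows <- rows[pass, , drop = FALSE]
    }
    ## m_eff uses each distinct grouping's score exactly once
    wres <- NULL
    if (weighted) {
      gene_ann <- ann[ann$gene == g & ann$transcript_set == min(ann$transcript_set[ann$gene == g]) &
                        ann$consequence %in% c("protein_truncating", "missense", "splice"), ,
                      drop = FALSE]
      gene_ann <- gene_ann[!duplicated(gene_ann$variant_id), , drop = FALSE]
      if (nrow(gene_ann)) {
        w <- inactivation_weights(gene_ann)
        keep <- w > 0
        if (any(keep)) {
          Dw <- as.matrix(D0[, gene_ann$variant_id[keep], drop = FALSE])
          bw <- burden_with_null(null, as.numeric(Dw %*% w[keep]), firth = firth)
          sw <- if (bw$n_carriers > 0L) {
            tryCatch(skat_with_null(Dw, w[keep], null$skat),
                     error = function(e) list(p = NA_real_))
          } else list(p = NA_real_)
          wres <- list(burden = bw, skat = sw)
        }
      }
    }
    skat_meff <- if (nrow(rows) > 1L) {
      union_vids <- unique(unlist(rows$variants))
      Gu <- as.matrix(D0[, union_vids, drop = FALSE])
      A <- crossprod(Gu * null$skat$w0, Gu)
      Bm <- crossprod(null$skat$X, Gu * null$skat$w0)
      kern <- A - t(Bm) %*% null$skat$XtWX_inv %*% Bm
      idx <- lapply(rows$variants, match, table = union_vids)
      tryCatch(skat_meff_mc(kern, idx, seed = substream_seed(seed, g)),
               error = function(e) NULL)
    } else 1
    res <- consolidate_gene(mask_results, grouping_scores, weighted = wres,
                            threshold = threshold, skat_m_eff = skat_meff)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Universe table for matched-gene construction
#'
#' Summarizes, per gene, the qualifying-variant count and aggregate variant
#' frequency used to match comparison genes to a gene set.
#'
#' @param scan A [gene_scan()] result.
#' @return Data frame: `gene`, `n_variants`, `aggregate_freq`, and the
#'   burden minimum-P statistic used for ranking.
#' @export
gene_universe <- function(scan) {
  data.frame(gene = scan$gene, n_variants = scan$n_variants,
             aggregate_freq = pmax(scan$carrier_freq, 1e-6),
             p = scan$p_burden_minp, stringsAsFactors = FALSE)
}
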