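assoc_result <- function(effect, se, p, n_cases, n_controls, test,
                         converged = TRUE) {
  structure(list(effect = effect, se = se, p = p,
                 direction = sign(effect), n_cases = n_cases,
                 n_controls = n_controls, test = test, converged = converged),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s test: beta = %.4g (se %.4g), P = %.3g, %d cases / %d controls\n",
              x$test, x$effect, x$se, x$p, x$n_cases, x$n_controls))
  invisible(x)
}

check_phenotype <- function(status) {
  if (length(unique(status[!is.na(status)])) < 2L) {
    stop("degenerate phenotype: need at least one case and one control",
         call. = FALSE)
  }
}

design_matrix <- function(n, covariates) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  X
}

## Penalized (Jeffreys-prior) logistic fit; the penalty keeps estimates
## finite under separation. `fixed` names coefficients constrained to zero
## while the penalty is still evaluated on the full design, so the
## difference of penalized log-likelihoods is the profile penalized
## likelihood-ratio statistic for those coefficients.
firth_fit <- function(y, X, fixed = integer(0), tol = 1e-8, max_iter = 50L) {
  k <- ncol(X)
  free <- setdiff(seq_len(k), fixed)
  beta <- numeric(k)
  mu <- mean(y)
  beta[1] <- log(mu / (1 - mu))
  pen_loglik <- function(b) {
    eta <- as.numeric(X %*% b)
    p <- expit(eta)
    XtWX <- crossprod(X * (p * (1 - p)), X)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(XtWX)$modulus[1]
  }
  ll <- pen_loglik(beta)
  converged <- FALSE
  se <- rep(NA_real_, k)
  for (it in seq_len(max_iter)) {
    p <- expit(as.numeric(X %*% beta))
    W <- p * (1 - p)
    XtWX <- crossprod(X * W, X)
    XtWX_inv <- solve(XtWX)
    ## h_i = W_i * x_i' (X'WX)^-1 x_i  (leverage of the weighted fit)
    h <- W * rowSums((X %*% XtWX_inv) * X)
    U <- as.numeric(crossprod(X, (y - p) + h * (0.5 - p)))
    if (max(abs(U[free])) < tol) { converged <- TRUE; break }
    step <- numeric(k)
    step[free] <- solve(XtWX[free, free, drop = FALSE], U[free])
    ## step-halving to guarantee penalized-likelihood ascent
    for (half in 0:15) {
      cand <- beta + step / 2^half
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    beta <- cand
    ll <- ll_new
  }
  p <- expit(as.numeric(X %*% beta))
  W <- p * (1 - p)
  cov <- solve(crossprod(X * W, X)[free, free, drop = FALSE])
  se[free] <- sqrt(diag(cov))
  list(beta = beta, se = se, loglik = ll, converged = converged)
}

#' Firth-penalized logistic regression single-variant test
#'
#' Penalized-likelihood logistic regression of case status on allele dosage
#' plus covariates. The Jeffreys-prior penalty yields finite effect
#' estimates even under complete separation, the situation typical of very
#' rare variants. Two-sided P value from the penalized likelihood-ratio
#' test of the dosage term; modified Newton iterations with step-halving,
#' tolerance 1e-8 on the score norm, at most 50 iterations.
#' Non-convergence is flagged, never silently dropped.
#'
#' @param status Binary phenotype vector (0 control, 1 case).
#' @param dosage Allele dosage vector (0/1/2; non-integer allowed).
#' @param covariates Optional numeric covariate matrix.
#' @return An `assoc_result`: log odds ratio `effect`, `se`, two-sided `p`,
#'   `direction`, sample counts, `converged` flag.
#' @export
firth_logistic <- function(status, dosage, covariates = NULL) {
  check_phenotype(status)
  if (stats::var(dosage) == 0) stop("monomorphic: dosage is constant", call. = FALSE)
  n <- length(status)
  X0 <- design_matrix(n, covariates)
  X <- cbind(X0, dosage = dosage)
  k <- ncol(X)
  full <- firth_fit(status, X)
  red <- firth_fit(status, X, fixed = k)
  lrt <- max(0, 2 * (full$loglik - red$loglik))
  assoc_result(effect = full$beta[k], se = full$se[k],
               p = stats::pchisq(lrt, 1L, lower.tail = FALSE),
               n_cases = sum(status == 1), n_controls = sum(status == 0),
               test = "firth", converged = full$converged && red$converged)
}

#' Single-variant score test
#'
#' Rao score test of association between a dosage and a binary phenotype
#' under a null model with covariates only. The `binomial` family uses the
#' logistic null model; the `gaussian` family is the quantitative-scale
#' score test (null-model maximum-likelihood residual variance), the test
#' to which the kinship-adjusted [mixed_score_test()] reduces when the
#' kinship matrix is a scaled identity. Without covariates the two families
#' coincide exactly.
#'
#' @inheritParams firth_logistic
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return An `assoc_result` with a score-based effect approximation
#'   (`U/V`) and `se = 1/sqrt(V)`.
#' @export
score_test <- function(status, dosage, covariates = NULL,
                       family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  check_phenotype(status)
  if (stats::var(dosage) == 0) stop("monomorphic: dosage is constant", call. = FALSE)
  n <- length(status)
  X <- design_matrix(n, covariates)
  if (family == "binomial") {
    fit0 <- if (ncol(X) == 1L) {
      list(p = rep(mean(status), n))
    } else {
      list(p = stats::glm.fit(X, status, family = stats::binomial())$fitted.values)
    }
    w <- fit0$p * (1 - fit0$p)
    r <- status - fit0$p
    U <- sum(dosage * r)
    gw <- dosage * w
    XtWX_inv <- solve(crossprod(X * w, X))
    a <- as.numeric(crossprod(X, gw))
    V <- sum(dosage * gw) - as.numeric(t(a) %*% XtWX_inv %*% a)
  } else {
    Q <- qr(X)
    r <- qr.resid(Q, status)
    gt <- qr.resid(Q, dosage)
    sigma2 <- mean(r^2)
    U <- sum(gt * r)
    V <- sigma2 * sum(gt^2)
  }
  stat <- if (V <= 0) 0 else U^2 / V
  assoc_result(effect = if (V > 0) U / V else 0,
               se = if (V > 0) 1 / sqrt(V) else Inf,
               p = stats::pchisq(stat, 1L, lower.tail = FALSE),
               n_cases = sum(status == 1), n_controls = sum(status == 0),
               test = "score")
}

#' Kinship-adjusted score test (simplified EMMAX)
#'
#' Variance-component score test treating the binary phenotype on the
#' quantitative scale, as EMMAX does: the phenotypic covariance
#' `sigma_g^2 K + sigma_e^2 I` is estimated once by maximum likelihood on
#' the eigenbasis of the kinship matrix, then a generalized-least-squares
#' score test of the dosage is performed. With `K` proportional to the
#' identity the two variance components are jointly unidentifiable, the
#' working covariance is proportional to `I` for any estimate, and the test
#' reduces exactly to [score_test()] with `family = "gaussian"`.
#'
#' @inheritParams firth_logistic
#' @param kinship Symmetric positive semidefinite kinship matrix.
#' @return An `assoc_result` labelled `"mixed_score"`.
#' @export
mixed_score_test <- function(status, dosage, covariates = NULL, kinship) {
  check_phenotype(status)
  if (stats::var(dosage) == 0) stop("monomorphic: dosage is constant", call. = FALSE)
  n <- length(status)
  if (!isSymmetric(unname(kinship), tol = 1e-8)) {
    stop("kinship must be symmetric", call. = FALSE)
  }
  eig <- eigen(kinship, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop("kinship must be positive semidefinite", call. = FALSE)
  }
  d <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  y <- as.numeric(Ut %*% status)
  X <- Ut %*% design_matrix(n, covariates)
  g <- as.numeric(Ut %*% dosage)

  ## profile ML over gamma = sigma_g^2 / sigma_e^2
  prof <- function(loggamma) {
    w <- 1 / (exp(loggamma) * d + 1)
    Xw <- X * w
    b <- solve(crossprod(Xw, X), crossprod(Xw, y))
    r <- y - as.numeric(X %*% b)
    sigma2 <- sum(w * r^2) / n
    -0.5 * (n * log(sigma2) - sum(log(w)))
  }
  op <- stats::optimize(prof, c(-12, 12), maximum = TRUE)
  if (prof(-12) >= op$objective) op$maximum <- -Inf  # boundary: no kinship variance
  w <- 1 / (exp(op$maximum) * d + 1)
  w <- w / mean(w)   # fix the weight scale so effect estimates are comparable

  Xw <- X * w
  XtWX_inv <- solve(crossprod(Xw, X))
  b <- XtWX_inv %*% crossprod(Xw, y)
  r <- y - as.numeric(X %*% b)
  sigma2 <- sum(w * r^2) / n
  gt <- g - as.numeric(X %*% (XtWX_inv %*% crossprod(Xw, g)))
  U <- sum(w * gt * r)
  V <- sigma2 * sum(w * gt^2)
  stat <- if (V <= 0) 0 else U^2 / V
  assoc_result(effect = if (V > 0) U / V else 0,
               se = if (V > 0) 1 / sqrt(V) else Inf,
               p = stats::pchisq(stat, 1L, lower.tail = FALSE),
               n_cases = sum(status == 1), n_controls = sum(status == 0),
               test = "mixed_score")
}

#' Fixed-effect inverse-variance weighted meta-analysis
#'
#' @param beta Per-study effect estimates (or a data frame with columns
#'   `effect`/`beta` and `se`).
#' @param se Per-study standard errors.
#' @return List: pooled `effect`, `se`, two-sided `p`, normalized
#'   `weights`, and `n_studies`.
#' @export
meta_fixed_ivw <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- if (!is.null(beta$effect)) beta$effect else beta$beta
  }
  ok <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[ok]; se <- se[ok]
  if (!length(beta)) stop("no estimable studies to meta-analyse", call. = FALSE)
  w <- 1 / se^2
  eff <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  list(effect = eff, se = pooled_se, p = z_to_p(eff / pooled_se),
       weights = w / sum(w), n_studies = length(beta),
       direction = sign(eff))
}

#' Sample-size weighted meta-analysis of z scores
#'
#' Pools signed z statistics across studies with square-root-sample-size
#' weights: `z = sum(sqrt(n_i) z_i dir_i) / sqrt(sum(n_i))`.
#'
#' @param z Per-study absolute or signed z statistics.
#' @param sample_sizes Per-study (effective) sample sizes, positive.
#' @param directions Optional direction signs; default `sign(z)` with `z`
#'   then taken as signed.
#' @return List with pooled `z` and two-sided `p`.
#' @export
meta_sample_weighted <- function(z, sample_sizes, directions = NULL) {
  if (is.null(directions)) { directions <- sign(z); z <- abs(z) }
  if (length(z) != length(sample_sizes) || length(z) != length(directions)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (any(sample_sizes <= 0)) stop("sample sizes must be positive", call. = FALSE)
  pooled <- sum(sqrt(sample_sizes) * z * directions) / sqrt(sum(sample_sizes))
  list(z = pooled, p = z_to_p(pooled))
}

## Resolve missing dosages (within-subgroup mean imputation, or reference
## zero-coding for burden scores) and return a sparse matrix over the
## requested variants; memory stays proportional to the carrier count.
dosage_for <- function(bundle, variant_ids, impute = c("mean", "zero")) {
  impute <- match.arg(impute)
  j <- match(variant_ids, bundle$genotypes$variant_ids)
  if (anyNA(j)) stop("unknown variant id", call. = FALSE)
  D <- bundle$genotypes$dosage[, j, drop = FALSE]
  M <- bundle$genotypes$missing[, j, drop = FALSE]
  miss <- Matrix::which(M > 0, arr.ind = TRUE)
  if (nrow(miss)) {
    old <- D[miss]
    new <- if (impute == "zero") {
      numeric(nrow(miss))
    } else {
      sg <- bundle$samples$subgroup
      vals <- numeric(nrow(miss))
      for (jj in unique(miss[, 2])) {
        rows_j <- miss[, 2] == jj
        mi <- miss[rows_j, 1]
        obs <- D[-mi, jj]
        mu <- tapply(obs, sg[-mi], mean)
        rep_mu <- mu[as.character(sg[mi])]
        rep_mu[is.na(rep_mu)] <- mean(obs)
        vals[rows_j] <- rep_mu
      }
      vals
    }
    ## sparse-safe scattered update: add the delta at the missing cells
    D <- Matrix::drop0(D + Matrix::sparseMatrix(i = miss[, 1], j = miss[, 2],
                                                x = new - old, dims = dim(D)))
  }
  colnames(D) <- variant_ids
  D
}

#' Per-subgroup single-variant scan with inverse-variance meta-analysis
#'
#' Runs the score test for every variant within each sample subgroup
#' (mirroring a stratified study design), then combines subgroups by
#' fixed-effect inverse-variance weighted meta-analysis. Missing dosages
#' are mean-imputed within subgroup. A pooled `"mega"` mode (single scan
#' across all samples with subgroup indicators as covariates) is available
#' as a cross-check.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param covariate_cols Columns of `bundle$samples` to adjust for
#'   (default the first two principal components).
#' @param mode `"meta"` (per-subgroup + meta-analysis) or `"mega"` (pooled).
#' @param min_subgroup_carriers Subgroup results with fewer carriers than
#'   this are dropped from the meta-analysis (default 1).
#' @return Data frame: `variant_id`, `effect`, `se`, `z`, `p`, `direction`,
#'   `n_studies`.
#' @export
sv_scan <- function(bundle, covariate_cols = c("PC1", "PC2"),
                    mode = c("meta", "mega"), min_subgroup_carriers = 1L) {
  mode <- match.arg(mode)
  y <- bundle$samples$status
  vids <- bundle$genotypes$variant_ids
  D <- dosage_for(bundle, vids)
  covs <- as.matrix(bundle$samples[, covariate_cols, drop = FALSE])
  if (mode == "mega") {
    sgf <- factor(bundle$samples$subgroup)
    if (nlevels(sgf) > 1L) {
      covs <- cbind(covs, stats::model.matrix(~sgf)[, -1, drop = FALSE])
    }
    res <- score_scan_block(y, D, covs)
    return(data.frame(variant_id = vids, effect = res$effect, se = res$se,
                      z = res$effect / res$se, p = res$p,
                      direction = sign(res$effect), n_studies = 1L,
                      stringsAsFactors = FALSE))
  }
  sgs <- sort(unique(bundle$samples$subgroup))
  per <- lapply(sgs, function(s) {
    idx <- bundle$samples$subgroup == s
    if (length(unique(y[idx])) < 2L) return(NULL)
    score_scan_block(y[idx], D[idx, , drop = FALSE], covs[idx, , drop = FALSE],
                     min_carriers = min_subgroup_carriers)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  eff <- do.call(cbind, lapply(per, `[[`, "effect"))
  ses <- do.call(cbind, lapply(per, `[[`, "se"))
  out <- t(vapply(seq_along(vids), function(v) {
    b <- eff[v, ]; s <- ses[v, ]
    ok <- is.finite(b) & is.finite(s) & s > 0
    if (!any(ok)) return(c(NA, NA, NA, 0))
    m <- meta_fixed_ivw(b[ok], s[ok])
    c(m$effect, m$se, m$p, m$n_studies)
  }, numeric(4)))
  data.frame(variant_id = vids, effect = out[, 1], se = out[, 2],
             z = out[, 1] / out[, 2], p = out[, 3],
             direction = sign(out[, 1]), n_studies = as.integer(out[, 4]),
             stringsAsFactors = FALSE)
}

## Vectorized logistic score scan over the columns of a (possibly sparse)
## dosage matrix; Matrix generics keep memory proportional to carriers.
score_scan_block <- function(y, D, covs, min_carriers = 1L) {
  n <- length(y)
  X <- design_matrix(n, covs)
  p0 <- stats::glm.fit(X, y, family = stats::binomial())$fitted.values
  w <- p0 * (1 - p0)
  r <- y - p0
  U <- as.numeric(Matrix::crossprod(D, r))
  XtWX_inv <- solve(crossprod(X * w, X))
  A <- as.matrix(Matrix::crossprod(X, D * w))   # k x V
  V <- as.numeric(Matrix::colSums(D * D * w)) - colSums(A * (XtWX_inv %*% A))
  carriers <- as.numeric(Matrix::colSums(D > 0))
  bad <- V <= 1e-12 | carriers < min_carriers | carriers == n
  eff <- ifelse(bad, NA, U / V)
  se <- ifelse(bad, NA, 1 / sqrt(pmax(V, 1e-12)))
  list(effect = eff, se = se,
       p = ifelse(bad, NA, stats::pchisq(U^2 / pmax(V, 1e-12), 1L, lower.tail = FALSE)))
}
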