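#' Simulation configuration for a synthetic case-control exome cohort
#'
#' Bundles every knob of the cohort generator. Defaults reproduce the scale
#' and frequency structure of a large multi-ancestry type 2 diabetes exome
#' study: 20,791 cases and 24,440 controls drawn from 25 sample subgroups and
#' 5 ancestries, an allele-frequency spectrum of 2.3% common (MAF > 5%),
#' 4.2% low-frequency (0.5% < MAF < 5%) and 93.5% rare (MAF < 0.5%) variants,
#' and an assumed population prevalence of K = 0.08. Analyses at desk scale
#' override the counts.
#'
#' @param n_cases,n_controls Requested case and control counts.
#' @param n_subgroups Number of sample subgroups (cohort x technology strata).
#' @param n_ancestries Number of ancestries; subgroups are nested within them.
#' @param n_genes Number of simulated genes.
#' @param variants_per_gene List with `mean` and `dispersion` of a negative
#'   binomial for the variant count per gene (minimum one variant).
#' @param maf_spectrum Length-3 numeric: target fractions of common
#'   (MAF > 5%), low-frequency (0.5% < MAF < 5%) and rare (MAF < 0.5%)
#'   variants; must sum to 1.
#' @param gene_effect_specs List of [gene_effect_spec()] objects; genes not
#'   named there are simulated as null.
#' @param predictor_concordance Probability that each of the five in-silico
#'   deleteriousness predictors agrees with the latent damaging state.
#' @param missing_rate Completely-at-random genotype missingness probability.
#' @param missing_subgroup_multiplier Optional per-subgroup multiplier on
#'   `missing_rate` (length `n_subgroups`), a differential-missingness
#'   stressor. Default 1 for all subgroups.
#' @param prevalence Assumed population disease prevalence K.
#' @param pool_multiplier Population pool size as a multiple of
#'   `n_cases + n_controls` before ascertainment sampling.
#' @param pool_cap Hard cap on the pool size.
#' @param seed Integer master seed, expanded into named substreams.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_cases = 20791, n_controls = 24440,
                              n_subgroups = 25, n_ancestries = 5,
                              n_genes = 200,
                              variants_per_gene = list(mean = 30, dispersion = 5),
                              maf_spectrum = c(common = 0.023, low = 0.042, rare = 0.935),
                              gene_effect_specs = list(),
                              predictor_concordance = 0.8,
                              missing_rate = 0.005,
                              missing_subgroup_multiplier = NULL,
                              prevalence = 0.08,
                              pool_multiplier = 20,
                              pool_cap = 400000L,
                              seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_subgroups = n_subgroups,
              n_ancestries = n_ancestries, n_genes = n_genes)
  if (any(counts <= 0)) stop("all counts must be > 0", call. = FALSE)
  stop_if_not_prob(predictor_concordance, "predictor_concordance")
  stop_if_not_prob(missing_rate, "missing_rate")
  stop_if_not_prob(prevalence, "prevalence")
  if (length(maf_spectrum) != 3L || abs(sum(maf_spectrum) - 1) > 1e-8) {
    stop("maf_spectrum must be three fractions summing to 1", call. = FALSE)
  }
  if (is.null(missing_subgroup_multiplier)) {
    missing_subgroup_multiplier <- rep(1, n_subgroups)
  }
  stopifnot(length(missing_subgroup_multiplier) == n_subgroups)
  for (sp in gene_effect_specs) {
    if (!inherits(sp, "gene_effect_spec")) {
      stop("gene_effect_specs must be a list of gene_effect_spec objects",
           call. = FALSE)
    }
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_subgroups = as.integer(n_subgroups), n_ancestries = as.integer(n_ancestries),
    n_genes = as.integer(n_genes), variants_per_gene = variants_per_gene,
    maf_spectrum = unname(maf_spectrum), gene_effect_specs = gene_effect_specs,
    predictor_concordance = predictor_concordance, missing_rate = missing_rate,
    missing_subgroup_multiplier = missing_subgroup_multiplier,
    prevalence = prevalence, pool_multiplier = pool_multiplier,
    pool_cap = as.integer(pool_cap), seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Gene architecture specification
#'
#' Describes the true genetic architecture of one simulated gene. The four
#' architectures mirror patterns seen in sequencing studies of common
#' disease: `allelic_series` (many rare same-direction alleles, for example a
#' protective series of combined MAF 1.4%), `single_driver` (one
#' low-frequency variant carrying the signal over a null background),
#' `mixed_direction` (risk and protective alleles in the same gene, the
#' situation that favours variance-component over burden tests), and `null`.
#'
#' @param gene Gene identifier (for example `"G0007"`).
#' @param architecture One of `"null"`, `"allelic_series"`, `"single_driver"`,
#'   `"mixed_direction"`.
#' @param beta_mean,beta_sd Mean and s.d. of per-variant |log odds ratio| for
#'   affected variants.
#' @param carrier_freq Target aggregate carrier frequency of the qualifying
#'   alleles, in (0, 0.05].
#' @param direction `"risk"` or `"protective"` (ignored for
#'   `mixed_direction`, where signs alternate).
#' @return An object of class `"gene_effect_spec"`.
#' @export
gene_effect_spec <- function(gene, architecture = c("null", "allelic_series",
                                                    "single_driver", "mixed_direction"),
                             beta_mean = 0.5, beta_sd = 0.1,
                             carrier_freq = 0.014,
                             direction = c("risk", "protective")) {
  architecture <- match.arg(architecture)
  direction <- match.arg(direction)
  if (carrier_freq <= 0 || carrier_freq > 0.05) {
    stop("carrier_freq must lie in (0, 0.05]", call. = FALSE)
  }
  structure(list(gene = gene, architecture = architecture,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 carrier_freq = carrier_freq, direction = direction),
            class = "gene_effect_spec")
}

## MAF bin boundaries shared by the generator and the spectrum summary
.maf_bins <- list(common = c(0.05, 0.5), low = c(0.005, 0.05), rare = c(1e-4, 0.005))

draw_maf <- function(n, spectrum) {
  bin <- sample.int(3L, n, replace = TRUE, prob = spectrum)
  lo <- c(.maf_bins$common[1], .maf_bins$low[1], .maf_bins$rare[1])[bin]
  hi <- c(.maf_bins$common[2], .maf_bins$low[2], .maf_bins$rare[2])[bin]
  ## log-uniform within bin: rare alleles dominate within the rare bin too
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Classify minor allele frequencies into the standard three bins
#'
#' @param maf Numeric vector of minor allele frequencies.
#' @return Factor with levels `common`, `low`, `rare` (MAF > 5%,
#'   0.5--5%, < 0.5%).
#' @export
maf_bin <- function(maf) {
  cut(maf, breaks = c(-Inf, 0.005, 0.05, Inf),
      labels = c("rare", "low", "common"))
}

.consequences <- c("protein_truncating", "missense", "splice", "synonymous", "other")
.consequence_probs <- c(0.04, 0.55, 0.03, 0.30, 0.08)

simulate_annotations <- function(config) {
  nb <- config$variants_per_gene
  n_var <- pmax(1L, stats::rnbinom(config$n_genes, mu = nb$mean, size = nb$dispersion))
  gene <- sprintf("G%04d", seq_len(config$n_genes))
  gene_of <- rep(gene, n_var)
  V <- length(gene_of)
  chrom <- rep(((seq_len(config$n_genes) - 1L) %% 22L) + 1L, n_var)
  pos <- unlist(lapply(seq_len(config$n_genes), function(g) {
    g * 1e5 + sort(sample.int(50000L, n_var[g])) # unique positions per gene
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  maf <- draw_maf(V, config$maf_spectrum)
  csq <- sample(.consequences, V, replace = TRUE, prob = .consequence_probs)
  latent <- ifelse(csq == "protein_truncating", 1L,
                   ifelse(csq %in% c("missense", "splice"),
                          stats::rbinom(V, 1L, 0.5), 0L))
  agree <- config$predictor_concordance
  calls <- matrix(stats::rbinom(5L * V, 1L,
                                ifelse(rep(latent, each = 5L) == 1L, agree, 1 - agree)),
                  nrow = V, ncol = 5L, byrow = TRUE)
  ptv_conf <- ifelse(csq == "protein_truncating",
                     ifelse(stats::rbinom(V, 1L, 0.95) == 1L, "high", "low"), NA)
  variant_id <- sprintf("%d:%d:%s:%s", chrom, pos, ref, alt)

  ## transcript structure: annotate every variant on transcript set 1; on
  ## sets 2 and 3 (when the gene has them) each variant is present w.p. 0.8,
  ## so some transcript sets collapse to identical allele groupings
  n_ts <- sample.int(3L, config$n_genes, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  names(n_ts) <- gene
  rows <- vector("list", 3L)
  base <- data.frame(variant_id = variant_id, gene = gene_of,
                     chrom = chrom, pos = pos, ref = ref, alt = alt,
                     consequence = csq, ptv_confidence = ptv_conf,
                     maf = maf, latent_damaging = latent,
                     stringsAsFactors = FALSE)
  base <- cbind(base, stats::setNames(as.data.frame(calls),
                                      paste0("pred", 1:5)))
  for (ts in 1:3) {
    has_ts <- n_ts[base$gene] >= ts
    keep <- if (ts == 1L) has_ts else has_ts & stats::rbinom(V, 1L, 0.8) == 1L
    r <- base[keep, , drop = FALSE]
    if (nrow(r)) r$transcript_set <- ts
    rows[[ts]] <- r
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  list(annotations = ann, base = base)
}

apply_gene_effects <- function(base, config) {
  beta <- numeric(nrow(base))
  maf <- base$maf
  specs <- config$gene_effect_specs
  gene_truth <- data.frame(gene = unique(base$gene), architecture = "null",
                           direction = NA_character_, carrier_freq = NA_real_,
                           stringsAsFactors = FALSE)
  for (sp in specs) {
    idx <- which(base$gene == sp$gene)
    if (!length(idx)) stop(sprintf("gene_effect_spec names unknown gene '%s'", sp$gene),
                           call. = FALSE)
    dir_sign <- if (sp$direction == "risk") 1 else -1
    nonsyn <- idx[base$consequence[idx] %in%
                    c("protein_truncating", "missense", "splice")]
    if (sp$architecture == "null") next
    g <- match(sp$gene, gene_truth$gene)
    gene_truth$architecture[g] <- sp$architecture
    gene_truth$direction[g] <- sp$direction
    gene_truth$carrier_freq[g] <- sp$carrier_freq
    if (sp$architecture == "single_driver") {
      if (!length(nonsyn)) stop(sprintf("gene '%s' has no nonsynonymous variant to drive",
                                        sp$gene), call. = FALSE)
      driver <- nonsyn[which.max(maf[nonsyn])]
      maf[driver] <- sp$carrier_freq / 2   # one low-frequency driver allele
      beta[driver] <- dir_sign * abs(stats::rnorm(1, sp$beta_mean, sp$beta_sd))
      next
    }
    ## allelic series / mixed direction: rescale the qualifying rare alleles
    ## so their aggregate carrier frequency (~ sum of 2*MAF) hits the target
    qual <- nonsyn[maf[nonsyn] < .maf_bins$rare[2]]
    if (!length(qual)) qual <- nonsyn
    if (!length(qual)) next
    max_agg <- 2 * length(qual) * .maf_bins$rare[2]
    if (sp$carrier_freq > max_agg) {
      stop(sprintf("gene '%s': aggregate carrier frequency %.4g infeasible for %d variants",
                   sp$gene, sp$carrier_freq, length(qual)), call. = FALSE)
    }
    scale <- sp$carrier_freq / sum(2 * maf[qual])
    maf[qual] <- pmin(maf[qual] * scale, 0.5)
    b <- abs(stats::rnorm(length(qual), sp$beta_mean, sp$beta_sd))
    signs <- if (sp$architecture == "mixed_direction") {
      rep_len(c(1, -1), length(qual))
    } else rep(dir_sign, length(qual))
    beta[qual] <- signs * b
  }
  base$maf <- maf
  base$beta <- beta
  list(base = base, gene_truth = gene_truth)
}

## Sparse pool genotypes: per variant draw Hardy-Weinberg genotype counts,
## then place carriers uniformly; memory scales with carrier count.
simulate_pool_genotypes <- function(n, maf) {
  V <- length(maf)
  ii <- vector("list", V); xx <- vector("list", V)
  for (j in seq_len(V)) {
    q <- maf[j]
    cnt <- stats::rmultinom(1L, n, c((1 - q)^2, 2 * q * (1 - q), q^2))
    ncar <- cnt[2L] + cnt[3L]
    if (ncar == 0L) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
    who <- sample.int(n, ncar)
    ii[[j]] <- who
    xx[[j]] <- c(rep(1, cnt[2L]), rep(2, cnt[3L]))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = rep(seq_len(V), lengths(ii)),
                       x = unlist(xx), dims = c(n, V))
}

calibrate_intercept <- function(eta, K) {
  f <- function(a) mean(expit(a + eta)) - K
  stats::uniroot(f, lower = -30, upper = 10, tol = 1e-10)$root
}

#' Simulate a seeded case-control exome cohort
#'
#' Generates per-transcript variant annotations, Hardy-Weinberg genotypes for
#' a large unascertained population pool, disease status from a logistic
#' model whose per-subgroup intercepts are calibrated so the expected
#' population prevalence equals K, and then samples the requested case and
#' control counts. Covariates comprise ancestry-informative
#' principal-component-like axes and a body-mass-index-like measure with a
#' modest effect on risk. Missing genotypes are injected completely at
#' random. Deterministic given the seed; independent named substreams are
#' used for annotations, genotypes, phenotypes, and missingness.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `"cohort_bundle"`: a list with elements
#'   `samples` (data frame: `sample_id`, `subgroup`, `ancestry`, `status`,
#'   `PC1`--`PC10`, `BMI`), `genotypes` (list: sparse `dosage` matrix,
#'   sparse `missing` indicator, `sample_ids`, `variant_ids`),
#'   `annotations` (per-variant, per-transcript-set table), `truth`
#'   (per-variant `beta`/`maf` and per-gene architecture), and `meta`
#'   (pool size and realized pool prevalence before ascertainment).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed

  ann <- with_substream(seed, "annotations", {
    a <- simulate_annotations(config)
    eff <- apply_gene_effects(a$base, config)
    list(annotations = a$annotations, base = eff$base, gene_truth = eff$gene_truth)
  })
  base <- ann$base
  ## transcript-level table shares the per-variant fields with the base table
  annotations <- ann$annotations
  annotations$maf <- base$maf[match(annotations$variant_id, base$variant_id)]

  n_req <- config$n_cases + config$n_controls
  n_pool <- min(config$pool_multiplier * n_req, config$pool_cap)

  G <- with_substream(seed, "genotypes", simulate_pool_genotypes(n_pool, base$maf))

  pheno <- with_substream(seed, "phenotypes", {
    subgroup <- sample.int(config$n_subgroups, n_pool, replace = TRUE)
    ancestry <- ceiling(subgroup * config$n_ancestries / config$n_subgroups)
    pc_shift <- matrix(stats::rnorm(config$n_ancestries * 10, 0, 1.5),
                       config$n_ancestries, 10)
    pcs <- pc_shift[ancestry, , drop = FALSE] + matrix(stats::rnorm(n_pool * 10), n_pool, 10)
    colnames(pcs) <- paste0("PC", 1:10)
    bmi <- stats::rnorm(n_pool, 28, 5)
    eta <- as.numeric(G %*% base$beta) + 0.05 * pcs[, 1] + 0.02 * (bmi - 28)
    alpha <- numeric(config$n_subgroups)
    for (s in seq_len(config$n_subgroups)) {
      alpha[s] <- calibrate_intercept(eta[subgroup == s], config$prevalence)
    }
    status <- stats::rbinom(n_pool, 1L, expit(alpha[subgroup] + eta))
    list(subgroup = subgroup, ancestry = ancestry, pcs = pcs, bmi = bmi,
         status = status, alpha = alpha)
  })

  pool_prev <- mean(pheno$status)
  cases <- which(pheno$status == 1L)
  controls <- which(pheno$status == 0L)
  if (length(cases) < config$n_cases || length(controls) < config$n_controls) {
    stop(sprintf("pool of %d yielded %d cases / %d controls; requested %d / %d",
                 n_pool, length(cases), length(controls),
                 config$n_cases, config$n_controls), call. = FALSE)
  }
  keep <- with_substream(seed, "ascertainment", {
    c(sample(cases, config$n_cases), sample(controls, config$n_controls))
  })

  dosage <- G[keep, , drop = FALSE]
  n <- length(keep)
  samples <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                        subgroup = pheno$subgroup[keep],
                        ancestry = pheno$ancestry[keep],
                        status = pheno$status[keep],
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(pheno$pcs[keep, , drop = FALSE]))
  samples$BMI <- pheno$bmi[keep]

  missing <- with_substream(seed, "missingness", {
    rate <- config$missing_rate *
      config$missing_subgroup_multiplier[samples$subgroup]
    n_miss <- stats::rbinom(1L, n * nrow(base), mean(rate))
    if (n_miss == 0L) {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = dim(dosage))
    } else {
      ## cell sampling weighted by the per-sample differential rate
      i <- sample.int(n, n_miss, replace = TRUE, prob = rate)
      j <- sample.int(nrow(base), n_miss, replace = TRUE)
      dup <- duplicated(cbind(i, j))
      Matrix::sparseMatrix(i = i[!dup], j = j[!dup], x = 1, dims = dim(dosage))
    }
  })

  truth_var <- data.frame(variant_id = base$variant_id, gene = base$gene,
                          maf = base$maf, beta = base$beta,
                          consequence = base$consequence,
                          stringsAsFactors = FALSE)
  structure(list(
    samples = samples,
    genotypes = list(dosage = dosage, missing = missing,
                     sample_ids = samples$sample_id,
                     variant_ids = base$variant_id),
    annotations = annotations,
    truth = list(variants = truth_var, genes = ann$gene_truth),
    meta = list(pool_size = n_pool, pool_prevalence = pool_prev,
                prevalence = config$prevalence, seed = seed,
                subgroup_intercepts = pheno$alpha)
  ), class = "cohort_bundle")
}

#' Summarize the empirical allele-frequency spectrum of a cohort
#'
#' @param bundle A [simulate_cohort()] result.
#' @return Named numeric: fractions of common, low-frequency, and rare
#'   variants by true simulated MAF.
#' @export
maf_spectrum_summary <- function(bundle) {
  b <- table(maf_bin(bundle$truth$variants$maf))
  p <- as.numeric(b / sum(b))
  names(p) <- names(b)
  p[c("common", "low", "rare")]
}

#' Simulate replication summary statistics for every discovery variant
#'
#' Draws replication-study effect estimates around the same true per-variant
#' effects recorded in the bundle's truth table, with sampling standard
#' errors appropriate to the replication sample size (allele-count
#' approximation for a log odds ratio). Null variants are therefore
#' direction-concordant with any discovery estimate with probability 1/2.
#'
#' @param bundle A [simulate_cohort()] result (must carry a truth table).
#' @param n_cases,n_controls Replication sample sizes.
#' @param seed Integer seed for the replication substream.
#' @return Data frame: `variant_id`, `beta`, `se`, `p`, `direction`.
#' @export
simulate_replication <- function(bundle, n_cases, n_controls, seed = 1L) {
  if (is.null(bundle$truth)) stop("bundle has no truth table", call. = FALSE)
  if (n_cases <= 0 || n_controls <= 0) {
    stop("replication sample sizes must be positive", call. = FALSE)
  }
  tv <- bundle$truth$variants
  se <- replication_se(tv$maf, n_cases, n_controls)
  with_substream(seed, "replication", {
    beta_hat <- stats::rnorm(nrow(tv), tv$beta, se)
    data.frame(variant_id = tv$variant_id, beta = beta_hat, se = se,
               p = z_to_p(beta_hat / se), direction = sign(beta_hat),
               stringsAsFactors = FALSE)
  })
}

## Allele-count standard error of a log odds ratio at minor allele
## frequency q: sqrt(1/a + 1/b + 1/c + 1/d) with expected counts.
replication_se <- function(maf, n_cases, n_controls) {
  q <- pmin(pmax(maf, 1e-6), 0.5)
  sqrt(1 / (2 * n_cases * q) + 1 / (2 * n_cases * (1 - q)) +
         1 / (2 * n_controls * q) + 1 / (2 * n_controls * (1 - q)))
}
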