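#' Construct matched comparison genes for a gene set
#'
#' For each gene in the set, samples up to `ratio` universe genes without
#' replacement from the same matching bin -- log2 of the qualifying-variant
#' count (bin width 1) crossed with log10 of the aggregate variant
#' frequency (bin width 0.5) -- so the comparison genes share the set's
#' variant-count and frequency profile. When a bin is exhausted the nearest
#' non-empty bin is used with a warning (disable via `fallback = FALSE`).
#'
#' @param set_genes Character vector of set gene ids.
#' @param universe Data frame with `gene`, `n_variants`, `aggregate_freq`
#'   (see [gene_universe()]).
#' @param ratio Target matched genes per set gene (default 50).
#' @param seed Integer seed; matching is deterministic given it.
#' @param fallback Allow nearest-bin fallback for exhausted bins.
#' @param bin_widths Widths of the log2 count and log10 frequency bins.
#' @return List of class `"matched_comparison"`: `set_genes`,
#'   `matched_genes`, `bins` (the per-gene bin labels), `n_fallback`.
#' @export
match_genes <- function(set_genes, universe, ratio = 50L, seed = 1L,
                        fallback = TRUE, bin_widths = c(1, 0.5)) {
  set_genes <- unique(set_genes)
  missing <- setdiff(set_genes, universe$gene)
  if (length(missing)) {
    stop(sprintf("set gene '%s' absent from universe", missing[1]), call. = FALSE)
  }
  if (nrow(universe) < ratio * length(set_genes)) {
    stop("universe smaller than ratio x set size", call. = FALSE)
  }
  cbin <- floor(log2(pmax(universe$n_variants, 1)) / bin_widths[1])
  fbin <- floor(log10(pmax(universe$aggregate_freq, 1e-8)) / bin_widths[2])
  bin <- paste(cbin, fbin, sep = "/")
  names(bin) <- universe$gene
  pool <- setdiff(universe$gene, set_genes)
  matched <- character(0)
  n_fallback <- 0L
  with_substream(seed, "match_genes", {
    for (g in set_genes) {
      want <- bin[g]
      avail <- setdiff(pool[bin[pool] == want], matched)
      if (length(avail) < ratio) {
        if (!fallback && length(avail) == 0L) {
          stop(sprintf("no match available in bin %s for gene %s", want, g),
               call. = FALSE)
        }
        ## nearest-bin fallback: widen by euclidean distance in bin space
        if (length(avail) < ratio && fallback) {
          n_fallback <- n_fallback + 1L
          warning(sprintf("bin %s exhausted for gene %s; using nearest bins",
                          want, g), call. = FALSE)
          tgt <- as.numeric(strsplit(want, "/", fixed = TRUE)[[1]])
          rest <- setdiff(pool, c(matched, avail))
          bb <- do.call(rbind, strsplit(bin[rest], "/", fixed = TRUE))
          d <- (as.numeric(bb[, 1]) - tgt[1])^2 + (as.numeric(bb[, 2]) - tgt[2])^2
          rest <- rest[order(d)]
          avail <- c(avail, rest[seq_len(min(ratio - length(avail), length(rest)))])
        }
      }
      take <- min(ratio, length(avail))
      matched <- c(matched, sample(avail, take))
    }
  })
  structure(list(set_genes = set_genes, matched_genes = matched,
                 bins = bin, n_fallback = n_fallback,
                 covariates = c("log2 variant count", "log10 aggregate frequency")),
            class = "matched_comparison")
}

## Exact one-sided rank-sum tail by complete enumeration of label
## assignments; feasible for both groups <= 10.
rank_sum_exact <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  W_obs <- sum(r[seq_along(x)])
  idx <- utils::combn(length(all_v), length(x))
  W_all <- colSums(matrix(r[idx], nrow = length(x)))
  mean(W_all >= W_obs - 1e-12)
}

#' One-sided rank-sum enrichment test for a gene set
#'
#' Tests whether set genes have more significant gene-level associations
#' (smaller P values, that is higher significance ranks) than their matched
#' comparison genes. Midranks for ties; normal approximation with
#' continuity correction, or complete enumeration when both groups have at
#' most `exact_limit` members. Genes with missing statistics are dropped
#' from both sides.
#'
#' @param set_p Gene-level P values (burden minimum-P statistic) for the
#'   set genes.
#' @param matched_p P values for the matched genes.
#' @param exact_limit Enumeration threshold per group (default 10).
#' @return List: one-sided `p`, `n_set`, `n_matched`, `method`.
#' @export
rank_sum_enrichment <- function(set_p, matched_p, exact_limit = 10L) {
  set_p <- set_p[is.finite(set_p)]
  matched_p <- matched_p[is.finite(matched_p)]
  if (!length(set_p) || !length(matched_p)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ## higher rank = more significant: work on -log(p) so "greater" is enrichment
  xs <- -log(set_p); ys <- -log(matched_p)
  if (length(xs) <= exact_limit && length(ys) <= exact_limit) {
    p <- rank_sum_exact(xs, ys)
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(xs, ys, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation"
  }
  list(p = p, n_set = length(xs), n_matched = length(ys), method = method)
}

#' One-sided exact binomial test of direction-of-effect concordance
#'
#' Probability of observing at least `successes` concordant directions out
#' of `trials` under chance concordance `null_p`:
#' `P = sum_{k >= successes} C(trials, k) null_p^k (1 - null_p)^(trials-k)`.
#'
#' @param successes Number of concordant results.
#' @param trials Number of comparisons (>= 1).
#' @param null_p Chance concordance probability (default 0.5).
#' @return The one-sided exact binomial P value.
#' @export
direction_concordance_test <- function(successes, trials, null_p = 0.5) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials) {
    stop("successes must lie in 0..trials", call. = FALSE)
  }
  stats::pbinom(successes - 1, trials, null_p, lower.tail = FALSE)
}

#' Concordance of gene-level odds ratios with expected directions
#'
#' A gene is concordant when its expected direction is `risk` and the
#' gene-level odds ratio exceeds 1, or `protective` and the odds ratio is
#' below 1. Ties (odds ratio exactly 1) are excluded with a warning, as are
#' genes appearing in two sets with opposite expectations.
#'
#' @param gene_results Data frame with `gene` and a log odds ratio column
#'   `effect` (for example the weighted burden effect).
#' @param expectations Data frame with `gene` and `direction`
#'   (`"risk"`/`"protective"`; `"unknown"` rows are dropped).
#' @return List: per-gene concordance table, `successes`, `trials`, and
#'   the one-sided binomial `p`.
#' @export
direction_expectation_report <- function(gene_results, expectations) {
  expectations <- expectations[expectations$direction %in% c("risk", "protective"), ,
                               drop = FALSE]
  dup <- expectations$gene[duplicated(expectations$gene)]
  opposite <- unique(expectations$gene[expectations$gene %in% dup])
  opposite <- opposite[vapply(opposite, function(g) {
    length(unique(expectations$direction[expectations$gene == g])) > 1L
  }, logical(1))]
  if (length(opposite)) {
    expectations <- expectations[!expectations$gene %in% opposite, , drop = FALSE]
  }
  tab <- merge(expectations, gene_results[, c("gene", "effect")], by = "gene")
  tab <- tab[is.finite(tab$effect), , drop = FALSE]
  ties <- tab$effect == 0
  if (any(ties)) {
    warning(sprintf("%d gene(s) with odds ratio exactly 1 excluded", sum(ties)),
            call. = FALSE)
    tab <- tab[!ties, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no estimable genes after exclusions", call. = FALSE)
  tab$concordant <- (tab$direction == "risk" & tab$effect > 0) |
    (tab$direction == "protective" & tab$effect < 0)
  k <- sum(tab$concordant); n <- nrow(tab)
  list(table = tab, successes = k, trials = n,
       p = direction_concordance_test(k, n))
}

#' Matched-gene set enrichment report
#'
#' Convenience wrapper chaining [match_genes()] and
#' [rank_sum_enrichment()] over a scan result.
#'
#' @param set_genes Character vector of set gene ids.
#' @param scan A [gene_scan()] result.
#' @param ratio,seed Passed to [match_genes()].
#' @return List combining the matching and the enrichment test.
#' @export
gene_set_report <- function(set_genes, scan, ratio = 50L, seed = 1L) {
  uni <- gene_universe(scan)
  uni <- uni[is.finite(uni$p), , drop = FALSE]
  mc <- match_genes(set_genes, uni, ratio = ratio, seed = seed)
  pv <- stats::setNames(uni$p, uni$gene)
  enr <- rank_sum_enrichment(pv[mc$set_genes], pv[mc$matched_genes])
  c(list(matched = mc), enr)
}
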