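#!/usr/bin/env Rscript

## Stage 4 — gene-set enrichment and direction-of-effect concordance.
##
## Builds a "candidate" set from the planted non-null genes plus a few
## decoys (emulating a curated disease gene set of mixed quality), matches
## comparison genes on variant count and aggregate frequency, runs the
## one-sided rank-sum enrichment, and evaluates concordance between
## estimated and expected effect directions with the one-sided exact
## binomial test. Writes results/gene_sets.tsv and
## results/direction_concordance.tsv.

source("analysis/config.R")
bundle <- study_cohort()
scan <- read.delim("results/gene_level.tsv", na.strings = ".")

truth <- bundle$truth$genes
planted <- truth[truth$architecture != "null", ]
set.seed(4)
decoys <- sample(setdiff(truth$gene, planted$gene), 4)
candidate_set <- c(planted$gene, decoys)

report <- gene_set_report(candidate_set, scan, ratio = 30, seed = 44L)
null_set <- sample(setdiff(truth$gene, candidate_set), 8)
report_null <- gene_set_report(null_set, scan, ratio = 30, seed = 45L)
tab <- data.frame(set = c("candidate", "random"),
                  n_set = c(report$n_set, report_null$n_set),
                  n_matched = c(report$n_matched, report_null$n_matched),
                  p = c(report$p, report_null$p))
write.table(tab, "results/gene_sets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("candidate set enrichment: one-sided rank-sum P = %.3g (%d set vs %d matched genes)",
                report$p, report$n_set, report$n_matched))
message(sprintf("random set control: P = %.3g", report_null$p))

## direction-of-effect concordance for genes with a declared direction
expect <- planted[!is.na(planted$direction) &
                    planted$architecture != "mixed_direction",
                  c("gene", "direction")]
res <- data.frame(gene = scan$gene, effect = scan$effect_burden)
conc <- direction_expectation_report(res, expect)
write.table(conc$table, "results/direction_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("direction concordance: %d/%d, one-sided binomial P = %.3g",
                conc$successes, conc$trials, conc$p))
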