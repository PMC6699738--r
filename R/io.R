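#' Write a cohort bundle to disk
#'
#' Writes genotypes as VCF v4.2 (one biallelic record per variant, GT
#' field, 1-based positions, `./.` for missing), the sample table, the
#' per-transcript annotation table, and the truth tables as TSV.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_vcf(bundle, paths["vcf"])
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE, na = ".")
  wt(bundle$samples, paths["samples"])
  wt(bundle$annotations, paths["annotations"])
  wt(bundle$truth$variants, paths["truth_variants"])
  wt(bundle$truth$genes, paths["truth_genes"])
  invisible(paths)
}

write_vcf <- function(bundle, path) {
  ids <- bundle$genotypes$variant_ids
  parts <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  D <- as.matrix(bundle$genotypes$dosage)
  M <- as.matrix(bundle$genotypes$missing) > 0
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1L], nrow = nrow(D))
  gt[M] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rvassoc",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", bundle$genotypes$sample_ids),
                     collapse = "\t")), con)
  body <- paste(parts[, 1], parts[, 2], ids, parts[, 3], parts[, 4], ".",
                "PASS", ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes back from a cohort VCF
#'
#' Round-trip reader for [write_cohort()] output: parses the VCF with
#' `vcfR`, converts GT calls to a sparse dosage matrix, and records
#' missing calls separately.
#'
#' @param path VCF path.
#' @return List: sparse `dosage`, sparse `missing`, `sample_ids`,
#'   `variant_ids` (matching the cohort-bundle genotype component).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  dos <- matrix(0, ncol(gt), nrow(gt))
  miss <- matrix(FALSE, ncol(gt), nrow(gt))
  code <- function(x) {
    d <- rep(NA_integer_, length(x))
    d[x %in% c("0/0", "0|0")] <- 0L
    d[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[x %in% c("1/1", "1|1")] <- 2L
    d
  }
  d <- code(as.vector(gt))
  dm <- matrix(d, nrow(gt), ncol(gt))
  dos <- t(ifelse(is.na(dm), 0L, dm))
  miss <- t(is.na(dm))
  list(dosage = Matrix::Matrix(dos, sparse = TRUE),
       missing = Matrix::Matrix(miss * 1, sparse = TRUE),
       sample_ids = colnames(gt), variant_ids = unname(ids))
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `cohort_bundle` (without the generator's `meta` element).
#' @export
read_cohort <- function(dir) {
  rt <- function(p) utils::read.delim(p, stringsAsFactors = FALSE, na.strings = ".")
  g <- read_cohort_vcf(file.path(dir, "genotypes.vcf"))
  structure(list(
    samples = rt(file.path(dir, "samples.tsv")),
    genotypes = g,
    annotations = rt(file.path(dir, "annotations.tsv")),
    truth = list(variants = rt(file.path(dir, "truth_variants.tsv")),
                 genes = rt(file.path(dir, "truth_genes.tsv"))),
    meta = list()
  ), class = "cohort_bundle")
}
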