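#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: simulation
#' parameters (or input paths), covariates, stage toggles, thresholds,
#' stratum boundaries, and seeds. Serializable to/from YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param simulation A [simulation_config()] (used when no `cohort_dir`).
#' @param cohort_dir Optional directory of a cohort written by
#'   [write_cohort()]; overrides simulation.
#' @param covariate_cols Sample-table covariate columns.
#' @param adjust_bmi Add the body-mass-index covariate to gene-level tests.
#' @param stages Character subset of
#'   `c("simulate", "single_variant", "gene_level", "gene_sets", "lve_power",
#'   "ppa")`.
#' @param gene_sets Named list of character vectors of gene ids (optional).
#' @param replication List with `n_cases`, `n_controls` for the synthetic
#'   replication study used by the PPA stage.
#' @param threshold Exome-wide gene significance threshold.
#' @param ppa_thresholds Discovery P strata for the PPA stage.
#' @param fraction_causal Causal-fraction grid.
#' @param seed Master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = simulation_config(n_cases = 1000,
                                                           n_controls = 1000,
                                                           n_genes = 200),
                            cohort_dir = NULL,
                            covariate_cols = c("PC1", "PC2"),
                            adjust_bmi = FALSE,
                            stages = c("simulate", "single_variant", "gene_level",
                                       "gene_sets", "lve_power", "ppa"),
                            gene_sets = NULL,
                            replication = list(n_cases = 25000, n_controls = 25000),
                            threshold = bonferroni_threshold(),
                            ppa_thresholds = c(5e-4, 5e-3, 0.05, 0.5, 1),
                            fraction_causal = c(0.25, 0.40, 0.55),
                            seed = 1L) {
  structure(list(out_dir = out_dir, simulation = simulation,
                 cohort_dir = cohort_dir, covariate_cols = covariate_cols,
                 adjust_bmi = adjust_bmi, stages = stages,
                 gene_sets = gene_sets, replication = replication,
                 threshold = threshold, ppa_thresholds = ppa_thresholds,
                 fraction_causal = fraction_causal, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  x$simulation$gene_effect_specs <- lapply(x$simulation$gene_effect_specs, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- lapply(x$simulation$gene_effect_specs, function(s) {
    do.call(gene_effect_spec, s)
  })
  sim <- x$simulation
  sim$gene_effect_specs <- specs
  sim$maf_spectrum <- as.numeric(sim$maf_spectrum)
  x$simulation <- do.call(simulation_config, sim)
  do.call(pipeline_config, x[setdiff(names(x), character(0))])
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] %s (%.1f s)", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end -- simulate (or load) the cohort,
#' single-variant scan with meta-analysis, gene-level scan, gene-set
#' enrichment, LVE/power planning, and PPA calibration against a synthetic
#' replication study -- writing one TSV per stage plus a manifest
#' (configuration hash, seed, package version) under `config$out_dir`.
#' Reruns with the same configuration are byte-identical; stage failures
#' abort with the failing stage named.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  outputs <- list()
  wt <- function(x, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    p
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(NULL)
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    stage_log(stage, t0)
    res
  }

  bundle <- if (!is.null(config$cohort_dir)) {
    read_cohort(config$cohort_dir)
  } else {
    run_stage("simulate", function() {
      b <- simulate_cohort(config$simulation)
      write_cohort(b, file.path(config$out_dir, "cohort"))
      b
    })
  }
  if (is.null(bundle)) {
    ## nothing enabled beyond the manifest
    write_manifest(config)
    return(invisible(outputs))
  }
  outputs$cohort <- bundle

  outputs$single_variant <- run_stage("single_variant", function() {
    sv <- sv_scan(bundle, covariate_cols = config$covariate_cols)
    wt(sv, "single_variant")
    sv
  })

  outputs$gene_level <- run_stage("gene_level", function() {
    gs <- gene_scan(bundle, covariate_cols = config$covariate_cols,
                    adjust_bmi = config$adjust_bmi,
                    threshold = config$threshold)
    wt(gs, "gene_level")
    gs
  })

  if (!is.null(outputs$gene_level)) {
    outputs$gene_sets <- run_stage("gene_sets", function() {
      sets <- config$gene_sets
      if (is.null(sets)) {
        truth <- bundle$truth$genes
        nonnull <- truth$gene[truth$architecture != "null"]
        if (length(nonnull) >= 2) sets <- list(simulated_true = nonnull)
      }
      if (is.null(sets)) return(NULL)
      rows <- lapply(names(sets), function(nm) {
        r <- tryCatch(gene_set_report(sets[[nm]], outputs$gene_level,
                                      ratio = min(50L, floor(nrow(outputs$gene_level) /
                                                               length(sets[[nm]])) - 1L),
                                      seed = substream_seed(config$seed, nm)),
                      error = function(e) NULL)
        if (is.null(r)) return(NULL)
        data.frame(set = nm, n_set = r$n_set, n_matched = r$n_matched,
                   p = r$p, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      if (!is.null(tab)) wt(tab, "gene_sets")
      tab
    })

    outputs$lve_power <- run_stage("lve_power", function() {
      gl <- outputs$gene_level
      gl <- gl[is.finite(gl$p_burden_minp) & is.finite(gl$effect_burden) &
                 gl$carrier_freq > 0, , drop = FALSE]
      gl <- gl[order(gl$p_burden_minp), , drop = FALSE]
      lve <- mapply(function(f, b) {
        tryCatch(lve_gene(min(f / 2, 0.5), exp(b)), error = function(e) NA_real_)
      }, gl$carrier_freq, gl$effect_burden)
      tab <- data.frame(gene = gl$gene, rank = seq_len(nrow(gl)),
                        p = gl$p_burden_minp, or = exp(gl$effect_burden),
                        aggregate_freq = gl$carrier_freq, lve = lve)
      wt(tab, "lve")
      pw <- data.frame(
        n_cases = c(6504, 21400), n_controls = c(6436, 21400),
        power = c(power_case_control(6504, 6436, 0.002, 2.5),
                  power_case_control(21400, 21400, 0.002, 2.5)))
      wt(pw, "power")
      list(lve = tab, power = pw)
    })
  }

  outputs$ppa <- run_stage("ppa", function() {
    sv <- outputs$single_variant
    if (is.null(sv)) return(NULL)
    rep_stats <- simulate_replication(bundle, config$replication$n_cases,
                                      config$replication$n_controls,
                                      seed = substream_seed(config$seed, "replication"))
    disc <- data.frame(variant_id = sv$variant_id, beta = sv$effect,
                       se = sv$se, p = sv$p, direction = sv$direction)
    disc <- disc[stats::complete.cases(disc), , drop = FALSE]
    cal <- tryCatch(
      ppa_calibration(disc, rep_stats, thresholds = config$ppa_thresholds,
                      fraction_causal = config$fraction_causal,
                      seed = config$seed),
      error = function(e) NULL)
    if (!is.null(cal)) wt(cal$table, "ppa_calibration")
    cal
  })

  write_manifest(config)
  invisible(outputs)
}

write_manifest <- function(config) {
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  hash <- sum(utf8ToInt(paste(readLines(cfg_path), collapse = "\n")) *
                (seq_along(utf8ToInt(paste(readLines(cfg_path), collapse = "\n"))) %% 997))
  manifest <- c(sprintf("config_hash: %d", hash),
                sprintf("seed: %d", config$seed),
                sprintf("package_version: %s",
                        as.character(utils::packageVersion("rvassoc"))),
                sprintf("stages: %s", paste(config$stages, collapse = ",")))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(NULL)
}
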