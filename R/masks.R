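#' Define a variant severity mask
#'
#' A mask is a rule selecting the qualifying variants of a gene for
#' aggregate testing, by predicted consequence severity, number of damaging
#' in-silico predictor calls, and minor allele frequency.
#'
#' @param name Mask name (for example `"1/5 1%"`).
#' @param consequences Qualifying consequence classes.
#' @param min_damaging Minimum number of damaging predictor calls (0--5)
#'   required of missense/splice variants; protein-truncating variants are
#'   exempt from the predictor predicate.
#' @param maf_ceiling Strict MAF upper bound in (0, 0.05], or `NULL` for none.
#' @param require_hc_ptv If `TRUE`, protein-truncating variants qualify only
#'   when flagged high-confidence.
#' @return An object of class `"mask_definition"`.
#' @export
mask_definition <- function(name, consequences, min_damaging = 0L,
                            maf_ceiling = NULL, require_hc_ptv = TRUE) {
  if (min_damaging < 0 || min_damaging > 5) {
    stop("min_damaging must lie in 0..5", call. = FALSE)
  }
  if (!is.null(maf_ceiling) && (maf_ceiling <= 0 || maf_ceiling > 0.05)) {
    stop("maf_ceiling must lie in (0, 0.05]", call. = FALSE)
  }
  bad <- setdiff(consequences, .consequences)
  if (length(bad)) stop(sprintf("unknown consequence class: %s", bad[1]), call. = FALSE)
  structure(list(name = name, consequences = consequences,
                 min_damaging = as.integer(min_damaging),
                 maf_ceiling = maf_ceiling, require_hc_ptv = require_hc_ptv),
            class = "mask_definition")
}

#' Default set of seven severity masks
#'
#' Reconstructed nested defaults running from high-confidence
#' protein-truncating variants only (the strictest) through all
#' nonsynonymous variants under a frequency ceiling. The exact mask
#' membership rules of published studies vary and are often defined in
#' supplementary material; these defaults are stand-ins with the same
#' naming convention ("x/5 y%" = at least x of 5 damaging predictor calls,
#' MAF below y%) and are fully overridable via [mask_definition()].
#'
#' @return Named list of [mask_definition()] objects.
#' @export
default_masks <- function() {
  ns <- c("protein_truncating", "missense", "splice")
  list(
    `PTV`       = mask_definition("PTV", "protein_truncating"),
    `5/5`       = mask_definition("5/5", ns, min_damaging = 5L),
    `5/5 1%`    = mask_definition("5/5 1%", ns, min_damaging = 5L, maf_ceiling = 0.01),
    `1/5 1%`    = mask_definition("1/5 1%", ns, min_damaging = 1L, maf_ceiling = 0.01),
    `0/5 1%`    = mask_definition("0/5 1%", ns, min_damaging = 0L, maf_ceiling = 0.01),
    `1/5 0.1%`  = mask_definition("1/5 0.1%", ns, min_damaging = 1L, maf_ceiling = 0.001),
    `0/5 0.5%`  = mask_definition("0/5 0.5%", ns, min_damaging = 0L, maf_ceiling = 0.005)
  )
}

mask_predicate <- function(ann, def) {
  ok <- ann$consequence %in% def$consequences
  is_ptv <- ann$consequence == "protein_truncating"
  if (def$require_hc_ptv) {
    ok <- ok & (!is_ptv | (!is.na(ann$ptv_confidence) & ann$ptv_confidence == "high"))
  }
  if (def$min_damaging > 0L) {
    ncalls <- rowSums(as.matrix(ann[, paste0("pred", 1:5)]))
    ok <- ok & (is_ptv | ncalls >= def$min_damaging)
  }
  if (!is.null(def$maf_ceiling)) ok <- ok & ann$maf < def$maf_ceiling
  ok
}

check_variant_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop(sprintf("malformed variant id '%s' (expect chrom:pos:ref:alt)",
                 ids[bad][1]), call. = FALSE)
  }
  alt <- vapply(parts, `[[`, character(1), 4L)
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multiallelic records must be decomposed to biallelic before masking",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign variants to severity masks per gene and transcript set
#'
#' A variant enters the grouping for a gene, transcript set, and mask iff
#' its annotation on that transcript set satisfies every predicate of the
#' mask definition. Pure function of its inputs: idempotent and independent
#' of row order.
#'
#' @param annotations Per-variant, per-transcript-set annotation table
#'   (columns `variant_id`, `gene`, `transcript_set`, `consequence`,
#'   `ptv_confidence`, `pred1`--`pred5`, `maf`).
#' @param defs List of [mask_definition()] objects (default
#'   [default_masks()]).
#' @return Data frame of groupings: `gene`, `transcript_set`, `mask`, and a
#'   list-column `variants` of qualifying variant ids (position order).
#'   Empty groupings are not emitted.
#' @export
assign_masks <- function(annotations, defs = default_masks()) {
  if (!nrow(annotations)) stop("empty annotation table", call. = FALSE)
  if (!length(defs)) stop("no mask definitions supplied", call. = FALSE)
  bad <- setdiff(unique(annotations$consequence), .consequences)
  if (length(bad)) stop(sprintf("unknown consequence class '%s'", bad[1]), call. = FALSE)
  check_variant_ids(unique(annotations$variant_id))
  ann <- annotations[order(annotations$gene, annotations$transcript_set,
                           annotations$pos, annotations$variant_id), ]
  out <- list()
  for (def in defs) {
    ok <- mask_predicate(ann, def)
    sub <- ann[ok, c("gene", "transcript_set", "variant_id")]
    if (!nrow(sub)) next
    key <- paste(sub$gene, sub$transcript_set, sep = "\r")
    sp <- split(sub$variant_id, key)
    ks <- strsplit(names(sp), "\r", fixed = TRUE)
    out[[def$name]] <- data.frame(
      gene = vapply(ks, `[[`, character(1), 1L),
      transcript_set = as.integer(vapply(ks, `[[`, character(1), 2L)),
      mask = def$name, stringsAsFactors = FALSE
    )
    out[[def$name]]$variants <- unname(lapply(sp, unique))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$mask, res$transcript_set), , drop = FALSE]
}

#' Collapse identical transcript-set groupings
#'
#' For many genes two or more transcript sets yield identical allele
#' groupings under a mask; these are collapsed to a single grouping and the
#' multiplicity recorded, so downstream minimum-P consolidation does not
#' multiple-count duplicates.
#'
#' @param groupings Output of [assign_masks()] for one gene (any number of
#'   masks).
#' @return The deduplicated groupings with a `multiplicity` column and a
#'   list-column `transcript_sets` of the sets collapsed into each row.
#' @export
collapse_transcript_sets <- function(groupings) {
  if (length(unique(groupings$gene)) > 1L) {
    stop("collapse_transcript_sets expects groupings from one gene", call. = FALSE)
  }
  keys <- vapply(groupings$variants,
                 function(v) paste(sort(v), collapse = ";"), character(1))
  out <- list()
  for (m in unique(groupings$mask)) {
    idx <- which(groupings$mask == m)
    first <- idx[!duplicated(keys[idx])]
    for (f in first) {
      same <- idx[keys[idx] == keys[f]]
      row <- groupings[f, , drop = FALSE]
      row$multiplicity <- length(same)
      row$transcript_sets <- list(groupings$transcript_set[same])
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export mask groupings as a flat table
#'
#' @param groupings Output of [assign_masks()].
#' @param path Optional TSV path; when given the table is written there.
#' @return Data frame with `variants` flattened to a comma-separated column.
#' @export
groupings_table <- function(groupings, path = NULL) {
  flat <- groupings
  flat$variants <- vapply(groupings$variants, paste, character(1), collapse = ",")
  if (!is.null(path)) {
    utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  flat
}
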