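#' Triage one patient's variants into a diagnostic outcome
#'
#' Converts per-variant ACMG pathogenicity classes (P, LP, VUS, LB, B —
#' supplied as annotations by an upstream curation pipeline) into a
#' positive/negative genetic diagnosis, requiring consistency between the
#' variant's inheritance call and the gene's OMIM inheritance models.  A
#' patient is positive iff they carry:
#' \itemize{
#'   \item a P/LP small variant in a gene with a dominant or X-linked
#'     model compatible with the variant's inheritance call, or
#'   \item two P/LP alleles of a recessive gene (homozygous, or a
#'     compound-heterozygous pair of P/LP alleles), or
#'   \item a P/LP copy-number variant overlapping a catalog gene.
#' }
#' A lone heterozygous P/LP allele in a recessive-only gene is negative
#' with rationale `single_allele_ar_insufficient`; variants of uncertain
#' significance never contribute (`vus_only` when they are all the
#' patient has).  An unresolved inheritance mode (uncertain/assumed) does
#' not block positivity: several diagnostic variants in real cohorts are
#' reported with uncertain inheritance.
#'
#' @param variants this patient's annotated small variants with columns
#'   `gene`, `acmg_class`, `proband_gt`, `mode`, `models`, `assumed`,
#'   `comp_het_partner`, `chrom`, `pos`, `ref`, `alt`.
#' @param cnvs this patient's CNV calls with columns `chrom`, `start`,
#'   `end`, `type`, `gene`, `acmg_class` (may be empty).
#' @param catalog candidate-gene catalog with OMIM models.
#' @return list: `status` (`positive`/`negative`), `causal_variants`
#'   (character vector of variant keys, empty when negative),
#'   `rationale` (one of `plp_consistent`, `single_allele_ar_insufficient`,
#'   `vus_only`, `no_candidate`).
#' @export
triage_patient <- function(variants, cnvs = NULL, catalog) {
  if (nrow(variants)) {
    bad <- setdiff(unique(variants$acmg_class), ACMG_CLASSES)
    if (length(bad)) {
      crs_abort(sprintf("unknown pathogenicity class token: %s",
                        paste(bad, collapse = ", ")),
                "crstrio_input_error")
    }
  }
  causal <- character(0)
  saw_single_ar <- FALSE
  plp <- variants[variants$acmg_class %in% c("P", "LP"), , drop = FALSE]
  if (nrow(plp)) {
    keys <- variant_key(plp$chrom, plp$pos, plp$ref, plp$alt)
    gm <- catalog_models(catalog, unique(plp$gene))
    for (i in seq_len(nrow(plp))) {
      models_gene <- gm[[plp$gene[i]]]
      if (!length(models_gene)) next   # gene unknown to the catalog
      dominant_gene <- length(intersect(models_gene, c("AD", "XLD"))) > 0
      # XLR genes take a single allele only when it is effectively
      # hemizygous or the inheritance could not be resolved
      xlr_ok <- "XLR" %in% models_gene &&
        (plp$mode[i] %in% c("hemizygous_maternal", "uncertain") ||
           isTRUE(plp$assumed[i]) || plp$proband_gt[i] == "1/1")
      if (dominant_gene || xlr_ok) {
        causal <- c(causal, keys[i])
        next
      }
      # recessive-only gene: need two alleles
      if ("AR" %in% models_gene) {
        if (plp$proband_gt[i] == "1/1") {
          causal <- c(causal, keys[i])
        } else if (!is.na(plp$comp_het_partner[i])) {
          partner <- match(plp$comp_het_partner[i], keys)
          if (!is.na(partner) &&
                plp$acmg_class[partner] %in% c("P", "LP")) {
            causal <- c(causal, keys[i])
          } else {
            saw_single_ar <- TRUE
          }
        } else {
          saw_single_ar <- TRUE
        }
      }
    }
  }
  if (!is.null(cnvs) && nrow(cnvs)) {
    plp_cnv <- cnvs[cnvs$acmg_class %in% c("P", "LP"), , drop = FALSE]
    for (i in seq_len(nrow(plp_cnv))) {
      if (!is.null(catalog_lookup(catalog, plp_cnv$gene[i]))) {
        causal <- c(causal, sprintf("%s:%d-%d:%s", plp_cnv$chrom[i],
                                    plp_cnv$start[i], plp_cnv$end[i],
                                    plp_cnv$type[i]))
      }
    }
  }
  causal <- unique(causal)
  if (length(causal)) {
    return(list(status = "positive", causal_variants = causal,
                rationale = "plp_consistent"))
  }
  rationale <- if (saw_single_ar) {
    "single_allele_ar_insufficient"
  } else if (nrow(variants) && any(variants$acmg_class == "VUS")) {
    "vus_only"
  } else {
    "no_candidate"
  }
  list(status = "negative", causal_variants = character(0),
       rationale = rationale)
}

#' Triage a whole two-stage cohort
#'
#' Applies [triage_patient()] stage-wise: every patient is first
#' evaluated on panel-stage variants; panel-negative patients who were
#' enrolled for exome sequencing are then evaluated on their WES-stage
#' variants and CNV calls; panel-negative patients never exome-sequenced
#' are counted as not tested beyond the panel.
#'
#' @param variants cohort variant table (with `patient_id`, `stage`
#'   column valued `panel`/`wes`, and the triage columns of
#'   [triage_patient()]).
#' @param cnvs cohort CNV table with `patient_id` (WES stage).
#' @param patients patient table with `patient_id`, `wes_enrolled`
#'   (logical).
#' @param catalog candidate-gene catalog.
#' @return list with `outcomes` (data.frame: `patient_id`, `stage`
#'   (`panel`/`wes`/`none`), `status`, `causal_variants` (comma string),
#'   `causal_genes`, `rationale`) and `tallies` (named list:
#'   `panel_positive`, `wes_positive`, `both_negative`, `not_tested`).
#' @export
triage_cohort <- function(variants, cnvs, patients, catalog) {
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    pv <- variants[variants$patient_id == pid, , drop = FALSE]
    panel_res <- triage_patient(pv[pv$stage == "panel", , drop = FALSE],
                                NULL, catalog)
    if (panel_res$status == "positive") {
      res <- panel_res; stage <- "panel"
    } else if (isTRUE(patients$wes_enrolled[i])) {
      res <- triage_patient(pv[pv$stage == "wes", , drop = FALSE],
                            cnvs[cnvs$patient_id == pid, , drop = FALSE],
                            catalog)
      stage <- if (res$status == "positive") "wes" else "none"
    } else {
      res <- list(status = "negative", causal_variants = character(0),
                  rationale = "no_candidate")
      stage <- "none"
    }
    genes <- character(0)
    if (length(res$causal_variants)) {
      pv_keys <- variant_key(pv$chrom, pv$pos, pv$ref, pv$alt)
      genes <- pv$gene[match(res$causal_variants, pv_keys)]
      if (anyNA(genes)) {  # CNV keys resolve through the CNV table
        cn <- cnvs[cnvs$patient_id == pid, , drop = FALSE]
        cn_keys <- sprintf("%s:%d-%d:%s", cn$chrom, cn$start, cn$end, cn$type)
        genes[is.na(genes)] <-
          cn$gene[match(res$causal_variants[is.na(genes)], cn_keys)]
      }
      genes <- unique(genes)
    }
    out[[i]] <- data.frame(
      patient_id = pid, stage = stage, status = res$status,
      causal_variants = paste(res$causal_variants, collapse = ","),
      causal_genes = paste(genes, collapse = ","),
      rationale = res$rationale, stringsAsFactors = FALSE
    )
  }
  outcomes <- do.call(rbind, out)
  if (is.null(outcomes)) {
    outcomes <- data.frame(patient_id = character(0), stage = character(0),
                           status = character(0),
                           causal_variants = character(0),
                           causal_genes = character(0),
                           rationale = character(0), stringsAsFactors = FALSE)
  }
  tallies <- list(
    panel_positive = sum(outcomes$stage == "panel" &
                           outcomes$status == "positive"),
    wes_positive = sum(outcomes$stage == "wes" &
                         outcomes$status == "positive"),
    both_negative = sum(outcomes$status == "negative" &
                          patients$wes_enrolled[match(outcomes$patient_id,
                                                      patients$patient_id)]),
    # lost to follow-up after a negative panel: panel-negative, never exomed
    not_tested = sum(outcomes$status == "negative" &
                       !patients$wes_enrolled[match(outcomes$patient_id,
                                                    patients$patient_id)])
  )
  list(outcomes = outcomes, tallies = tallies)
}
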