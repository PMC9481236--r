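#' Research-pipeline filter thresholds
#'
#' Thresholds for the two-part candidate-variant discovery pipeline.
#' Part one keeps loss-of-function variants plus scored protein-altering
#' variants (deleterious score >= `ds_min` or CADD >= `cadd_min`) and then
#' applies inheritance-model-specific allele-frequency cuts: under a
#' dominant (or de novo) evaluation the variant must be at or below
#' `af_ad_gnomad` in gnomAD and `af_ad_huabiao` in the Huabiao cohort;
#' under a recessive or X-linked evaluation the recessive thresholds
#' apply.  Part two keeps the top `rank_max` phenotype-prioritized
#' variants per proband.  All comparisons are inclusive.
#'
#' The dominant defaults (5e-5 gnomAD, 5e-4 Huabiao) correspond to allele
#' counts of about 20 in 141,456 gnomAD samples and 5 in ~5,000 Huabiao
#' samples; the recessive defaults scale both up by the same factor used
#' between the two databases and are configurable because recessive
#' carrier alleles tolerate higher population frequencies.
#'
#' @param cadd_min minimum CADD for a scored protein-altering variant.
#' @param ds_min minimum deleterious score (integer predictor summary).
#' @param af_ad_gnomad,af_ad_huabiao dominant-model frequency ceilings.
#' @param af_recessive_gnomad,af_recessive_huabiao recessive/X-linked
#'   frequency ceilings.
#' @param rank_max prioritizer rank ceiling ("top 20").
#' @return a `crs_thresholds` list.
#' @export
filter_thresholds <- function(cadd_min = 20, ds_min = 4,
                              af_ad_gnomad = 0.00005,
                              af_ad_huabiao = 0.0005,
                              af_recessive_gnomad = 0.001,
                              af_recessive_huabiao = 0.005,
                              rank_max = 20) {
  afs <- c(af_ad_gnomad, af_ad_huabiao, af_recessive_gnomad,
           af_recessive_huabiao)
  if (any(afs < 0 | afs > 1)) {
    crs_abort("allele-frequency thresholds must lie in [0, 1]",
              "crstrio_config_error")
  }
  if (rank_max < 1) crs_abort("rank_max must be >= 1", "crstrio_config_error")
  if (ds_min < 0) crs_abort("ds_min must be >= 0", "crstrio_config_error")
  structure(list(
    cadd_min = cadd_min, ds_min = ds_min,
    af_ad_gnomad = af_ad_gnomad, af_ad_huabiao = af_ad_huabiao,
    af_recessive_gnomad = af_recessive_gnomad,
    af_recessive_huabiao = af_recessive_huabiao,
    rank_max = rank_max
  ), class = "crs_thresholds")
}

#' Functional-consequence filter (part one, first stage)
#'
#' Retains loss-of-function variants (frameshift, nonsense, splicing)
#' unconditionally, and protein-altering variants that carry predicted
#' deleteriousness (missense and in-frame indels with deleterious score
#' >= `ds_min` or CADD >= `cadd_min`).  All other consequence classes
#' (synonymous, intronic, UTR, intergenic, noncoding) are removed.
#' In-frame indels are scored like missense variants: they alter the
#' protein without truncating it, and diagnostic in-frame deletions would
#' otherwise be invisible to a pure LoF-plus-missense rule.
#'
#' @param variants variant table with columns `functional_class`, `cadd`,
#'   `ds` (scores may be `NA` for non-missense classes).
#' @param thresholds a [filter_thresholds()] object.
#' @return the retained rows.
#' @export
functional_filter <- function(variants, thresholds = filter_thresholds()) {
  unknown <- setdiff(unique(variants$functional_class), FUNCTIONAL_CLASSES)
  if (length(unknown)) {
    crs_abort(sprintf("unknown functional class token: %s",
                      paste(unknown, collapse = ", ")),
              "crstrio_input_error")
  }
  lof <- variants$functional_class %in% LOF_CLASSES
  scored <- variants$functional_class %in% c("missense", "inframe_indel")
  ds_ok <- !is.na(variants$ds) & variants$ds >= thresholds$ds_min
  cadd_ok <- !is.na(variants$cadd) & variants$cadd >= thresholds$cadd_min
  variants[lof | (scored & (ds_ok | cadd_ok)), , drop = FALSE]
}

# map genetic models to the threshold regime they use
model_regime <- function(model) {
  ifelse(model %in% c("AD", "XLD"), "dominant", "recessive")
}

#' Inheritance-model-aware allele-frequency filter (part one, second stage)
#'
#' Evaluates each variant under every genetic model in its `models`
#' column (comma-separated subset of AD, AR, XLD, XLR, as assigned by
#' [assign_inheritance_table()]); a variant is retained when it survives
#' the frequency ceilings of at least one model, and the surviving models
#' are recorded in `surviving_models`.  Dominant-type models (AD, XLD)
#' use the dominant ceilings, recessive-type models (AR, XLR) the
#' recessive ceilings, in both gnomAD (`af_gnomad`) and Huabiao
#' (`af_huabiao`).  Absent frequencies are treated as 0 (never observed).
#'
#' @param variants variant table with columns `af_gnomad`, `af_huabiao`,
#'   `models`.
#' @param thresholds a [filter_thresholds()] object.
#' @return retained rows with an added `surviving_models` column.
#' @export
frequency_filter <- function(variants, thresholds = filter_thresholds()) {
  afg <- variants$af_gnomad
  afh <- variants$af_huabiao
  afg[is.na(afg)] <- 0
  afh[is.na(afh)] <- 0
  if (any(afg < 0 | afg > 1 | afh < 0 | afh > 1)) {
    crs_abort("allele frequency outside [0, 1]", "crstrio_input_error")
  }
  model_list <- split_tags(variants$models)
  surv <- vapply(seq_len(nrow(variants)), function(i) {
    ms <- model_list[[i]]
    ok <- vapply(ms, function(m) {
      if (model_regime(m) == "dominant") {
        afg[i] <= thresholds$af_ad_gnomad && afh[i] <= thresholds$af_ad_huabiao
      } else {
        afg[i] <= thresholds$af_recessive_gnomad &&
          afh[i] <= thresholds$af_recessive_huabiao
      }
    }, logical(1))
    paste(ms[ok], collapse = ",")
  }, character(1))
  variants$surviving_models <- surv
  variants[nzchar(surv), , drop = FALSE]
}

#' Prioritizer rank filter (part two)
#'
#' Keeps variants whose phenotype-driven prioritizer rank (e.g. an
#' Exomiser hiPhive rank, supplied as an input column, one ranking per
#' proband across all genes) is at most `rank_max`.  Variants without a
#' rank are removed from part two; they can still reach the final set
#' only through no route (the intersection requires both parts).
#'
#' @param variants variant table with an `exomiser_rank` column.
#' @param rank_max rank ceiling, inclusive ("top 20").
#' @return retained rows.
#' @export
rank_filter <- function(variants, rank_max = 20) {
  keep <- !is.na(variants$exomiser_rank) & variants$exomiser_rank <= rank_max
  variants[keep, , drop = FALSE]
}

#' Intersect the two pipeline parts
#'
#' Exact set intersection on `(patient_id, variant key)`.
#'
#' @param part1,part2 variant tables carrying `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @return the rows of `part1` whose keys also appear in `part2`.
#' @export
intersect_parts <- function(part1, part2) {
  k1 <- paste(part1$patient_id,
              variant_key(part1$chrom, part1$pos, part1$ref, part1$alt))
  k2 <- paste(part2$patient_id,
              variant_key(part2$chrom, part2$pos, part2$ref, part2$alt))
  part1[k1 %in% k2, , drop = FALSE]
}

# models a variant can actually satisfy given its inheritance resolution:
# a resolved single het cannot satisfy a recessive model on its own, but a
# comp-het partner, a hom-biparental genotype, a hemizygous male X call or
# an assumed (proband-only / unresolved) call can.
effective_models <- function(mode, models, assumed, has_partner, proband_gt) {
  ms <- models
  if (!assumed && is.na(has_partner) && mode %in%
        c("de_novo", "paternal", "maternal") && proband_gt == "0/1") {
    ms <- setdiff(ms, c("AR", "XLR"))
  }
  ms
}

#' Candidate-gene and OMIM-model concordance filter
#'
#' Retains variants whose gene is in the candidate catalog and whose
#' surviving genetic models intersect the gene's OMIM inheritance models.
#' A resolved single heterozygous allele cannot satisfy a recessive-only
#' gene (one allele is not a recessive genotype) unless it is half of a
#' compound-heterozygous pair; assumed calls (proband-only cases) are
#' given the benefit of the doubt.  Compound-heterozygous pairs are kept
#' or dropped as a unit.  Genes absent from the catalog (after synonym
#' normalisation) count as non-hits.
#'
#' @param variants variant table with inheritance and `surviving_models`
#'   columns (see [frequency_filter()]).
#' @param catalog a [build_catalog()] catalog.
#' @return `variants` with logical columns `catalog_hit` and
#'   `omim_model_match` appended; rows are not removed (the caller
#'   combines flags), but `omim_model_match` is only `TRUE` where
#'   `catalog_hit` is.
#' @export
catalog_and_model_match <- function(variants, catalog) {
  n <- nrow(variants)
  variants$catalog_hit <- logical(n)
  variants$omim_model_match <- logical(n)
  if (!n) return(variants)
  gene_models <- catalog_models(catalog, unique(variants$gene))
  hit <- vapply(unique(variants$gene),
                function(g) !is.null(catalog_lookup(catalog, g)), logical(1))
  surv <- split_tags(variants$surviving_models)
  for (i in seq_len(n)) {
    g <- variants$gene[i]
    variants$catalog_hit[i] <- hit[[g]]
    if (!hit[[g]]) next
    gm <- gene_models[[g]]
    eff <- effective_models(variants$mode[i], surv[[i]],
                            isTRUE(variants$assumed[i]),
                            variants$comp_het_partner[i],
                            variants$proband_gt[i])
    variants$omim_model_match[i] <- length(intersect(eff, gm)) > 0
  }
  # comp-het pairs live or die together: a partner that fails drags the
  # mate down with it
  vkey <- paste(variants$patient_id,
                variant_key(variants$chrom, variants$pos,
                            variants$ref, variants$alt))
  paired <- which(!is.na(variants$comp_het_partner))
  if (length(paired)) {
    pkey <- paste(variants$patient_id[paired], variants$comp_het_partner[paired])
    pidx <- match(pkey, vkey)
    ok <- variants$omim_model_match[paired] &
      ifelse(is.na(pidx), FALSE, variants$omim_model_match[pidx])
    variants$omim_model_match[paired] <- ok
  }
  variants
}

#' Run the two-part research pipeline
#'
#' Part one applies the functional-consequence filter and the
#' model-aware allele-frequency filter; part two applies the same
#' frequency filter to the phenotype-prioritized ranking and keeps the
#' top `rank_max` variants per proband; the two parts are intersected,
#' then candidate-gene membership and OMIM inheritance-model concordance
#' are required.  A final manual-review stand-in flags (but does not
#' silently delete) variants classified likely benign/benign and variants
#' in genes on the review exclusion list (by default `APC`, whose disease
#' association is oncological rather than skeletal).
#'
#' @param variants annotated proband variant table after QC and
#'   inheritance assignment (see [assign_inheritance_table()]); small
#'   variants only.
#' @param catalog candidate-gene catalog.
#' @param thresholds a [filter_thresholds()] object.
#' @param review_exclude_genes character vector of genes removed at the
#'   manual review stage.
#' @return the input table with provenance columns `passed_part1`,
#'   `passed_part2`, `catalog_hit`, `omim_model_match`,
#'   `excluded_on_review`, and `final`; `final` implies all four pass
#'   flags and no review exclusion.
#' @export
run_research_pipeline <- function(variants, catalog,
                                  thresholds = filter_thresholds(),
                                  review_exclude_genes = "APC") {
  v <- variants
  p1 <- functional_filter(v, thresholds)
  p1 <- frequency_filter(p1, thresholds)
  p2 <- frequency_filter(v, thresholds)
  p2 <- rank_filter(p2, thresholds$rank_max)
  inter <- intersect_parts(p1, p2)

  vk <- paste(v$patient_id, variant_key(v$chrom, v$pos, v$ref, v$alt))
  k1 <- paste(p1$patient_id, variant_key(p1$chrom, p1$pos, p1$ref, p1$alt))
  k2 <- paste(p2$patient_id, variant_key(p2$chrom, p2$pos, p2$ref, p2$alt))
  v$passed_part1 <- vk %in% k1
  v$passed_part2 <- vk %in% k2
  v$surviving_models <- ""
  v$surviving_models[match(k1, vk)] <- p1$surviving_models
  # part-2-only survivors still carry their surviving models forward
  only2 <- setdiff(k2, k1)
  v$surviving_models[match(only2, vk)] <- p2$surviving_models[match(only2, k2)]

  v <- catalog_and_model_match(v, catalog)
  v$excluded_on_review <- (!is.na(v$acmg_class) &
                             v$acmg_class %in% c("LB", "B")) |
    v$gene %in% review_exclude_genes
  v$final <- v$passed_part1 & v$passed_part2 & v$catalog_hit &
    v$omim_model_match & !v$excluded_on_review
  # comp-het unit rule also applies to the final flag
  paired <- which(!is.na(v$comp_het_partner))
  if (length(paired)) {
    pidx <- match(paste(v$patient_id[paired], v$comp_het_partner[paired]), vk)
    v$final[paired] <- v$final[paired] &
      ifelse(is.na(pidx), FALSE,
             v$passed_part1[pidx] & v$passed_part2[pidx] &
               v$omim_model_match[pidx] & !v$excluded_on_review[pidx])
  }
  v
}
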