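#' Assign an inheritance call to a proband variant
#'
#' Maps proband and parental genotypes at one site to an inheritance mode
#' and the set of genetic models the observation is compatible with.
#' Modes: `de_novo`, `paternal`, `maternal`, `hom_biparental`, `comp_het`
#' (assigned later by [pair_compound_hets()]), `hemizygous_maternal`
#' (X-linked male probands) and `uncertain`.
#'
#' Rules, for autosomes:
#' \itemize{
#'   \item proband het, both parents hom-ref -> `de_novo`, models AD;
#'   \item proband het, exactly one parent carries the allele ->
#'     `paternal`/`maternal`, models AD (reduced penetrance) and AR
#'     (carrier allele awaiting a partner);
#'   \item proband hom-alt, both parents carriers -> `hom_biparental`,
#'     models AR;
#'   \item proband hom-alt with a hom-ref parent is a Mendelian
#'     inconsistency (possible after depth-ratio re-calling) ->
#'     `uncertain`, kept for review rather than discarded;
#'   \item any missing parental genotype (including proband-only cases)
#'     -> `uncertain`, with every model tagged as assumed.
#' }
#' On chromosome X, male probands carrying the alternative allele are
#' hemizygous: a carrier mother gives `hemizygous_maternal` (XLR), a
#' genotyped hom-ref mother gives `de_novo` (XLD/XLR); female probands
#' follow the autosomal shape with XLD/XLR in place of AD/AR.
#'
#' @param proband_gt,father_gt,mother_gt genotype strings (`0/0`, `0/1`,
#'   `1/1`, `./.`); use `NA` for an unsequenced parent.
#' @param sex proband sex, `"male"` or `"female"`.
#' @param chromosome chromosome label; `"X"` (or `"chrX"`) triggers the
#'   X-linked rules.
#' @return list with `mode`, `models` (character vector), `assumed`
#'   (logical: models assumed rather than observed).
#' @export
assign_inheritance <- function(proband_gt, father_gt = NA, mother_gt = NA,
                               sex = "female", chromosome = "1") {
  if (is.na(proband_gt) || proband_gt == "./.") {
    crs_abort("proband genotype must be non-missing", "crstrio_input_error")
  }
  on_x <- sub("^chr", "", chromosome) == "X"
  male <- identical(sex, "male")
  fa_missing <- is.na(father_gt) || father_gt == "./."
  mo_missing <- is.na(mother_gt) || mother_gt == "./."

  if (proband_gt == "0/0") {
    return(list(mode = "uncertain", models = INHERITANCE_MODELS,
                assumed = TRUE))
  }

  carries <- function(gt) gt %in% c("0/1", "1/1")
  all_models <- if (on_x) c("XLD", "XLR") else INHERITANCE_MODELS

  if (on_x && male) {
    # hemizygous proband: father does not transmit X to a son
    if (mo_missing) {
      return(list(mode = "uncertain", models = c("XLD", "XLR"),
                  assumed = TRUE))
    }
    if (carries(mother_gt)) {
      return(list(mode = "hemizygous_maternal", models = "XLR",
                  assumed = FALSE))
    }
    return(list(mode = "de_novo", models = c("XLD", "XLR"), assumed = FALSE))
  }

  if (fa_missing || mo_missing) {
    return(list(mode = "uncertain", models = all_models, assumed = TRUE))
  }

  dom <- if (on_x) "XLD" else "AD"
  rec <- if (on_x) "XLR" else "AR"

  if (proband_gt == "0/1") {
    fa <- carries(father_gt)
    mo <- carries(mother_gt)
    if (!fa && !mo) {
      return(list(mode = "de_novo", models = dom, assumed = FALSE))
    }
    if (fa && !mo) {
      return(list(mode = "paternal", models = c(dom, rec), assumed = FALSE))
    }
    if (!fa && mo) {
      return(list(mode = "maternal", models = c(dom, rec), assumed = FALSE))
    }
    # both parents carry: transmitting parent unresolved
    return(list(mode = "uncertain", models = c(dom, rec), assumed = FALSE))
  }

  # proband 1/1
  if (carries(father_gt) && carries(mother_gt)) {
    return(list(mode = "hom_biparental", models = rec, assumed = FALSE))
  }
  # Mendelian inconsistency after re-calling: keep for review
  list(mode = "uncertain", models = all_models, assumed = TRUE)
}

#' Assign inheritance calls across a cohort variant table
#'
#' Joins the annotated proband variants with the QC'd family genotypes and
#' the pedigree, assigns one inheritance call per proband variant, then
#' pairs compound heterozygotes gene-wise.  Variants whose proband
#' genotype was re-called to hom-ref are dropped (the proband no longer
#' carries the allele).
#'
#' @param variants annotated variant table (one row per proband variant)
#'   with columns `patient_id`, `family_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`.
#' @param genotypes QC'd long genotype table (see [qc_genotypes()]).
#' @param pedigree 6-column pedigree data.frame (`family_id`, `sample_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`) with `0` for a missing
#'   parent.
#' @return `variants` with appended columns `proband_gt`, `mode`, `models`
#'   (comma string), `assumed`, `comp_het_partner` (variant key or `NA`),
#'   minus rows no longer carried by the proband.
#' @export
assign_inheritance_table <- function(variants, genotypes, pedigree) {
  if (!nrow(variants)) {
    variants$proband_gt <- character(0)
    variants$mode <- character(0)
    variants$models <- character(0)
    variants$assumed <- logical(0)
    variants$comp_het_partner <- character(0)
    return(variants)
  }
  ped_pro <- pedigree[pedigree$phenotype == 2, , drop = FALSE]
  ped_idx <- match(variants$patient_id, ped_pro$sample_id)
  if (any(is.na(ped_idx))) {
    crs_abort(sprintf("patient %s has no pedigree entry",
                      variants$patient_id[which(is.na(ped_idx))[1]]),
              "crstrio_pedigree_error")
  }
  gkey <- paste(genotypes$family_id, genotypes$sample_id,
                variant_key(genotypes$chrom, genotypes$pos,
                            genotypes$ref, genotypes$alt))
  gt_of <- function(family, sample, key) {
    if (is.na(sample) || sample == "0") return(NA_character_)
    i <- match(paste(family, sample, key), gkey)
    if (is.na(i)) NA_character_ else genotypes$gt[i]
  }
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  n <- nrow(variants)
  mode <- character(n); models <- character(n); assumed <- logical(n)
  proband_gt <- character(n)
  sex_lab <- ifelse(ped_pro$sex[ped_idx] == 1, "male", "female")
  for (i in seq_len(n)) {
    fam <- variants$family_id[i]
    pro <- variants$patient_id[i]
    p_gt <- gt_of(fam, pro, key[i])
    if (is.na(p_gt) || p_gt == "./.") {
      # proband call lost in QC; handled by caller via drop below
      proband_gt[i] <- NA_character_
      mode[i] <- NA_character_
      next
    }
    f_gt <- gt_of(fam, ped_pro$father_id[ped_idx[i]], key[i])
    m_gt <- gt_of(fam, ped_pro$mother_id[ped_idx[i]], key[i])
    call <- assign_inheritance(p_gt, f_gt, m_gt, sex_lab[i],
                               variants$chrom[i])
    proband_gt[i] <- p_gt
    mode[i] <- call$mode
    models[i] <- paste(call$models, collapse = ",")
    assumed[i] <- call$assumed
  }
  variants$proband_gt <- proband_gt
  variants$mode <- mode
  variants$models <- models
  variants$assumed <- assumed
  drop <- is.na(variants$proband_gt) | variants$proband_gt == "0/0"
  variants <- variants[!drop, , drop = FALSE]
  pairs <- pair_compound_hets(variants)
  variants$comp_het_partner <- NA_character_
  if (nrow(pairs)) {
    vkey <- paste(variants$patient_id,
                  variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt))
    for (j in seq_len(nrow(pairs))) {
      i1 <- match(paste(pairs$patient_id[j], pairs$key1[j]), vkey)
      i2 <- match(paste(pairs$patient_id[j], pairs$key2[j]), vkey)
      # a variant in several candidate pairs keeps its first partner key
      if (is.na(variants$comp_het_partner[i1]))
        variants$comp_het_partner[i1] <- pairs$key2[j]
      if (is.na(variants$comp_het_partner[i2]))
        variants$comp_het_partner[i2] <- pairs$key1[j]
    }
  }
  variants
}

#' Pair compound heterozygotes within genes
#'
#' Emits one pair for every combination of two distinct heterozygous
#' variants of the same gene in the same proband where one allele is of
#' paternal and the other of maternal origin (phase by transmission).  A
#' variant may take part in several candidate pairs; two variants
#' inherited from the same parent never pair.  Pairs carry model
#' compatibility AR.
#'
#' @param variants variant table with inheritance columns (`patient_id`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `proband_gt`, `mode`).
#' @return data.frame of pairs: `patient_id`, `gene`, `key1` (paternal),
#'   `key2` (maternal), `models` = `"AR"`.  Empty when no pair exists.
#' @export
pair_compound_hets <- function(variants) {
  empty <- data.frame(patient_id = character(0), gene = character(0),
                      key1 = character(0), key2 = character(0),
                      models = character(0), stringsAsFactors = FALSE)
  if (!nrow(variants)) return(empty)
  het <- variants[variants$proband_gt == "0/1" &
                    variants$mode %in% c("paternal", "maternal"), ,
                  drop = FALSE]
  if (!nrow(het)) return(empty)
  out <- list()
  grp <- split(seq_len(nrow(het)), paste(het$patient_id, het$gene))
  for (idx in grp) {
    pat <- idx[het$mode[idx] == "paternal"]
    mat <- idx[het$mode[idx] == "maternal"]
    if (!length(pat) || !length(mat)) next
    for (i in pat) {
      for (j in mat) {
        out[[length(out) + 1]] <- data.frame(
          patient_id = het$patient_id[i],
          gene = het$gene[i],
          key1 = variant_key(het$chrom[i], het$pos[i], het$ref[i], het$alt[i]),
          key2 = variant_key(het$chrom[j], het$pos[j], het$ref[j], het$alt[j]),
          models = "AR",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
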