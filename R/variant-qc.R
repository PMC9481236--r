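#' Depth filter for genotype calls
#'
#' Removes per-sample genotype calls whose total read depth is below
#' `min_depth` (default 10, i.e. calls with depth < 10 are dropped).  The
#' filter is applied per sample; use [qc_genotypes()] for the family-level
#' rule that drops a site for a whole family only when the proband fails.
#'
#' @param genotypes data.frame with at least columns `dp` (total depth)
#'   and `ad_alt` (alternative-allele depth).
#' @param min_depth minimum retained total depth (calls with
#'   `dp < min_depth` are removed).
#' @return list with `retained` (the surviving rows) and `removed` (the
#'   dropped rows with a `reason` column, `"low_depth"`).
#' @export
depth_filter <- function(genotypes, min_depth = 10) {
  check_depths(genotypes)
  drop <- genotypes$dp < min_depth
  removed <- genotypes[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "low_depth"
  else removed$reason <- character(0)
  list(
    retained = genotypes[!drop, , drop = FALSE],
    removed = removed
  )
}

check_depths <- function(genotypes) {
  if (any(is.na(genotypes$dp)) || any(genotypes$dp < 0)) {
    crs_abort("negative or missing total depth", "crstrio_input_error")
  }
  if (any(!is.na(genotypes$ad_alt) &
          (genotypes$ad_alt < 0 | genotypes$ad_alt > genotypes$dp))) {
    crs_abort("alternative-allele depth outside [0, dp]", "crstrio_input_error")
  }
  invisible(TRUE)
}

#' Re-call genotypes from the alternative-allele depth ratio
#'
#' Replaces each called genotype by the one implied by the depth ratio of
#' the alternative allele, DPRA = `ad_alt / dp`:
#' \itemize{
#'   \item DPRA < 0.3 -> `0/0` (homozygous reference)
#'   \item 0.3 <= DPRA <= 0.7 -> `0/1` (heterozygous)
#'   \item DPRA > 0.7 -> `1/1` (homozygous alternative)
#' }
#' Both boundaries are inclusive for the heterozygous state.  The
#' comparison is done in exact integer arithmetic (`10*ad_alt` against
#' `3*dp` and `7*dp`), so depths on the boundary such as 3/10 or 7/10 are
#' classified bit-stably with no floating-point rounding.  Missing
#' genotypes (`./.`) stay missing: the depth ratio is not used to
#' resurrect a no-call.  Depths are never modified.
#'
#' @param genotypes data.frame with columns `gt` (one of `0/0`, `0/1`,
#'   `1/1`, `./.`), `dp`, `ad_alt`.
#' @return the same data.frame with `gt` replaced by the recalibrated
#'   genotype.
#' @export
#' @examples
#' g <- data.frame(gt = c("0/1", "0/1", "0/1"), dp = c(10, 10, 10),
#'                 ad_alt = c(2, 3, 8))
#' recalibrate_genotype(g)$gt   # "0/0" "0/1" "1/1"
recalibrate_genotype <- function(genotypes) {
  check_depths(genotypes)
  called <- genotypes$gt != "./." & !is.na(genotypes$gt)
  if (any(called & genotypes$dp == 0)) {
    crs_abort("undefined depth ratio: called genotype with total depth 0",
              "crstrio_input_error")
  }
  ad10 <- 10 * genotypes$ad_alt
  new_gt <- ifelse(ad10 < 3 * genotypes$dp, "0/0",
                   ifelse(ad10 <= 7 * genotypes$dp, "0/1", "1/1"))
  genotypes$gt <- ifelse(called, new_gt, genotypes$gt)
  genotypes
}

#' Family-aware genotype quality control
#'
#' Runs the depth filter and then the depth-ratio genotype recalibration
#' over a long genotype table (one row per sample per site).  The depth
#' filter acts per sample; a site is dropped for an entire family only
#' when the proband's call fails it, so parental evidence with adequate
#' depth is kept for inheritance assignment even if one parent's call at
#' another site was shallow.
#'
#' @param genotypes long genotype table with columns `family_id`,
#'   `sample_id`, `role` (`proband`/`father`/`mother`), `chrom`, `pos`,
#'   `ref`, `alt`, `gt`, `dp`, `ad_alt`.
#' @param min_depth minimum retained total depth.
#' @return list with `genotypes` (the QC'd table) and `log` (data.frame of
#'   removed or re-called entries: variant key, sample, action, reason).
#' @export
qc_genotypes <- function(genotypes, min_depth = 10) {
  key <- variant_key(genotypes$chrom, genotypes$pos,
                     genotypes$ref, genotypes$alt)
  df <- depth_filter(genotypes, min_depth)
  kept <- df$retained
  log <- data.frame(
    key = variant_key(df$removed$chrom, df$removed$pos,
                      df$removed$ref, df$removed$alt),
    sample_id = df$removed$sample_id,
    action = rep("removed", nrow(df$removed)),
    reason = df$removed$reason,
    stringsAsFactors = FALSE
  )
  # drop the whole family's site when the proband call was removed
  failed_proband <- df$removed[df$removed$role == "proband", , drop = FALSE]
  if (nrow(failed_proband)) {
    fp_key <- paste(failed_proband$family_id,
                    variant_key(failed_proband$chrom, failed_proband$pos,
                                failed_proband$ref, failed_proband$alt))
    k_key <- paste(kept$family_id,
                   variant_key(kept$chrom, kept$pos, kept$ref, kept$alt))
    cascade <- k_key %in% fp_key
    if (any(cascade)) {
      log <- rbind(log, data.frame(
        key = variant_key(kept$chrom, kept$pos, kept$ref, kept$alt)[cascade],
        sample_id = kept$sample_id[cascade],
        action = "removed",
        reason = "proband_low_depth",
        stringsAsFactors = FALSE
      ))
      kept <- kept[!cascade, , drop = FALSE]
    }
  }
  old_gt <- kept$gt
  kept <- recalibrate_genotype(kept)
  changed <- which(old_gt != kept$gt)
  if (length(changed)) {
    log <- rbind(log, data.frame(
      key = variant_key(kept$chrom, kept$pos, kept$ref, kept$alt)[changed],
      sample_id = kept$sample_id[changed],
      action = "recalibrated",
      reason = sprintf("dpra:%s->%s", old_gt[changed], kept$gt[changed]),
      stringsAsFactors = FALSE
    ))
  }
  list(genotypes = kept, log = log)
}
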