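# Plain-text serialization of a cohort bundle: VCF 4.2 per family
# (FORMAT GT:DP:AD), 6-column PED, tab-separated patient/annotation/CNV
# tables, JSON spike-in manifest.  Reading goes through vcfR so the
# written VCFs are validated against a standard parser.

#' Write one family's genotypes as a VCF 4.2 file
#'
#' Emits a minimal VCF 4.2 with per-sample `GT:DP:AD` (AD as
#' `ref_depth,alt_depth`), one column per family member, sorted by
#' chromosome and position.
#'
#' @param genotypes long genotype table for one family (see
#'   [qc_genotypes()] for columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(genotypes, path) {
  fam <- unique(genotypes$family_id)
  if (length(fam) != 1) {
    crs_abort("write_family_vcf expects exactly one family",
              "crstrio_input_error")
  }
  samples <- unique(genotypes[, c("sample_id", "role")])
  samples <- samples[order(match(samples$role,
                                 c("proband", "father", "mother"))), ]
  sites <- unique(genotypes[, c("chrom", "pos", "ref", "alt")])
  sites <- sites[order(suppressWarnings(as.integer(sub("X", "23",
                                                       sites$chrom))),
                       sites$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crstrio",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  )
  gkey <- paste(genotypes$sample_id,
                variant_key(genotypes$chrom, genotypes$pos, genotypes$ref,
                            genotypes$alt))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    skey <- variant_key(sites$chrom[i], sites$pos[i], sites$ref[i],
                        sites$alt[i])
    cells <- vapply(samples$sample_id, function(s) {
      j <- match(paste(s, skey), gkey)
      if (is.na(j)) return("./.:.:.")
      sprintf("%s:%d:%d,%d", genotypes$gt[j], genotypes$dp[j],
              genotypes$dp[j] - genotypes$ad_alt[j], genotypes$ad_alt[j])
    }, character(1))
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:DP:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a family VCF back into the long genotype table
#'
#' Parses with vcfR and reconstructs the `family_id`/`role` columns from
#' the pedigree.
#'
#' @param path VCF file path.
#' @param pedigree pedigree table covering this family's samples.
#' @return long genotype table (see [qc_genotypes()]).
#' @export
read_family_vcf <- function(path, pedigree) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  rows <- lapply(seq_along(samples), function(j) {
    s <- samples[j]
    pi <- match(s, pedigree$sample_id)
    role <- if (pedigree$phenotype[pi] == 2) "proband"
      else if (pedigree$sex[pi] == 1) "father" else "mother"
    keep <- !is.na(gt[, j]) & gt[, j] != "./."
    if (!any(keep)) return(NULL)
    ad_alt <- vapply(strsplit(ad[keep, j], ",", fixed = TRUE),
                     function(x) as.integer(x[2]), integer(1))
    data.frame(
      family_id = pedigree$family_id[pi], sample_id = s, role = role,
      chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep], alt = fix$ALT[keep],
      gt = sub("|", "/", gt[keep, j], fixed = TRUE),
      dp = as.integer(dp[keep, j]), ad_alt = ad_alt,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_genotype_table() else out
}

#' Serialize a cohort bundle to a directory
#'
#' Writes `patients.tsv`, `pedigree.ped`, `annotations.tsv`, `cnvs.tsv`
#' (BED-like intervals), `manifest.json` and one VCF per family under
#' `vcf/`.  Identical bundles produce byte-identical output.
#'
#' @param bundle a `crs_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  wt(bundle$patients, "patients.tsv")
  utils::write.table(bundle$pedigree, file.path(dir, "pedigree.ped"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  wt(bundle$variants, "annotations.tsv")
  wt(bundle$cnvs, "cnvs.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (fam in unique(bundle$genotypes$family_id)) {
    g <- bundle$genotypes[bundle$genotypes$family_id == fam, , drop = FALSE]
    write_family_vcf(g, file.path(dir, "vcf", paste0(fam, ".vcf")))
  }
  invisible(dir)
}

#' Read a serialized cohort bundle
#'
#' Inverse of [write_cohort()]; genotypes are re-read from the per-family
#' VCFs through vcfR.
#'
#' @param dir directory written by [write_cohort()].
#' @return a `crs_cohort` bundle.
#' @export
read_cohort <- function(dir) {
  rt <- function(name, colClasses = NA) {
    utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE,
                      na.strings = ".", colClasses = colClasses)
  }
  patients <- rt("patients.tsv", colClasses = c(suture_type = "character"))
  ped <- utils::read.delim(file.path(dir, "pedigree.ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"))
  ped$father_id <- as.character(ped$father_id)
  ped$mother_id <- as.character(ped$mother_id)
  variants <- rt("annotations.tsv", colClasses = c(chrom = "character"))
  cnvs <- rt("cnvs.tsv", colClasses = c(chrom = "character"))
  manifest <- as.data.frame(jsonlite::read_json(file.path(dir,
                                                          "manifest.json"),
                                                simplifyVector = TRUE))
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg_raw$decoy_af_distribution <- as.list(cfg_raw$decoy_af_distribution)
  config <- do.call(cohort_config, cfg_raw)
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  genotypes <- do.call(rbind, lapply(vcfs, read_family_vcf, pedigree = ped))
  if (is.null(genotypes)) genotypes <- empty_genotype_table()
  structure(list(config = config, patients = patients, pedigree = ped,
                 variants = variants, genotypes = genotypes, cnvs = cnvs,
                 manifest = manifest),
            class = "crs_cohort")
}
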