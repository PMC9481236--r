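# Built-in spike-in payloads for the synthetic cohort generator.
#
# Coordinates (GRCh37), genes, consequence classes, inheritance labels,
# ACMG classes and — where available — CADD / deleterious score /
# prioritizer rank follow published craniosynostosis trio-exome case
# reports.  Values that the case reports do not print (population
# frequencies for all spike-ins; scores and ranks for the diagnostic P/LP
# set) are synthetic, chosen to be consistent with each variant's
# reported fate, and flagged in `scores_synthetic`.  Indel alleles use a
# synthetic anchor base in VCF left-aligned form.

#' Diagnostic P/LP spike-in payloads (exome stage)
#'
#' Seven small variants (four SNVs, three InDels) classified
#' pathogenic/likely pathogenic, carried by seven exome-stage patients.
#' Used by [generate_cohort()]; the companion CNV payloads are in
#' [cmm_positive_cnv_payloads()].
#'
#' @return data.frame, one row per variant.
#' @export
cmm_positive_small_payloads <- function() {
  df <- read_payload_rows(c(
    #pid  sex gr suture        po    kind  chrom pos       ref        alt  gene    transcript    class          inh       cadd ds af_g af_h rank acmg
    "W003|female|syndromic|Multiple|TRUE|indel|5|14716824|AGAA|A|ANKH|NM_054027|inframe_indel|uncertain|24.1|5|0|0|6|LP",
    "W007|female|syndromic|Uni/Bi-lambdoidal|FALSE|indel|6|26157051|TC|T|H1-4|NM_005321|frameshift|de_novo|NA|NA|0|0|3|LP",
    "W016|female|syndromic|Metopic|FALSE|snv|17|7214668|G|C|EIF5A|NM_001970|splicing|de_novo|NA|NA|0|0|2|LP",
    "W033|female|syndromic|Uni/Bi-coronal|FALSE|snv|3|147131159|C|T|ZIC1|NM_003412|nonsense|de_novo|36|8|0|0|1|P",
    "W072|male|nonsyndromic|Uni/Bi-lambdoidal|FALSE|snv|11|16077306|G|A|SOX6|NM_033326|nonsense|de_novo|38|8|0|0|1|P",
    "W083|female|nonsyndromic|Multiple|FALSE|snv|1|61553899|C|T|NFIA|NM_005595|nonsense|de_novo|35|7|0|0|1|P",
    "W097|male|syndromic|Sagittal|FALSE|indel|6|157431669|ACCAGTCA|A|ARID1B|NM_020732|frameshift|de_novo|NA|NA|0|0|2|P"
  ))
  df$expected_fate <- "cmm_positive"
  df$scores_synthetic <- TRUE
  df
}

#' Diagnostic P/LP CNV spike-in payloads (exome stage)
#'
#' Three heterozygous deletions spanning TWIST1, invisible to the small-
#' variant panel chemistry, classified pathogenic.
#'
#' @return data.frame, one row per CNV.
#' @export
cmm_positive_cnv_payloads <- function() {
  data.frame(
    patient_id = c("W026", "W034", "W053"),
    sex = c("female", "female", "female"),
    group = c("syndromic", "syndromic", "nonsyndromic"),
    suture_type = c("Multiple", "Uni/Bi-coronal", "Sagittal"),
    proband_only = c(FALSE, FALSE, TRUE),
    chrom = "7",
    start = c(16572119L, 16127149L, 18498464L),
    end = c(19185044L, 21956512L, 19185044L),
    type = "DEL",
    gene = "TWIST1",
    inheritance = c("de_novo", "de_novo", "uncertain"),
    acmg_class = "P",
    expected_fate = "cmm_positive",
    stringsAsFactors = FALSE
  )
}

#' Research-pipeline candidate spike-in payloads (exome stage)
#'
#' Fifteen variants of eleven candidate genes in thirteen exome-stage
#' patients, all classified VUS: eleven single-variant cases (five
#' autosomal with assumed dominant inheritance in proband-only cases, six
#' maternally inherited X-linked recessive in male trios) and two
#' compound-heterozygous pairs (IL11RA, DNAH11) with one paternal and one
#' maternal allele each.  CADD, deleterious score and prioritizer rank
#' are as reported; population frequencies are synthetic rare values
#' consistent with each variant's model-specific frequency filter fate.
#'
#' @return data.frame, one row per variant; `pair_id` groups the
#'   compound-heterozygous pairs.
#' @export
rp_candidate_payloads <- function() {
  df <- read_payload_rows(c(
    "W001|male|nonsyndromic|Sagittal|TRUE|snv|5|140966698|A|G|DIAPH1|NM_005219|missense|uncertain|22.9|5|0|0|1|VUS",
    "W008|male|nonsyndromic|Sagittal|FALSE|snv|X|79988961|C|G|BRWD3|NM_153252|missense|hemizygous_maternal|26.7|2|0|0|1|VUS",
    "W015|male|nonsyndromic|Sagittal|TRUE|snv|4|5798945|C|A|EVC|NM_153717|missense|uncertain|25.7|2|0|0|2|VUS",
    "W021|male|syndromic|Multiple|TRUE|snv|9|109688611|C|G|ZNF462|NM_021224|missense|uncertain|20.7|1|17|VUS",
    "W023|male|nonsyndromic|Uni/Bi-coronal|TRUE|snv|17|41833050|G|A|SOST|NM_025237|missense|uncertain|23.5|4|0|0|1|VUS",
    "W038|male|nonsyndromic|Sagittal|TRUE|snv|4|5733339|C|T|EVC|NM_153717|missense|uncertain|27.1|1|3|VUS",
    "W041|male|nonsyndromic|Uni/Bi-lambdoidal|FALSE|snv|X|50378636|C|A|SHROOM4|NM_020717|missense|hemizygous_maternal|33|4|18|VUS",
    "W043|male|nonsyndromic|Multiple|FALSE|snv|X|63410654|A|G|AMER1|NM_152424|missense|hemizygous_maternal|24.2|4|1|VUS",
    "W051|male|nonsyndromic|Sagittal|FALSE|snv|X|50345801|C|A|SHROOM4|NM_020717|missense|hemizygous_maternal|23.2|3|19|VUS",
    "W071|male|nonsyndromic|Sagittal|FALSE|snv|X|148037734|C|T|AFF2|NM_002025|missense|hemizygous_maternal|29.1|5|8|VUS",
    "W085|male|nonsyndromic|Sagittal|FALSE|snv|X|129149626|G|A|BCORL1|NM_021946|missense|hemizygous_maternal|21.2|2|7|VUS",
    "W093|female|nonsyndromic|Multiple|FALSE|snv|9|34658598|C|G|IL11RA|NM_001142784|missense|paternal|27.6|5|5|VUS",
    "W093|female|nonsyndromic|Multiple|FALSE|snv|9|34658577|T|C|IL11RA|NM_001142784|missense|maternal|27.4|5|5|VUS",
    "W095|male|syndromic|Sagittal|FALSE|snv|7|21726797|A|C|DNAH11|NM_001277115|missense|paternal|25.1|6|1|VUS",
    "W095|male|syndromic|Sagittal|FALSE|snv|7|21639655|T|C|DNAH11|NM_001277115|missense|maternal|24.8|3|1|VUS"
  ))
  df$expected_fate <- "rp_candidate"
  df$scores_synthetic <- FALSE
  # comp-het carrier alleles sit below the recessive-model frequency
  # ceilings but (for IL11RA) above the dominant ones, exercising the
  # model-specific thresholds
  comp_het <- df$gene %in% c("IL11RA", "DNAH11")
  df$af_gnomad[df$gene == "IL11RA"] <- 1e-4
  df$af_huabiao[df$gene == "IL11RA"] <- 2e-4
  df$pair_id <- ifelse(comp_het, df$gene, NA_character_)
  df
}

#' Potentially pathogenic (non-diagnostic) spike-in payloads
#'
#' Variants noticed by the curation pipeline but not diagnostic: a single
#' paternally inherited LP frameshift allele that cannot satisfy the
#' recessive-only inheritance of CDC45, and a de novo nonsense variant of
#' SNRPB classified VUS (phenotype fit judged insufficient).  Coordinates
#' and scores are synthetic; fates follow the reported reasoning.
#'
#' @return data.frame, one row per variant.
#' @export
potentially_pathogenic_payloads <- function() {
  df <- read_payload_rows(c(
    "W030|male|syndromic|Multiple|FALSE|indel|22|19479152|C|CT|CDC45|NM_003504|frameshift|paternal|NA|NA|0|0|4|LP",
    "W019|female|syndromic|Uni/Bi-coronal|FALSE|snv|20|2461572|G|A|SNRPB|NM_003091|nonsense|de_novo|38.0|8|0|0|25|VUS"
  ))
  df$expected_fate <- "potentially_pathogenic"
  df$scores_synthetic <- TRUE
  df
}

#' Review-excluded spike-in payload
#'
#' A rare deleterious APC missense variant that survives every automatic
#' filter but is removed at the manual review stage because APC's disease
#' association is oncological; it exercises the review-exclusion flag.
#' Entirely synthetic.
#'
#' @return one-row data.frame.
#' @export
review_excluded_payloads <- function() {
  df <- read_payload_rows(c(
    "W101|male|syndromic|Uncertain|FALSE|snv|5|112175211|G|A|APC|NM_000038|missense|paternal|28.3|6|0|0|2|VUS"
  ))
  df$expected_fate <- "decoy"
  df$scores_synthetic <- TRUE
  df
}

# parse the compact pipe-separated payload rows above
read_payload_rows <- function(rows) {
  parts <- strsplit(rows, "|", fixed = TRUE)
  full <- lapply(parts, function(p) {
    # rows omitting the two frequency fields default them to 0
    if (length(p) == 18) p <- c(p[1:16], "0", "0", p[17:18])
    p
  })
  stopifnot(all(lengths(full) == 20))
  m <- do.call(rbind, full)
  df <- data.frame(
    patient_id = m[, 1], sex = m[, 2], group = m[, 3], suture_type = m[, 4],
    proband_only = as.logical(m[, 5]), kind = m[, 6], chrom = m[, 7],
    pos = as.integer(m[, 8]), ref = m[, 9], alt = m[, 10], gene = m[, 11],
    transcript = m[, 12], functional_class = m[, 13], inheritance = m[, 14],
    cadd = suppressWarnings(as.numeric(m[, 15])),
    ds = suppressWarnings(as.integer(m[, 16])),
    af_gnomad = as.numeric(m[, 17]), af_huabiao = as.numeric(m[, 18]),
    exomiser_rank = as.integer(m[, 19]), acmg_class = m[, 20],
    stringsAsFactors = FALSE
  )
  df
}

# all spike-in small-variant payloads in one table
all_small_payloads <- function() {
  dfs <- list(cmm_positive_small_payloads(), rp_candidate_payloads(),
              potentially_pathogenic_payloads(), review_excluded_payloads())
  dfs <- lapply(dfs, function(d) {
    if (!"pair_id" %in% names(d)) d$pair_id <- NA_character_
    d
  })
  do.call(rbind, dfs)
}
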