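# Shared fixtures: the default-condition workflow run is computed once
# per test session and reused across files.

.crstrio_cache <- new.env(parent = emptyenv())

default_workflow <- function() {
  if (is.null(.crstrio_cache$wf)) {
    .crstrio_cache$wf <- run_cohort_workflow(cohort_config(seed = 1))
  }
  .crstrio_cache$wf
}

default_cohort <- function() default_workflow()$bundle

builtin_catalog <- function() {
  if (is.null(.crstrio_cache$catalog)) {
    .crstrio_cache$catalog <- crs_builtin_catalog()
  }
  .crstrio_cache$catalog
}

# a tiny catalog built from temp files, for unit tests
tiny_catalog <- function(entries) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  path <- file.path(dir, "genes.tsv")
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  build_catalog(c(test = path))
}

# one annotated variant row with sensible defaults, for triage/pipeline
# unit tests
variant_row <- function(patient_id = "PT1", chrom = "1", pos = 1000L,
                        ref = "A", alt = "G", gene = "GENE1",
                        functional_class = "missense", cadd = 25,
                        ds = 5L, af_gnomad = 0, af_huabiao = 0,
                        exomiser_rank = 1L, acmg_class = "VUS",
                        proband_gt = "0/1", mode = "de_novo",
                        models = "AD", assumed = FALSE,
                        comp_het_partner = NA_character_,
                        stage = "wes", kind = "snv") {
  data.frame(patient_id = patient_id, family_id = paste0("FAM_", patient_id),
             stage = stage, kind = kind, chrom = chrom, pos = pos,
             ref = ref, alt = alt, gene = gene, transcript = NA_character_,
             functional_class = functional_class, cadd = cadd, ds = ds,
             af_gnomad = af_gnomad, af_huabiao = af_huabiao,
             exomiser_rank = exomiser_rank, acmg_class = acmg_class,
             spike = FALSE, proband_gt = proband_gt, mode = mode,
             models = models, assumed = assumed,
             comp_het_partner = comp_het_partner, stringsAsFactors = FALSE)
}

empty_config <- function() {
  cohort_config(n_total = 0, n_panel_pos = 0, n_wes_enrolled = 0,
                n_wes_pos = 0, n_lost = 0, n_syndromic = 0,
                n_nonsyndromic = 0, n_trio = 0, n_proband_only = 0,
                n_wes_syndromic = 0, n_panel_pos_syndromic = 0)
}
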