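triage_catalog <- function() {
  tiny_catalog(data.frame(
    symbol = c("ZIC1", "CDC45", "SNRPB", "ARG", "TWIST1"),
    models = c("AD", "AR", "AD", "AR", "AD")
  ))
}

test_that("a de novo P variant in a dominant gene is diagnostic", {
  v <- variant_row(gene = "ZIC1", functional_class = "nonsense",
                   acmg_class = "P", mode = "de_novo", models = "AD")
  res <- triage_patient(v, NULL, triage_catalog())
  expect_equal(res$status, "positive")
  expect_equal(res$rationale, "plp_consistent")
  expect_equal(res$causal_variants, variant_key("1", 1000L, "A", "G"))
})

test_that("a lone het LP allele cannot satisfy a recessive-only gene", {
  v <- variant_row(gene = "CDC45", functional_class = "frameshift",
                   acmg_class = "LP", mode = "paternal", models = "AD,AR")
  res <- triage_patient(v, NULL, triage_catalog())
  expect_equal(res$status, "negative")
  expect_equal(res$rationale, "single_allele_ar_insufficient")
})

test_that("VUS never contributes to a diagnosis", {
  v <- variant_row(gene = "SNRPB", functional_class = "nonsense",
                   acmg_class = "VUS", mode = "de_novo", models = "AD")
  res <- triage_patient(v, NULL, triage_catalog())
  expect_equal(res$status, "negative")
  expect_equal(res$rationale, "vus_only")
})

test_that("two P/LP alleles satisfy a recessive gene", {
  hom <- variant_row(gene = "ARG", acmg_class = "LP", proband_gt = "1/1",
                     mode = "hom_biparental", models = "AR")
  expect_equal(triage_patient(hom, NULL, triage_catalog())$status, "positive")
  k1 <- variant_key("1", 10L, "A", "G"); k2 <- variant_key("1", 20L, "A", "G")
  pair <- rbind(
    variant_row(pos = 10L, gene = "ARG", acmg_class = "LP",
                mode = "paternal", models = "AD,AR", comp_het_partner = k2),
    variant_row(pos = 20L, gene = "ARG", acmg_class = "P",
                mode = "maternal", models = "AD,AR", comp_het_partner = k1)
  )
  res <- triage_patient(pair, NULL, triage_catalog())
  expect_equal(res$status, "positive")
  expect_setequal(res$causal_variants, c(k1, k2))
  # a VUS partner breaks the pair
  pair$acmg_class[2] <- "VUS"
  expect_equal(triage_patient(pair, NULL, triage_catalog())$status,
               "negative")
})

test_that("P/LP CNVs over catalog genes are diagnostic", {
  cnv <- data.frame(chrom = "7", start = 16572119L, end = 19185044L,
                    type = "DEL", gene = "TWIST1", acmg_class = "P",
                    stringsAsFactors = FALSE)
  v <- variant_row()[0, ]
  res <- triage_patient(v, cnv, triage_catalog())
  expect_equal(res$status, "positive")
  cnv$gene <- "NOTACATGENE"
  expect_equal(triage_patient(v, cnv, triage_catalog())$status, "negative")
})

test_that("unknown pathogenicity tokens are rejected by name", {
  v <- variant_row(acmg_class = "PATHO")
  expect_error(triage_patient(v, NULL, triage_catalog()), "PATHO",
               class = "crstrio_input_error")
})

test_that("upgrading a class from VUS to LP never flips positive to
           negative, and non-causal variants are inert", {
  cat <- triage_catalog()
  withr::with_seed(21, {
    for (rep in 1:30) {
      n <- sample(1:5, 1)
      v <- do.call(rbind, lapply(seq_len(n), function(i) {
        variant_row(pos = i * 100L,
                    gene = sample(c("ZIC1", "CDC45", "ARG", "NOPE"), 1),
                    acmg_class = sample(c("P", "LP", "VUS", "LB", "B"), 1),
                    mode = sample(c("de_novo", "paternal", "maternal",
                                    "uncertain"), 1),
                    models = "AD,AR", assumed = FALSE)
      }))
      before <- triage_patient(v, NULL, cat)
      vus <- which(v$acmg_class == "VUS")
      if (length(vus)) {
        v2 <- v
        v2$acmg_class[sample(vus, 1)] <- "LP"
        after <- triage_patient(v2, NULL, cat)
        if (before$status == "positive") {
          expect_equal(after$status, "positive")
        }
      }
      # removing a variant that is not causal leaves the outcome alone
      noncausal <- setdiff(seq_len(n),
                           match(before$causal_variants,
                                 variant_key(v$chrom, v$pos, v$ref, v$alt)))
      if (length(noncausal)) {
        drop1 <- triage_patient(v[-noncausal[1], , drop = FALSE], NULL, cat)
        expect_equal(drop1$status, before$status)
        expect_setequal(drop1$causal_variants, before$causal_variants)
      }
    }
  })
})

test_that("stage-wise cohort triage reproduces the two-tier accounting", {
  wf <- default_workflow()
  t <- wf$triage$tallies
  expect_equal(t$panel_positive, 139)
  expect_equal(t$wes_positive, 10)
  expect_equal(t$both_negative, 92)
  expect_equal(t$not_tested, 23)
  # tallies partition the cohort
  expect_equal(t$panel_positive + t$wes_positive + t$both_negative +
                 t$not_tested, nrow(wf$bundle$patients))
  # at most one positive stage per patient
  out <- wf$triage$outcomes
  expect_true(all(table(out$patient_id[out$status == "positive"]) == 1))
  # positivity iff causal variants listed
  expect_true(all(nzchar(out$causal_variants) ==
                    (out$status == "positive")))
})

test_that("a cohort with no P/LP annotation yields zero positives", {
  wf <- default_workflow()
  v <- wf$variants
  v$acmg_class[v$acmg_class %in% c("P", "LP")] <- "VUS"
  cn <- wf$bundle$cnvs
  cn$acmg_class <- "VUS"
  res <- triage_cohort(v, cn, wf$bundle$patients, builtin_catalog())
  expect_equal(res$tallies$panel_positive + res$tallies$wes_positive, 0)
})
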