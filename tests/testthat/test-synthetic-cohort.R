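test_that("configuration invariants are enforced by name", {
  expect_error(cohort_config(n_panel_pos = 140),
               "n_panel_pos \\+ n_wes_enrolled \\+ n_lost",
               class = "crstrio_config_error")
  expect_error(cohort_config(n_syndromic = 100, n_nonsyndromic = 100,
                             n_total = 264, n_panel_pos = 139,
                             n_wes_enrolled = 102, n_lost = 23),
               "n_syndromic \\+ n_nonsyndromic",
               class = "crstrio_config_error")
  expect_error(cohort_config(n_trio = 80),
               "n_trio \\+ n_proband_only", class = "crstrio_config_error")
  expect_error(cohort_config(n_total = -1), class = "crstrio_config_error")
})

test_that("the default cohort reproduces every configured stage count", {
  b <- default_cohort()
  p <- b$patients
  cfg <- b$config
  expect_equal(nrow(p), cfg$n_total)
  expect_equal(sum(p$panel_positive), cfg$n_panel_pos)
  expect_equal(sum(p$wes_enrolled), cfg$n_wes_enrolled)
  expect_equal(sum(p$lost), cfg$n_lost)
  expect_equal(sum(p$trio), cfg$n_trio)
  expect_equal(sum(p$wes_enrolled & !p$trio), cfg$n_proband_only)
  expect_equal(sum(p$group == "syndromic"), cfg$n_syndromic)
  expect_equal(sum(p$group == "nonsyndromic"), cfg$n_nonsyndromic)
  expect_equal(sum(p$wes_enrolled & p$group == "syndromic"),
               cfg$n_wes_syndromic)
  expect_equal(sum(p$panel_positive & p$group == "syndromic"),
               cfg$n_panel_pos_syndromic)
  # suture-fusion composition per clinical group
  syn <- table(p$suture_type[p$group == "syndromic"])
  expect_equal(unname(syn[c("Sagittal", "Metopic", "Uni/Bi-coronal",
                            "Uni/Bi-lambdoidal", "Multiple", "Uncertain")]),
               c(16, 4, 53, 5, 54, 31), ignore_attr = TRUE)
  non <- table(p$suture_type[p$group == "nonsyndromic"])
  expect_equal(unname(non[c("Sagittal", "Metopic", "Uni/Bi-coronal",
                            "Uni/Bi-lambdoidal", "Multiple")]),
               c(41, 1, 36, 10, 13), ignore_attr = TRUE)
})

test_that("an all-zero configuration yields an empty but valid bundle", {
  b <- generate_cohort(empty_config())
  expect_equal(nrow(b$patients), 0)
  expect_equal(nrow(b$variants), 0)
  expect_equal(nrow(b$genotypes), 0)
  expect_equal(nrow(b$manifest), 0)
})

test_that("too few exome slots for the spike-in payloads is a capacity
           error", {
  cfg <- cohort_config(n_total = 264, n_panel_pos = 221,
                       n_wes_enrolled = 20, n_lost = 23, n_wes_pos = 10,
                       n_trio = 10, n_proband_only = 10,
                       n_wes_syndromic = 10, n_panel_pos_syndromic = 146)
  expect_error(generate_cohort(cfg), class = "crstrio_capacity_error")
})

test_that("generation is seed-reproducible and spike payloads are
           seed-independent", {
  b1 <- generate_cohort(cohort_config(seed = 101,
                                      decoy_variants_per_proband = 5))
  b2 <- generate_cohort(cohort_config(seed = 101,
                                      decoy_variants_per_proband = 5))
  expect_identical(b1, b2)
  b3 <- generate_cohort(cohort_config(seed = 202,
                                      decoy_variants_per_proband = 5))
  expect_identical(b1$manifest, b3$manifest)
  expect_identical(b1$variants[b1$variants$spike, ],
                   b3$variants[b3$variants$spike, ])
  expect_false(identical(b1$variants, b3$variants))
})

test_that("decoys never collide with spike-in coordinates", {
  b <- default_cohort()
  spikes <- b$variants[b$variants$spike, ]
  decoys <- b$variants[!b$variants$spike & b$variants$stage == "wes", ]
  expect_equal(length(intersect(paste(decoys$chrom, decoys$pos),
                                paste(spikes$chrom, spikes$pos))), 0)
  # and decoy keys are unique within a proband
  k <- paste(decoys$patient_id,
             variant_key(decoys$chrom, decoys$pos, decoys$ref, decoys$alt))
  expect_equal(anyDuplicated(k), 0)
})

test_that("the diagnostic payload set is placed as described", {
  b <- default_cohort()
  m <- b$manifest
  cmm <- m[m$expected_fate == "cmm_positive", ]
  expect_equal(nrow(cmm), 10)
  expect_equal(sum(cmm$kind == "snv"), 4)
  expect_equal(sum(cmm$kind == "indel"), 3)
  expect_equal(sum(cmm$kind == "cnv"), 3)
  expect_true(all(cmm$patient_id %in%
                    b$patients$patient_id[b$patients$wes_enrolled]))
  # each diagnostic payload sits in exactly one patient
  expect_equal(anyDuplicated(cmm$patient_id), 0)
  # ZIC1 nonsense, de novo, in a full trio
  zic1 <- b$variants[b$variants$gene == "ZIC1" & b$variants$spike, ]
  expect_equal(zic1$functional_class, "nonsense")
  g <- b$genotypes[b$genotypes$family_id == zic1$family_id &
                     b$genotypes$pos == zic1$pos, ]
  expect_setequal(g$role, c("proband", "father", "mother"))
  expect_equal(g$gt[g$role == "proband"], "0/1")
  expect_true(all(g$gt[g$role != "proband"] == "0/0"))
  # uncertain-inheritance carrier: parental genotypes withheld
  ankh <- b$variants[b$variants$gene == "ANKH" & b$variants$spike, ]
  g3 <- b$genotypes[b$genotypes$family_id == ankh$family_id, ]
  expect_setequal(unique(g3$role), "proband")
  # the three CNV deletions all span TWIST1
  expect_true(all(b$cnvs$gene == "TWIST1"))
  expect_equal(nrow(b$cnvs), 3)
})

test_that("the candidate payload set carries the printed annotations", {
  b <- default_cohort()
  m <- b$manifest
  rp <- m[m$expected_fate == "rp_candidate", ]
  expect_equal(nrow(rp), 15)
  expect_equal(length(unique(rp$gene)), 11)
  expect_equal(length(unique(rp$patient_id)), 13)
  v <- b$variants
  znf <- v[v$gene == "ZNF462" & v$spike, ]
  expect_equal(znf$cadd, 20.7)
  expect_equal(znf$ds, 1L)
  expect_equal(znf$exomiser_rank, 17L)
  # the recessive pairs carry one paternal and one maternal allele
  for (gene in c("IL11RA", "DNAH11")) {
    pv <- v[v$gene == gene & v$spike, ]
    expect_equal(nrow(pv), 2)
    fam <- unique(pv$family_id)
    expect_length(fam, 1)
    g <- b$genotypes[b$genotypes$family_id == fam &
                       b$genotypes$pos %in% pv$pos, ]
    carrier_parent <- vapply(split(g, g$pos), function(d) {
      d$role[d$role != "proband" & d$gt == "0/1"]
    }, character(1))
    expect_setequal(unname(carrier_parent), c("father", "mother"))
  }
})

test_that("spike-in payloads round-trip through VCF write/read", {
  b <- default_cohort()
  dir <- withr::local_tempdir()
  spikes <- b$manifest[b$manifest$kind != "cnv", ]
  fams <- unique(b$patients$family_id[match(spikes$patient_id,
                                            b$patients$patient_id)])
  for (fam in fams[1:5]) {
    g <- b$genotypes[b$genotypes$family_id == fam, ]
    path <- file.path(dir, paste0(fam, ".vcf"))
    write_family_vcf(g, path)
    back <- read_family_vcf(path, b$pedigree)
    k0 <- order(g$sample_id, g$chrom, g$pos)
    k1 <- order(back$sample_id, back$chrom, back$pos)
    expect_equal(back[k1, c("sample_id", "chrom", "pos", "ref", "alt",
                            "gt", "dp", "ad_alt")],
                 g[k0, c("sample_id", "chrom", "pos", "ref", "alt",
                         "gt", "dp", "ad_alt")],
                 ignore_attr = TRUE)
  }
})
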