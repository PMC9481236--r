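test_that("functional filter keeps LoF unconditionally and scored
           protein-altering variants by threshold", {
  v <- rbind(
    variant_row(pos = 1L, functional_class = "missense", cadd = 20.7, ds = 1L),
    variant_row(pos = 2L, functional_class = "nonsense", cadd = NA, ds = NA),
    variant_row(pos = 3L, functional_class = "missense", cadd = 19.9, ds = 3L),
    variant_row(pos = 4L, functional_class = "synonymous", cadd = 35, ds = 9L),
    variant_row(pos = 5L, functional_class = "inframe_indel", cadd = 10, ds = 5L),
    variant_row(pos = 6L, functional_class = "missense", cadd = NA, ds = 4L)
  )
  out <- functional_filter(v)
  expect_setequal(out$pos, c(1L, 2L, 5L, 6L))
  expect_error(functional_filter(variant_row(functional_class = "weird")),
               class = "crstrio_input_error")
})

test_that("frequency filter applies model-specific ceilings inclusively", {
  th <- filter_thresholds()
  ad_ok <- variant_row(pos = 1L, af_gnomad = 4e-5, af_huabiao = 1e-4,
                       models = "AD")
  expect_equal(nrow(frequency_filter(ad_ok, th)), 1)
  ad_edge <- variant_row(pos = 2L, af_gnomad = 5e-5, models = "AD")
  expect_equal(nrow(frequency_filter(ad_edge, th)), 1)
  ad_out <- variant_row(pos = 3L, af_gnomad = 6e-5, models = "AD")
  expect_equal(nrow(frequency_filter(ad_out, th)), 0)
  # absent from both databases survives every model
  zero <- variant_row(pos = 4L, af_gnomad = NA, af_huabiao = NA,
                      models = "AD,AR,XLD,XLR")
  out <- frequency_filter(zero, th)
  expect_equal(out$surviving_models, "AD,AR,XLD,XLR")
  # a carrier-frequency allele fails the dominant ceiling but survives
  # the recessive one, and the surviving model is recorded
  carrier <- variant_row(pos = 5L, af_gnomad = 1e-4, models = "AD,AR")
  out <- frequency_filter(carrier, th)
  expect_equal(out$surviving_models, "AR")
  expect_error(frequency_filter(variant_row(af_gnomad = 2), th),
               class = "crstrio_input_error")
})

test_that("rank filter keeps the top 20 inclusively and drops unranked", {
  v <- rbind(variant_row(pos = 1L, exomiser_rank = 17L),
             variant_row(pos = 2L, exomiser_rank = 20L),
             variant_row(pos = 3L, exomiser_rank = 21L),
             variant_row(pos = 4L, exomiser_rank = NA_integer_))
  expect_setequal(rank_filter(v, 20)$pos, c(1L, 2L))
})

test_that("part intersection is an exact key intersection per proband", {
  a <- rbind(variant_row(pos = 1L), variant_row(pos = 2L))
  b <- rbind(variant_row(pos = 2L), variant_row(pos = 3L))
  expect_equal(intersect_parts(a, b)$pos, 2L)
  other <- variant_row(pos = 2L, patient_id = "PT2")
  expect_equal(nrow(intersect_parts(a, other)), 0)
  expect_equal(nrow(intersect_parts(a[0, ], b[0, ])), 0)
})

test_that("model concordance requires catalog membership and blocks
           resolved single hets in recessive-only genes", {
  cat <- tiny_catalog(data.frame(symbol = c("ARG", "ADG", "XG"),
                                 models = c("AR", "AD", "XLR")))
  v <- rbind(
    variant_row(pos = 1L, gene = "ARG", mode = "paternal", models = "AD,AR"),
    variant_row(pos = 2L, gene = "ADG", mode = "de_novo", models = "AD"),
    variant_row(pos = 3L, gene = "NOTINCAT", mode = "de_novo", models = "AD"),
    variant_row(pos = 4L, gene = "XG", chrom = "X", proband_gt = "1/1",
                mode = "hemizygous_maternal", models = "XLR"),
    variant_row(pos = 5L, gene = "ARG", mode = "uncertain",
                models = "AD,AR,XLD,XLR", assumed = TRUE)
  )
  v$surviving_models <- v$models
  out <- catalog_and_model_match(v, cat)
  expect_equal(out$catalog_hit, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # paternal single het cannot satisfy AR-only ARG; assumed call can
  expect_equal(out$omim_model_match, c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("compound-het pairs survive or fall as a unit", {
  cat <- tiny_catalog(data.frame(symbol = "ARG", models = "AR"))
  k1 <- variant_key("1", 10L, "A", "G"); k2 <- variant_key("1", 20L, "A", "G")
  v <- rbind(
    variant_row(pos = 10L, gene = "ARG", mode = "paternal", models = "AD,AR",
                comp_het_partner = k2),
    variant_row(pos = 20L, gene = "ARG", mode = "maternal", models = "AD,AR",
                comp_het_partner = k1)
  )
  v$surviving_models <- v$models
  out <- catalog_and_model_match(v, cat)
  expect_true(all(out$omim_model_match))
  # partner dropped (e.g. failed an upstream filter and absent from the
  # table): the remaining half no longer matches
  solo <- v[1, ]
  out_solo <- catalog_and_model_match(solo, cat)
  expect_false(out_solo$omim_model_match)
})

test_that("research pipeline provenance flags are consistent on the
           default cohort", {
  res <- default_workflow()$research
  expect_true(all(res$final <= (res$passed_part1 & res$passed_part2 &
                                  res$catalog_hit & res$omim_model_match &
                                  !res$excluded_on_review)))
  # intersection containment: final implies both parts
  expect_true(all(res$passed_part1[res$final]))
  expect_true(all(res$passed_part2[res$final]))
})

test_that("final set equals a brute-force re-evaluation of every
           predicate over the exome variants", {
  wf <- default_workflow()
  v <- wf$variants
  v <- v[v$stage == "wes" & v$kind %in% c("snv", "indel"), ]
  th <- filter_thresholds()
  cat <- builtin_catalog()
  # independent predicate evaluation with plain vector operations
  lof <- v$functional_class %in% c("frameshift", "nonsense", "splicing")
  scored <- v$functional_class %in% c("missense", "inframe_indel") &
    ((!is.na(v$ds) & v$ds >= 4) | (!is.na(v$cadd) & v$cadd >= 20))
  afg <- ifelse(is.na(v$af_gnomad), 0, v$af_gnomad)
  afh <- ifelse(is.na(v$af_huabiao), 0, v$af_huabiao)
  surv <- mapply(function(models, g, h) {
    ms <- strsplit(models, ",")[[1]]
    keep <- vapply(ms, function(m) {
      if (m %in% c("AD", "XLD")) g <= 5e-5 && h <= 5e-4
      else g <= 1e-3 && h <= 5e-3
    }, logical(1))
    paste(ms[keep], collapse = ",")
  }, v$models, afg, afh, USE.NAMES = FALSE)
  p1 <- (lof | scored) & nzchar(surv)
  p2 <- nzchar(surv) & !is.na(v$exomiser_rank) & v$exomiser_rank <= 20
  hit <- vapply(v$gene, function(g) !is.null(catalog_lookup(cat, g)),
                logical(1))
  model_ok <- vapply(seq_len(nrow(v)), function(i) {
    if (!hit[i]) return(FALSE)
    gm <- catalog_models(cat, v$gene[i])[[1]]
    ms <- strsplit(surv[i], ",")[[1]]
    if (!isTRUE(v$assumed[i]) && is.na(v$comp_het_partner[i]) &&
          v$mode[i] %in% c("de_novo", "paternal", "maternal") &&
          v$proband_gt[i] == "0/1") {
      ms <- setdiff(ms, c("AR", "XLR"))
    }
    length(intersect(ms, gm)) > 0
  }, logical(1))
  # comp-het unit rule
  vk <- paste(v$patient_id, variant_key(v$chrom, v$pos, v$ref, v$alt))
  paired <- which(!is.na(v$comp_het_partner))
  pidx <- match(paste(v$patient_id[paired], v$comp_het_partner[paired]), vk)
  reviewed <- (v$acmg_class %in% c("LB", "B")) | v$gene == "APC"
  expected <- p1 & p2 & hit & model_ok & !reviewed
  expected[paired] <- expected[paired] &
    ifelse(is.na(pidx), FALSE,
           (p1 & p2 & model_ok & !reviewed)[pidx])
  res <- run_research_pipeline(v, cat, th)
  rk <- paste(res$patient_id, variant_key(res$chrom, res$pos, res$ref,
                                          res$alt))
  expect_setequal(rk[res$final], vk[expected])
})

test_that("tightening any threshold never adds a final variant", {
  wf <- default_workflow()
  v <- wf$variants
  v <- v[v$stage == "wes" & v$kind %in% c("snv", "indel"), ]
  cat <- builtin_catalog()
  base <- run_research_pipeline(v, cat, filter_thresholds())
  base_keys <- with(base[base$final, ],
                    paste(patient_id, variant_key(chrom, pos, ref, alt)))
  tighter <- list(
    filter_thresholds(cadd_min = 25),
    filter_thresholds(ds_min = 6),
    filter_thresholds(rank_max = 5),
    filter_thresholds(af_ad_gnomad = 1e-6, af_ad_huabiao = 1e-6),
    filter_thresholds(af_recessive_gnomad = 1e-5,
                      af_recessive_huabiao = 1e-5)
  )
  for (th in tighter) {
    res <- run_research_pipeline(v, cat, th)
    keys <- with(res[res$final, ],
                 paste(patient_id, variant_key(chrom, pos, ref, alt)))
    expect_true(all(keys %in% base_keys))
  }
  # degenerate: infinite score thresholds leave only LoF in part one
  inf <- run_research_pipeline(v, cat,
                               filter_thresholds(cadd_min = Inf,
                                                 ds_min = .Machine$integer.max))
  expect_true(all(inf$functional_class[inf$passed_part1] %in%
                    c("frameshift", "nonsense", "splicing")))
})
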