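# Hand-written truth table over all 3^3 autosomal trio genotype
# combinations: the oracle is an explicit lookup, independent of the
# implementation's branching.
autosomal_truth <- function(p, f, m) {
  carrier <- function(g) g %in% c("0/1", "1/1")
  if (p == "0/1") {
    if (!carrier(f) && !carrier(m)) return("de_novo")
    if (carrier(f) && !carrier(m)) return("paternal")
    if (!carrier(f) && carrier(m)) return("maternal")
    return("uncertain")
  }
  if (p == "1/1") {
    if (carrier(f) && carrier(m)) return("hom_biparental")
    return("uncertain")
  }
  "uncertain"
}

test_that("autosomal trio modes match the exhaustive truth table", {
  gts <- c("0/0", "0/1", "1/1")
  for (p in gts) for (f in gts) for (m in gts) {
    call <- assign_inheritance(p, f, m, sex = "female", chromosome = "7")
    expect_equal(call$mode, autosomal_truth(p, f, m),
                 info = sprintf("p=%s f=%s m=%s", p, f, m))
    expect_gt(length(call$models), 0)
  }
})

test_that("de novo requires both parents genotyped hom-ref", {
  expect_equal(assign_inheritance("0/1", "0/0", "0/0")$mode, "de_novo")
  # a missing parent can never yield a de novo call
  for (f in c(NA, "./.")) {
    expect_equal(assign_inheritance("0/1", f, "0/0")$mode, "uncertain")
    expect_equal(assign_inheritance("0/1", "0/0", f)$mode, "uncertain")
  }
})

test_that("X-linked male probands are called hemizygous from the mother", {
  call <- assign_inheritance("1/1", "0/0", "0/1", sex = "male",
                             chromosome = "X")
  expect_equal(call$mode, "hemizygous_maternal")
  expect_equal(call$models, "XLR")
  # genotyped non-carrier mother: de novo on X
  dn <- assign_inheritance("1/1", "0/0", "0/0", sex = "male",
                           chromosome = "X")
  expect_equal(dn$mode, "de_novo")
  expect_setequal(dn$models, c("XLD", "XLR"))
})

test_that("proband-only cases get assumed models under every mode", {
  call <- assign_inheritance("0/1", NA, NA, sex = "male", chromosome = "2")
  expect_equal(call$mode, "uncertain")
  expect_true(call$assumed)
  expect_setequal(call$models, c("AD", "AR", "XLD", "XLR"))
})

test_that("Mendelian-inconsistent genotypes are kept as uncertain", {
  call <- assign_inheritance("1/1", "0/0", "0/0")
  expect_equal(call$mode, "uncertain")
  expect_true(call$assumed)
})

comp_het_fixture <- function(modes, gene = "G1", patient = "PT1") {
  n <- length(modes)
  data.frame(patient_id = patient, gene = gene, chrom = "2",
             pos = seq_len(n) * 10L, ref = "A", alt = "T",
             proband_gt = "0/1", mode = modes, stringsAsFactors = FALSE)
}

test_that("compound-het pairing equals the cross-parent cross product", {
  # 2 paternal x 1 maternal -> 2 pairs
  expect_equal(nrow(pair_compound_hets(
    comp_het_fixture(c("paternal", "paternal", "maternal")))), 2)
  # same-parent phase never pairs
  expect_equal(nrow(pair_compound_hets(
    comp_het_fixture(c("maternal", "maternal")))), 0)
  # exhaustive-enumeration oracle on random instances of <= 10 variants
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(1:10, 1)
      modes <- sample(c("paternal", "maternal", "de_novo", "uncertain"),
                      n, replace = TRUE)
      v <- comp_het_fixture(modes)
      expected <- 0L
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (modes[i] == "paternal" && modes[j] == "maternal") {
          expected <- expected + 1L
        }
      }
      pairs <- pair_compound_hets(v)
      expect_equal(nrow(pairs), expected)
      if (nrow(pairs)) {
        expect_true(all(pairs$models == "AR"))
      }
    }
  })
})

test_that("pairing is gene- and patient-local", {
  v <- rbind(comp_het_fixture(c("paternal", "maternal"), gene = "G1"),
             comp_het_fixture(c("paternal", "maternal"), gene = "G2",
                              patient = "PT2"))
  v$pos <- c(10L, 20L, 30L, 40L)
  pairs <- pair_compound_hets(v)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$gene, c("G1", "G2"))
})

test_that("table-level assignment joins genotypes and flags pedigree gaps", {
  ped <- data.frame(family_id = "F1", sample_id = c("PT1", "PT1_fa", "PT1_mo"),
                    father_id = c("PT1_fa", "0", "0"),
                    mother_id = c("PT1_mo", "0", "0"),
                    sex = c(2L, 1L, 2L), phenotype = c(2L, 1L, 1L),
                    stringsAsFactors = FALSE)
  gt <- data.frame(
    family_id = "F1", sample_id = c("PT1", "PT1_fa", "PT1_mo"),
    role = c("proband", "father", "mother"), chrom = "5", pos = 100L,
    ref = "C", alt = "T", gt = c("0/1", "0/0", "0/0"),
    dp = 50L, ad_alt = c(25L, 0L, 1L), stringsAsFactors = FALSE)
  v <- data.frame(patient_id = "PT1", family_id = "F1", chrom = "5",
                  pos = 100L, ref = "C", alt = "T", gene = "GENEX",
                  stringsAsFactors = FALSE)
  out <- assign_inheritance_table(v, gt, ped)
  expect_equal(out$mode, "de_novo")
  expect_equal(out$proband_gt, "0/1")
  v2 <- v; v2$patient_id <- "NOPE"
  expect_error(assign_inheritance_table(v2, gt, ped),
               class = "crstrio_pedigree_error")
})
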