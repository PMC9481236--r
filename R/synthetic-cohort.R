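#' Configuration of the synthetic two-stage cohort
#'
#' Describes a craniosynostosis cohort with a tiered genetic-testing
#' history: every patient is panel-sequenced first; panel-negative
#' patients are either enrolled for trio/proband-only exome sequencing
#' or lost to follow-up.  Defaults encode the modelled study conditions:
#' 264 patients, 139 resolved by the 17-gene panel, 102 exome-enrolled
#' (81 trios, 21 proband-only), 10 exome-stage diagnoses, 23 lost after
#' a negative panel; 163 syndromic and 101 non-syndromic patients, with
#' 33 syndromic among the exome-enrolled and 123 among the
#' panel-resolved (the remaining 7 syndromic and 16 non-syndromic
#' patients are the lost group — the split is configurable).
#'
#' @param n_total cohort size.
#' @param n_panel_pos patients resolved at the panel stage.
#' @param n_wes_enrolled panel-negative patients exome-sequenced.
#' @param n_wes_pos exome-stage positive diagnoses.
#' @param n_lost panel-negative patients lost to follow-up (no exome).
#' @param n_syndromic,n_nonsyndromic clinical group sizes.
#' @param n_trio,n_proband_only family structure of the exome stage.
#' @param n_wes_syndromic syndromic patients among the exome-enrolled.
#' @param n_panel_pos_syndromic syndromic patients among the
#'   panel-resolved.
#' @param decoy_variants_per_proband rare-variant background depth per
#'   exome proband.
#' @param decoy_af_distribution list `min`, `max` (log-uniform allele-
#'   frequency range for decoys) and `p_absent` (share absent from both
#'   population databases).
#' @param seed random seed governing decoys (spike-in payloads are
#'   seed-independent).
#' @return validated `crs_cohort_config` list.
#' @export
cohort_config <- function(n_total = 264L, n_panel_pos = 139L,
                          n_wes_enrolled = 102L, n_wes_pos = 10L,
                          n_lost = 23L, n_syndromic = 163L,
                          n_nonsyndromic = 101L, n_trio = 81L,
                          n_proband_only = 21L, n_wes_syndromic = 33L,
                          n_panel_pos_syndromic = 123L,
                          decoy_variants_per_proband = 30L,
                          decoy_af_distribution = list(min = 1e-6,
                                                       max = 0.5,
                                                       p_absent = 0.2),
                          seed = 1L) {
  cfg <- list(
    n_total = as.integer(n_total), n_panel_pos = as.integer(n_panel_pos),
    n_wes_enrolled = as.integer(n_wes_enrolled),
    n_wes_pos = as.integer(n_wes_pos), n_lost = as.integer(n_lost),
    n_syndromic = as.integer(n_syndromic),
    n_nonsyndromic = as.integer(n_nonsyndromic),
    n_trio = as.integer(n_trio),
    n_proband_only = as.integer(n_proband_only),
    n_wes_syndromic = as.integer(n_wes_syndromic),
    n_panel_pos_syndromic = as.integer(n_panel_pos_syndromic),
    decoy_variants_per_proband = as.integer(decoy_variants_per_proband),
    decoy_af_distribution = decoy_af_distribution,
    seed = as.integer(seed)
  )
  counts <- unlist(cfg[startsWith(names(cfg), "n_")])
  if (any(counts < 0)) {
    crs_abort("all cohort counts must be non-negative",
              "crstrio_config_error")
  }
  if (cfg$n_panel_pos + cfg$n_wes_enrolled + cfg$n_lost != cfg$n_total) {
    crs_abort(sprintf(
      "violated identity: n_panel_pos + n_wes_enrolled + n_lost = n_total (%d + %d + %d != %d)",
      cfg$n_panel_pos, cfg$n_wes_enrolled, cfg$n_lost, cfg$n_total),
      "crstrio_config_error")
  }
  if (cfg$n_syndromic + cfg$n_nonsyndromic != cfg$n_total) {
    crs_abort(sprintf(
      "violated identity: n_syndromic + n_nonsyndromic = n_total (%d + %d != %d)",
      cfg$n_syndromic, cfg$n_nonsyndromic, cfg$n_total),
      "crstrio_config_error")
  }
  if (cfg$n_trio + cfg$n_proband_only != cfg$n_wes_enrolled) {
    crs_abort(sprintf(
      "violated identity: n_trio + n_proband_only = n_wes_enrolled (%d + %d != %d)",
      cfg$n_trio, cfg$n_proband_only, cfg$n_wes_enrolled),
      "crstrio_config_error")
  }
  if (cfg$n_wes_pos > cfg$n_wes_enrolled) {
    crs_abort("violated identity: n_wes_pos <= n_wes_enrolled",
              "crstrio_config_error")
  }
  lost_syn <- cfg$n_syndromic - cfg$n_wes_syndromic -
    cfg$n_panel_pos_syndromic
  if (cfg$n_wes_syndromic > cfg$n_wes_enrolled ||
        cfg$n_panel_pos_syndromic > cfg$n_panel_pos ||
        lost_syn < 0 || lost_syn > cfg$n_lost) {
    crs_abort(
      "violated identity: syndromic stage split must fit within stage sizes",
      "crstrio_config_error")
  }
  structure(cfg, class = "crs_cohort_config")
}

SUTURE_TYPES <- c("Sagittal", "Metopic", "Uni/Bi-coronal",
                  "Uni/Bi-lambdoidal", "Multiple", "Uncertain")
# per-group suture-type weights of the modelled cohort (syndromic /
# non-syndromic), and per-group male counts
SUTURE_WEIGHTS <- list(
  syndromic = c(16, 4, 53, 5, 54, 31),
  nonsyndromic = c(41, 1, 36, 10, 13, 0)
)
MALE_WEIGHTS <- c(syndromic = 87 / 163, nonsyndromic = 58 / 101)
WES_MALE_FRACTION <- 61 / 102

# evenly interleave category labels: rep(cats, counts) reordered so each
# category is spread across the sequence (deterministic)
spread_labels <- function(cats, counts) {
  if (sum(counts) == 0) return(character(0))
  pos <- unlist(lapply(seq_along(cats), function(k) {
    if (counts[k] == 0) return(numeric(0))
    (seq_len(counts[k]) - 0.5) / counts[k]
  }))
  labs <- rep(cats, counts)
  labs[order(pos, labs)]
}

# default per-gene plan for the panel-resolved patients: five recurrently
# mutated core genes plus four single-patient genes, so that the union
# with the exome-stage genes yields 16 pathogenic genes of which 11
# contribute one patient each
panel_gene_plan <- function() {
  data.frame(
    gene = c("FGFR2", "FGFR3", "TWIST1", "TCF12", "EFNB1",
             "ERF", "SKI", "SMAD3", "MSX2"),
    chrom = c("10", "4", "7", "15", "X", "19", "1", "15", "5"),
    base_pos = c(123256215L, 1803564L, 19156500L, 57214000L, 68059000L,
                 42751500L, 2160200L, 67358200L, 174151500L),
    n_patients = c(60L, 30L, 20L, 15L, 10L, 1L, 1L, 1L, 1L),
    n_distinct = c(20L, 8L, 10L, 10L, 7L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-stage cohort bundle
#'
#' Builds a fully self-contained cohort: patient table with clinical
#' descriptors and testing history, pedigrees, per-family small-variant
#' genotypes, an annotated variant table, CNV calls, and a spike-in
#' manifest.  The exome stage carries the built-in spike-in payloads
#' (diagnostic P/LP variants, research-pipeline candidates, potentially
#' pathogenic non-diagnostic variants, a review-excluded variant) plus a
#' seeded background of decoy variants drawn from the configured
#' frequency/deleteriousness distributions.  Panel-resolved patients
#' carry one causal P/LP panel variant each, drawn from a pool of
#' distinct variants across the core panel genes.  Identical seeds give
#' identical bundles; different seeds change only the decoys.
#'
#' @param config a [cohort_config()].
#' @return a `crs_cohort` list: `config`, `patients`, `pedigree`,
#'   `variants`, `genotypes`, `cnvs`, `manifest`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "crs_cohort_config"))
  if (config$n_total == 0) return(empty_cohort(config))

  spikes_sm <- all_small_payloads()
  spikes_cnv <- cmm_positive_cnv_payloads()
  spike_pat <- unique(rbind(
    spikes_sm[, c("patient_id", "sex", "group", "suture_type",
                  "proband_only")],
    spikes_cnv[, c("patient_id", "sex", "group", "suture_type",
                   "proband_only")]
  ))
  if (config$n_wes_enrolled < nrow(spike_pat)) {
    crs_abort(sprintf(
      "capacity error: %d exome-enrolled patients cannot host %d spike-in carriers",
      config$n_wes_enrolled, nrow(spike_pat)), "crstrio_capacity_error")
  }
  if (config$n_wes_pos != sum(spikes_sm$expected_fate == "cmm_positive") +
        nrow(spikes_cnv)) {
    crs_abort(sprintf(
      "capacity error: n_wes_pos = %d but the diagnostic payload set has 10 carriers",
      config$n_wes_pos), "crstrio_capacity_error")
  }

  patients <- build_patients(config, spike_pat)
  panel <- build_panel_variants(config, patients)
  patients$causal_panel_key[match(panel$patient_id, patients$patient_id)] <-
    variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)

  wes <- build_wes_spike_variants(spikes_sm, patients)
  decoys <- withr::with_seed(config$seed,
                             build_decoys(config, patients, spikes_sm))
  variants <- rbind(panel$variants, wes$variants, decoys$variants)
  rownames(variants) <- NULL
  genotypes <- rbind(wes$genotypes, decoys$genotypes)
  rownames(genotypes) <- NULL

  pedigree <- build_pedigree(patients)
  cnvs <- build_cnv_table(spikes_cnv, patients)
  manifest <- build_manifest(spikes_sm, spikes_cnv)

  structure(list(config = config, patients = patients, pedigree = pedigree,
                 variants = variants, genotypes = genotypes, cnvs = cnvs,
                 manifest = manifest),
            class = "crs_cohort")
}

empty_cohort <- function(config) {
  structure(list(
    config = config,
    patients = data.frame(patient_id = character(0), family_id = character(0),
                          sex = character(0), group = character(0),
                          suture_type = character(0),
                          panel_positive = logical(0), wes_enrolled = logical(0),
                          lost = logical(0), trio = logical(0),
                          causal_panel_key = character(0),
                          stringsAsFactors = FALSE),
    pedigree = data.frame(family_id = character(0), sample_id = character(0),
                          father_id = character(0), mother_id = character(0),
                          sex = integer(0), phenotype = integer(0),
                          stringsAsFactors = FALSE),
    variants = empty_variant_table(),
    genotypes = empty_genotype_table(),
    cnvs = data.frame(patient_id = character(0), family_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      gene = character(0), acmg_class = character(0),
                      inheritance = character(0), stringsAsFactors = FALSE),
    manifest = data.frame(patient_id = character(0), kind = character(0),
                          key = character(0), gene = character(0),
                          expected_fate = character(0),
                          acmg_class = character(0),
                          inheritance = character(0), stringsAsFactors = FALSE)
  ), class = "crs_cohort")
}

empty_variant_table <- function() {
  data.frame(patient_id = character(0), family_id = character(0),
             stage = character(0), kind = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             gene = character(0), transcript = character(0),
             functional_class = character(0), cadd = numeric(0),
             ds = integer(0), af_gnomad = numeric(0), af_huabiao = numeric(0),
             exomiser_rank = integer(0), acmg_class = character(0),
             spike = logical(0), stringsAsFactors = FALSE)
}

empty_genotype_table <- function() {
  data.frame(family_id = character(0), sample_id = character(0),
             role = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), gt = character(0),
             dp = integer(0), ad_alt = integer(0), stringsAsFactors = FALSE)
}

build_patients <- function(config, spike_pat) {
  groups <- c("syndromic", "nonsyndromic")
  group_sizes <- c(syndromic = config$n_syndromic,
                   nonsyndromic = config$n_nonsyndromic)
  # per-group suture targets for the whole cohort
  suture_targets <- lapply(groups, function(g) {
    allocate_counts(SUTURE_WEIGHTS[[g]], group_sizes[[g]])
  })
  names(suture_targets) <- groups
  male_targets <- vapply(groups, function(g) {
    as.integer(round_half_up(MALE_WEIGHTS[[g]] * group_sizes[[g]]))
  }, integer(1))
  names(male_targets) <- groups

  # consume the spike carriers' cells
  for (i in seq_len(nrow(spike_pat))) {
    g <- spike_pat$group[i]
    k <- match(spike_pat$suture_type[i], SUTURE_TYPES)
    suture_targets[[g]][k] <- max(0L, suture_targets[[g]][k] - 1L)
    if (spike_pat$sex[i] == "male") {
      male_targets[[g]] <- max(0L, male_targets[[g]] - 1L)
    }
  }

  n_spike <- nrow(spike_pat)
  spike_syn <- sum(spike_pat$group == "syndromic")
  gen_wes_syn <- config$n_wes_syndromic - spike_syn
  gen_wes_non <- (config$n_wes_enrolled - n_spike) - gen_wes_syn
  if (gen_wes_syn < 0 || gen_wes_non < 0) {
    crs_abort("capacity error: syndromic split cannot host the spike carriers",
              "crstrio_capacity_error")
  }
  panel_syn <- config$n_panel_pos_syndromic
  panel_non <- config$n_panel_pos - panel_syn
  lost_syn <- config$n_syndromic - config$n_wes_syndromic - panel_syn
  lost_non <- config$n_lost - lost_syn

  blocks <- data.frame(
    block = c("wes", "wes", "panel", "panel", "lost", "lost"),
    group = rep(groups, 3),
    n = c(gen_wes_syn, gen_wes_non, panel_syn, panel_non, lost_syn, lost_non),
    stringsAsFactors = FALSE
  )
  gen <- data.frame(
    block = rep(blocks$block, blocks$n),
    group = rep(blocks$group, blocks$n),
    stringsAsFactors = FALSE
  )
  gen$patient_id <- ""
  gen$patient_id[gen$block == "wes"] <-
    sprintf("W%03d", 100 + seq_len(sum(gen$block == "wes")))
  gen$patient_id[gen$block == "panel"] <-
    sprintf("P%03d", seq_len(sum(gen$block == "panel")))
  gen$patient_id[gen$block == "lost"] <-
    sprintf("L%03d", seq_len(sum(gen$block == "lost")))

  # sutures: evenly interleaved fill of the remaining per-group cells
  gen$suture_type <- NA_character_
  for (g in groups) {
    labs <- spread_labels(SUTURE_TYPES, suture_targets[[g]])
    idx <- which(gen$group == g)
    gen$suture_type[idx] <- labs[seq_along(idx)]
  }
  # sex: exome-stage male share first, then per-group remainders
  gen$sex <- "female"
  wes_male_target <- as.integer(round_half_up(
    WES_MALE_FRACTION * config$n_wes_enrolled))
  wes_male_gen <- max(0L, wes_male_target - sum(spike_pat$sex == "male"))
  wes_idx <- which(gen$block == "wes")
  gen$sex[utils::head(wes_idx, wes_male_gen)] <- "male"
  for (g in groups) {
    used <- sum(gen$sex == "male" & gen$group == g)
    remaining <- max(0L, male_targets[[g]] - used)
    idx <- which(gen$group == g & gen$block != "wes")
    gen$sex[utils::head(idx, remaining)] <- "male"
  }

  spike_df <- data.frame(
    patient_id = spike_pat$patient_id, block = "wes",
    group = spike_pat$group, suture_type = spike_pat$suture_type,
    sex = spike_pat$sex, stringsAsFactors = FALSE
  )
  all_df <- rbind(spike_df,
                  gen[, c("patient_id", "block", "group", "suture_type",
                          "sex")])
  all_df$wes_enrolled <- all_df$block == "wes"
  all_df$panel_positive <- all_df$block == "panel"
  all_df$lost <- all_df$block == "lost"

  # family structure: spike carriers carry their fixed proband-only flag;
  # the remaining proband-only slots go to the first generated exome
  # patients
  all_df$trio <- FALSE
  po <- logical(nrow(all_df))
  po[match(spike_pat$patient_id, all_df$patient_id)] <- spike_pat$proband_only
  need_po <- config$n_proband_only - sum(po)
  if (need_po < 0) {
    crs_abort("capacity error: fewer proband-only slots than spike carriers need",
              "crstrio_capacity_error")
  }
  gen_wes_ids <- all_df$patient_id[all_df$wes_enrolled &
                                     !all_df$patient_id %in%
                                     spike_pat$patient_id]
  po[match(utils::head(gen_wes_ids, need_po), all_df$patient_id)] <- TRUE
  all_df$trio <- all_df$wes_enrolled & !po
  all_df$family_id <- ifelse(all_df$wes_enrolled,
                             paste0("FAM_", all_df$patient_id),
                             NA_character_)
  all_df$causal_panel_key <- NA_character_
  all_df[, c("patient_id", "family_id", "sex", "group", "suture_type",
             "panel_positive", "wes_enrolled", "lost", "trio",
             "causal_panel_key")]
}

build_panel_variants <- function(config, patients) {
  plan <- panel_gene_plan()
  counts <- allocate_counts(plan$n_patients, config$n_panel_pos)
  pool <- list()
  ref_cycle <- c("C", "G", "A", "T")
  alt_cycle <- c("T", "A", "G", "C")
  class_cycle <- c("missense", "nonsense", "missense", "frameshift",
                   "missense", "splicing")
  acmg_cycle <- c("P", "LP")
  rows <- list()
  pids <- patients$patient_id[patients$panel_positive]
  gene_of <- rep(plan$gene, counts)
  offset <- 0L
  for (k in seq_len(nrow(plan))) {
    if (counts[k] == 0) next
    d <- min(plan$n_distinct[k], counts[k])
    i <- seq_len(d)
    ref <- ref_cycle[(i - 1L) %% 4L + 1L]
    alt <- alt_cycle[(i - 1L) %% 4L + 1L]
    cls <- class_cycle[(i - 1L) %% 6L + 1L]
    fs <- cls == "frameshift"
    ref[fs] <- paste0(ref[fs], "A")
    pool_k <- data.frame(
      chrom = plan$chrom[k], pos = plan$base_pos[k] + (i - 1L) * 37L,
      ref = ref, alt = alt, functional_class = cls,
      acmg_class = acmg_cycle[(i - 1L) %% 2L + 1L],
      stringsAsFactors = FALSE
    )
    assign_idx <- (seq_len(counts[k]) - 1L) %% d + 1L
    sel <- pool_k[assign_idx, , drop = FALSE]
    sel$patient_id <- pids[offset + seq_len(counts[k])]
    sel$gene <- plan$gene[k]
    offset <- offset + counts[k]
    rows[[k]] <- sel
  }
  sel <- do.call(rbind, rows)
  if (is.null(sel)) {
    return(list(variants = empty_variant_table(),
                patient_id = character(0), chrom = character(0),
                pos = integer(0), ref = character(0), alt = character(0)))
  }
  v <- empty_variant_table()[rep(1, 0), ]
  v <- data.frame(
    patient_id = sel$patient_id, family_id = NA_character_, stage = "panel",
    kind = ifelse(nchar(sel$ref) > 1 | nchar(sel$alt) > 1, "indel", "snv"),
    chrom = sel$chrom, pos = as.integer(sel$pos), ref = sel$ref,
    alt = sel$alt, gene = sel$gene, transcript = NA_character_,
    functional_class = sel$functional_class, cadd = NA_real_,
    ds = NA_integer_, af_gnomad = 0, af_huabiao = 0,
    exomiser_rank = NA_integer_, acmg_class = sel$acmg_class, spike = FALSE,
    stringsAsFactors = FALSE
  )
  list(variants = v, patient_id = v$patient_id, chrom = v$chrom,
       pos = v$pos, ref = v$ref, alt = v$alt)
}

# deterministic spike genotype depths: heterozygous calls sit safely
# inside the 0.3-0.7 depth-ratio band, hemizygous calls near 1
spike_depths <- function(i, kind) {
  switch(kind,
    het = {
      dp <- 44L + (i * 3L) %% 17L
      c(dp = dp, ad = dp %/% 2L)
    },
    hom_ref = {
      dp <- 42L + (i * 5L) %% 11L
      c(dp = dp, ad = i %% 2L)
    },
    hemi_alt = {
      dp <- 40L + i %% 9L
      c(dp = dp, ad = dp - 2L)
    },
    carrier_het = {
      dp <- 45L + (i * 7L) %% 13L
      c(dp = dp, ad = as.integer(floor(dp * 0.45)))
    }
  )
}

build_wes_spike_variants <- function(spikes_sm, patients) {
  pidx <- match(spikes_sm$patient_id, patients$patient_id)
  fam <- patients$family_id[pidx]
  trio <- patients$trio[pidx]
  male <- spikes_sm$sex == "male"
  on_x <- spikes_sm$chrom == "X"
  v <- data.frame(
    patient_id = spikes_sm$patient_id, family_id = fam, stage = "wes",
    kind = spikes_sm$kind, chrom = spikes_sm$chrom, pos = spikes_sm$pos,
    ref = spikes_sm$ref, alt = spikes_sm$alt, gene = spikes_sm$gene,
    transcript = spikes_sm$transcript,
    functional_class = spikes_sm$functional_class, cadd = spikes_sm$cadd,
    ds = spikes_sm$ds, af_gnomad = spikes_sm$af_gnomad,
    af_huabiao = spikes_sm$af_huabiao,
    exomiser_rank = spikes_sm$exomiser_rank,
    acmg_class = spikes_sm$acmg_class, spike = TRUE,
    stringsAsFactors = FALSE
  )
  g <- list()
  for (i in seq_len(nrow(spikes_sm))) {
    pid <- spikes_sm$patient_id[i]
    hemi <- on_x[i] && male[i]
    pro <- spike_depths(i, if (hemi) "hemi_alt" else "het")
    rows <- data.frame(
      family_id = fam[i], sample_id = pid, role = "proband",
      chrom = spikes_sm$chrom[i], pos = spikes_sm$pos[i],
      ref = spikes_sm$ref[i], alt = spikes_sm$alt[i],
      gt = if (hemi) "1/1" else "0/1",
      dp = unname(pro["dp"]), ad_alt = unname(pro["ad"]),
      stringsAsFactors = FALSE
    )
    if (trio[i]) {
      inh <- spikes_sm$inheritance[i]
      fa_kind <- if (inh == "paternal") "carrier_het" else "hom_ref"
      mo_kind <- if (inh %in% c("maternal", "hemizygous_maternal"))
        "carrier_het" else "hom_ref"
      fa <- spike_depths(i + 1L, fa_kind)
      mo <- spike_depths(i + 2L, mo_kind)
      rows <- rbind(rows,
        data.frame(family_id = fam[i],
                   sample_id = paste0(pid, "_fa"), role = "father",
                   chrom = spikes_sm$chrom[i], pos = spikes_sm$pos[i],
                   ref = spikes_sm$ref[i], alt = spikes_sm$alt[i],
                   gt = if (fa_kind == "carrier_het") "0/1" else "0/0",
                   dp = unname(fa["dp"]), ad_alt = unname(fa["ad"]),
                   stringsAsFactors = FALSE),
        data.frame(family_id = fam[i],
                   sample_id = paste0(pid, "_mo"), role = "mother",
                   chrom = spikes_sm$chrom[i], pos = spikes_sm$pos[i],
                   ref = spikes_sm$ref[i], alt = spikes_sm$alt[i],
                   gt = if (mo_kind == "carrier_het") "0/1" else "0/0",
                   dp = unname(mo["dp"]), ad_alt = unname(mo["ad"]),
                   stringsAsFactors = FALSE))
    }
    g[[i]] <- rows
  }
  list(variants = v, genotypes = do.call(rbind, g))
}

build_decoys <- function(config, patients, spikes_sm) {
  n_per <- config$decoy_variants_per_proband
  wes <- patients[patients$wes_enrolled, , drop = FALSE]
  if (!nrow(wes) || n_per == 0) {
    return(list(variants = empty_variant_table(),
                genotypes = empty_genotype_table()))
  }
  afd <- config$decoy_af_distribution
  spike_pos <- paste(spikes_sm$chrom, spikes_sm$pos)
  classes <- c("synonymous", "missense", "nonsense", "frameshift",
               "splicing", "intronic", "utr")
  class_p <- c(0.35, 0.40, 0.04, 0.02, 0.04, 0.10, 0.05)
  vs <- list(); gs <- list()
  for (i in seq_len(nrow(wes))) {
    pid <- wes$patient_id[i]
    repeat {
      chrom <- as.character(sample(1:22, n_per, replace = TRUE))
      pos <- sample.int(2e8, n_per) + 1e6L
      if (!any(paste(chrom, pos) %in% spike_pos) &&
            !anyDuplicated(paste(chrom, pos))) break
    }
    ref <- sample(c("A", "C", "G", "T"), n_per, replace = TRUE)
    alt_shift <- sample(1:3, n_per, replace = TRUE)
    alt <- c("A", "C", "G", "T")[(match(ref, c("A", "C", "G", "T")) - 1L +
                                    alt_shift) %% 4L + 1L]
    cls <- sample(classes, n_per, replace = TRUE, prob = class_p)
    fs <- cls == "frameshift"
    ref[fs] <- paste0(ref[fs], "C")
    cadd <- ifelse(stats::runif(n_per) < 0.5,
                   stats::runif(n_per, 0, 19.9),
                   stats::runif(n_per, 20, 40))
    cadd[cls %in% c("intronic", "utr")] <- NA_real_
    ds <- sample(0:10, n_per, replace = TRUE)
    absent <- stats::runif(n_per) < afd$p_absent
    af_g <- ifelse(absent, 0,
                   10^stats::runif(n_per, log10(afd$min), log10(afd$max)))
    af_h <- ifelse(absent, 0,
                   10^stats::runif(n_per, log10(afd$min), log10(afd$max)))
    spike_ranks <- spikes_sm$exomiser_rank[spikes_sm$patient_id == pid]
    rank_pool <- setdiff(seq_len(n_per + 40L), spike_ranks)
    ranks <- sample(rank_pool, n_per)
    acmg <- sample(c("B", "LB", "VUS"), n_per, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
    vs[[i]] <- data.frame(
      patient_id = pid, family_id = wes$family_id[i], stage = "wes",
      kind = ifelse(fs, "indel", "snv"), chrom = chrom,
      pos = as.integer(pos), ref = ref, alt = alt, gene = sprintf(
        "DGENE%03d", sample.int(300, n_per, replace = TRUE)),
      transcript = NA_character_, functional_class = cls, cadd = cadd,
      ds = as.integer(ds), af_gnomad = af_g, af_huabiao = af_h,
      exomiser_rank = as.integer(ranks), acmg_class = acmg, spike = FALSE,
      stringsAsFactors = FALSE
    )
    # genotypes: mostly clean hets, a few shallow or ratio-discordant
    # calls so the depth filter and recalibration have work to do
    dp <- sample(8:110, n_per, replace = TRUE)
    hom <- stats::runif(n_per) < 0.12
    ad <- ifelse(hom, dp - stats::rbinom(n_per, dp, 0.03),
                 stats::rbinom(n_per, dp, 0.5))
    gt <- ifelse(hom, "1/1", "0/1")
    pro <- data.frame(
      family_id = wes$family_id[i], sample_id = pid, role = "proband",
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gt = gt,
      dp = as.integer(dp), ad_alt = as.integer(pmin(ad, dp)),
      stringsAsFactors = FALSE
    )
    if (wes$trio[i]) {
      par_rows <- lapply(c("fa", "mo"), function(tag) {
        carrier <- stats::runif(n_per) < 0.35
        pdp <- sample(25:90, n_per, replace = TRUE)
        pad <- ifelse(carrier, stats::rbinom(n_per, pdp, 0.5),
                      stats::rbinom(n_per, pdp, 0.01))
        data.frame(
          family_id = wes$family_id[i],
          sample_id = paste0(pid, "_", tag),
          role = if (tag == "fa") "father" else "mother",
          chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
          gt = ifelse(carrier, "0/1", "0/0"),
          dp = as.integer(pdp), ad_alt = as.integer(pmin(pad, pdp)),
          stringsAsFactors = FALSE
        )
      })
      pro <- rbind(pro, par_rows[[1]], par_rows[[2]])
    }
    gs[[i]] <- pro
  }
  list(variants = do.call(rbind, vs), genotypes = do.call(rbind, gs))
}

build_pedigree <- function(patients) {
  wes <- patients[patients$wes_enrolled, , drop = FALSE]
  if (!nrow(wes)) {
    return(data.frame(family_id = character(0), sample_id = character(0),
                      father_id = character(0), mother_id = character(0),
                      sex = integer(0), phenotype = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(wes)), function(i) {
    pid <- wes$patient_id[i]
    pro <- data.frame(
      family_id = wes$family_id[i], sample_id = pid,
      father_id = if (wes$trio[i]) paste0(pid, "_fa") else "0",
      mother_id = if (wes$trio[i]) paste0(pid, "_mo") else "0",
      sex = if (wes$sex[i] == "male") 1L else 2L, phenotype = 2L,
      stringsAsFactors = FALSE
    )
    if (!wes$trio[i]) return(pro)
    rbind(pro,
          data.frame(family_id = wes$family_id[i],
                     sample_id = paste0(pid, "_fa"), father_id = "0",
                     mother_id = "0", sex = 1L, phenotype = 1L,
                     stringsAsFactors = FALSE),
          data.frame(family_id = wes$family_id[i],
                     sample_id = paste0(pid, "_mo"), father_id = "0",
                     mother_id = "0", sex = 2L, phenotype = 1L,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

build_cnv_table <- function(spikes_cnv, patients) {
  data.frame(
    patient_id = spikes_cnv$patient_id,
    family_id = patients$family_id[match(spikes_cnv$patient_id,
                                         patients$patient_id)],
    chrom = spikes_cnv$chrom, start = spikes_cnv$start,
    end = spikes_cnv$end, type = spikes_cnv$type, gene = spikes_cnv$gene,
    acmg_class = spikes_cnv$acmg_class,
    inheritance = spikes_cnv$inheritance, stringsAsFactors = FALSE
  )
}

build_manifest <- function(spikes_sm, spikes_cnv) {
  rbind(
    data.frame(
      patient_id = spikes_sm$patient_id, kind = spikes_sm$kind,
      key = variant_key(spikes_sm$chrom, spikes_sm$pos, spikes_sm$ref,
                        spikes_sm$alt),
      gene = spikes_sm$gene, expected_fate = spikes_sm$expected_fate,
      acmg_class = spikes_sm$acmg_class,
      inheritance = spikes_sm$inheritance, stringsAsFactors = FALSE
    ),
    data.frame(
      patient_id = spikes_cnv$patient_id, kind = "cnv",
      key = sprintf("%s:%d-%d:%s", spikes_cnv$chrom, spikes_cnv$start,
                    spikes_cnv$end, spikes_cnv$type),
      gene = spikes_cnv$gene, expected_fate = spikes_cnv$expected_fate,
      acmg_class = spikes_cnv$acmg_class,
      inheritance = spikes_cnv$inheritance, stringsAsFactors = FALSE
    )
  )
}
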