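#' Attach inheritance calls to the cohort variant table
#'
#' Exome-stage variants are joined with the (QC'd) family genotypes and
#' receive trio inheritance calls via [assign_inheritance_table()];
#' panel-stage variants, for which no parental data exist, are marked
#' `uncertain` with all models assumed.  Exome variants whose proband
#' genotype was removed or re-called to hom-ref during QC drop out.
#'
#' @param variants cohort variant table (from a `crs_cohort` bundle).
#' @param genotypes QC'd long genotype table.
#' @param pedigree pedigree table.
#' @return variant table with `proband_gt`, `mode`, `models`, `assumed`,
#'   `comp_het_partner` columns.
#' @export
annotate_inheritance <- function(variants, genotypes, pedigree) {
  wes <- variants[variants$stage == "wes", , drop = FALSE]
  panel <- variants[variants$stage == "panel", , drop = FALSE]
  wes <- assign_inheritance_table(wes, genotypes, pedigree)
  if (nrow(panel)) {
    panel$proband_gt <- "0/1"
    panel$mode <- "uncertain"
    panel$models <- paste(INHERITANCE_MODELS, collapse = ",")
    panel$assumed <- TRUE
    panel$comp_het_partner <- NA_character_
  } else {
    panel <- wes[rep(1, 0), , drop = FALSE]
  }
  out <- rbind(panel, wes)
  rownames(out) <- NULL
  out
}

#' Cohort-level yield and association statistics
#'
#' Computes the headline statistics of a triaged cohort: overall and
#' stage-wise diagnostic yields, yields by clinical group, the count of
#' distinct causal P/LP variants, per-gene contributions, the one-tailed
#' exact test for syndromic versus non-syndromic yield, and the exact
#' (or Monte-Carlo) test across suture-fusion types.
#'
#' @param outcomes outcome table from [triage_cohort()].
#' @param patients patient table.
#' @param suture_monte_carlo Monte-Carlo draws for the suture-type r x c
#'   test when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list of summaries (see details in the returned names).
#' @export
compute_cohort_stats <- function(outcomes, patients,
                                 suture_monte_carlo = 2000L, seed = 1L) {
  overall <- summarize_yields(outcomes, patients, "overall")
  stage <- summarize_yields(outcomes, patients, "stage")
  syn <- summarize_yields(outcomes, patients, "syndromic_status")
  suture <- summarize_yields(outcomes, patients, "suture_type")
  genes <- gene_contributions(outcomes)
  causal <- unlist(split_tags(outcomes$causal_variants[
    outcomes$status == "positive"]))
  distinct_plp <- length(unique(causal))

  syn_tab <- matrix(c(
    syn$n_positive[syn$group == "syndromic"],
    syn$n_total[syn$group == "syndromic"] -
      syn$n_positive[syn$group == "syndromic"],
    syn$n_positive[syn$group == "nonsyndromic"],
    syn$n_total[syn$group == "nonsyndromic"] -
      syn$n_positive[syn$group == "nonsyndromic"]
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("syndromic", "nonsyndromic"),
                  c("positive", "negative")))
  p_syn <- fisher_exact(syn_tab, "one_tailed_greater")

  suture_tab <- do.call(cbind, lapply(seq_len(nrow(suture)), function(i) {
    c(suture$n_positive[i], suture$n_total[i] - suture$n_positive[i])
  }))
  colnames(suture_tab) <- suture$group
  p_suture <- if (ncol(suture_tab) >= 2 && sum(suture_tab) > 0) {
    fisher_rxc(suture_tab, monte_carlo = suture_monte_carlo, seed = seed)
  } else {
    list(p_value = NA_real_, method = "not_applicable")
  }

  list(overall = overall, stage = stage, syndromic = syn, suture = suture,
       gene_contributions = genes, distinct_plp_variants = distinct_plp,
       syndromic_table = syn_tab, p_syndromic_one_tailed = p_syn,
       suture_test = p_suture)
}

#' Run the whole workflow on one configuration
#'
#' Executes, in order: cohort simulation, genotype quality control
#' (depth filter and depth-ratio re-calling), inheritance assignment with
#' compound-heterozygote pairing, stage-wise diagnostic triage, the
#' two-part research pipeline, cohort statistics, and the tiered cost
#' comparison built from the triage tallies.
#'
#' @param config a [cohort_config()].
#' @param thresholds a [filter_thresholds()].
#' @param catalog candidate-gene catalog; defaults to the bundled one.
#' @param min_depth QC depth cutoff.
#' @param panel_price,wes_price per-trio prices for the cost comparison.
#' @return list with the bundle and every stage's output: `qc`,
#'   `variants` (inheritance-annotated), `comp_het_pairs`, `triage`,
#'   `research`, `stats`, `cost`.
#' @export
run_cohort_workflow <- function(config = cohort_config(),
                                thresholds = filter_thresholds(),
                                catalog = crs_builtin_catalog(),
                                min_depth = 10,
                                panel_price = 315, wes_price = 945) {
  bundle <- generate_cohort(config)
  qc <- qc_genotypes(bundle$genotypes, min_depth)
  variants <- annotate_inheritance(bundle$variants, qc$genotypes,
                                   bundle$pedigree)
  pairs <- pair_compound_hets(variants[variants$stage == "wes", ,
                                       drop = FALSE])
  triage <- triage_cohort(variants, bundle$cnvs, bundle$patients, catalog)
  research <- run_research_pipeline(
    variants[variants$stage == "wes" &
               variants$kind %in% c("snv", "indel"), , drop = FALSE],
    catalog, thresholds)
  stats <- compute_cohort_stats(triage$outcomes, bundle$patients,
                                seed = config$seed)
  spec <- strategy_cost_spec(
    panel_price = panel_price, wes_price = wes_price,
    n_panel_pos = triage$tallies$panel_positive,
    n_wes_pos = triage$tallies$wes_positive,
    n_both_neg = triage$tallies$both_negative
  )
  cost <- list(panel_first = cost_panel_first(spec),
               wes_only = cost_wes_only(spec),
               comparison = compare_strategies(spec), spec = spec)
  list(bundle = bundle, qc = qc, variants = variants,
       comp_het_pairs = pairs, triage = triage, research = research,
       stats = stats, cost = cost)
}

#' Run the workflow and serialize every stage to a directory
#'
#' Stage outputs are written as tab-separated tables (plus the JSON
#' manifest of the simulated cohort and a JSON statistics block), and a
#' run manifest with the configuration digest, seed and per-file MD5
#' digests is returned and written as `run_manifest.json`.  Re-running
#' with identical configuration and seed yields identical digests.
#'
#' @inheritParams run_cohort_workflow
#' @param out_dir output directory.
#' @return the run manifest, invisibly.
#' @export
run_all <- function(config = cohort_config(), out_dir,
                    thresholds = filter_thresholds(),
                    catalog = crs_builtin_catalog(), min_depth = 10,
                    panel_price = 315, wes_price = 945) {
  res <- run_cohort_workflow(config, thresholds, catalog, min_depth,
                             panel_price, wes_price)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(res$bundle, file.path(out_dir, "cohort"))
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  }
  wt(res$qc$log, "qc_log.tsv")
  wt(res$variants, "variants_inheritance.tsv")
  wt(res$triage$outcomes, "triage_outcomes.tsv")
  wt(res$research, "research_candidates.tsv")
  wt(res$stats$gene_contributions, "gene_contributions.tsv")
  stats_block <- list(
    tallies = res$triage$tallies,
    overall = res$stats$overall, stage = res$stats$stage,
    syndromic = res$stats$syndromic,
    distinct_plp_variants = res$stats$distinct_plp_variants,
    p_syndromic_one_tailed = res$stats$p_syndromic_one_tailed,
    suture_test = res$stats$suture_test,
    cost = list(
      panel_first = res$cost$panel_first, wes_only = res$cost$wes_only,
      comparison = res$cost$comparison
    )
  )
  jsonlite::write_json(stats_block, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "run_manifest.json"))
  manifest <- list(
    tool = paste0("crstrio ",
                  as.character(utils::packageVersion("crstrio"))),
    seed = config$seed,
    config_digest = unname(tools::md5sum(file.path(out_dir, "cohort",
                                                   "config.json"))),
    stages = c("simulate", "qc", "inherit", "diagnose", "research",
               "stats", "cost"),
    files = as.list(stats::setNames(unname(tools::md5sum(
      file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
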