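# crstrio

Post-annotation analysis workflow for tiered genetic testing of
craniosynostosis (CRS) cohorts sequenced as parent–child trios.

Craniosynostosis — premature fusion of one or more cranial sutures —
is genetically heterogeneous: a compact panel of core genes (*FGFR2*,
*FGFR3*, *TWIST1*, *TCF12*, *EFNB1*, …) resolves roughly half of the
patients, and whole-exome sequencing (WES) of the panel-negative
remainder adds further diagnoses and research candidates.  `crstrio`
implements the analysis layer of such a two-tier programme for users
who already have annotated variant calls: genotype quality control,
trio inheritance assignment, diagnostic triage, candidate-variant
discovery, cohort statistics, and the economics of tiered testing.
It is aimed at clinical-genetics analysts and methodologists who want
the whole post-annotation pipeline reproducible and testable on a
synthetic cohort before pointing it at patient data.

## What it computes

* **Genotype QC** — sites with total depth `DP < 10` are removed
  per sample; remaining genotypes are re-called from the depth ratio of
  the alternative allele, `DPRA = AD_alt / DP`:

  `DPRA < 0.3 → 0/0`,  `0.3 ≤ DPRA ≤ 0.7 → 0/1`,  `DPRA > 0.7 → 1/1`,

  with boundary comparisons done in exact integer arithmetic.
* **Trio inheritance** — each proband variant is labelled de novo,
  paternal, maternal, biparental-homozygous, hemizygous-maternal (male
  X) or uncertain, with the set of compatible genetic models
  (AD/AR/XLD/XLR); heterozygous variants of one gene with one paternal
  and one maternal allele are paired as compound heterozygotes.
* **Diagnostic triage** — ACMG classes (P/LP/VUS/LB/B) arrive as
  annotations; a patient is positive iff they carry a P/LP variant
  whose inheritance fits the gene's OMIM model (one allele for
  dominant/X-linked genes, two alleles for recessive-only genes, or a
  P/LP CNV over a catalog gene).  A lone heterozygous P/LP allele in a
  recessive-only gene is explicitly negative.
* **Research pipeline** — part one keeps loss-of-function variants
  plus scored protein-altering variants (deleterious score ≥ 4 or
  CADD ≥ 20) below model-specific allele-frequency ceilings
  (dominant: ≤ 5·10⁻⁵ gnomAD, ≤ 5·10⁻⁴ Huabiao; recessive/X: ≤ 10⁻³ /
  5·10⁻³); part two keeps the top-20 phenotype-prioritized variants;
  the parts are intersected, then candidate-gene membership and OMIM
  model concordance are required.
* **Cohort statistics** — diagnostic yields with half-up rounding,
  per-gene contributions, and exact conditional contingency tests
  (hypergeometric 2×2 Fisher with point-probability two-tailed
  convention; exact r×c by enumeration with a seeded Monte-Carlo
  fallback).
* **Cost model** — per-trio and total costs of "Panel-first" versus
  "WES-only" strategies (and arbitrary k-tier strategies) from
  per-test prices and stage-outcome counts.
* **Synthetic cohort generator** — a seeded, fully self-contained
  fixture cohort (patients, pedigrees, per-family VCFs, annotations,
  CNVs, spike-in manifest) emulating a 264-patient two-stage testing
  history, with known diagnostic and candidate payloads spiked into
  the exome stage plus a configurable decoy background.

## Worked example

```r
library(crstrio)

wf <- run_cohort_workflow(cohort_config(seed = 1))

wf$triage$tallies
#> $panel_positive  139
#> $wes_positive     10
#> $both_negative    92
#> $not_tested       23

wf$stats$stage
#>   group n_total n_positive yield_percent
#> 1 panel     264        139          52.7
#> 2   wes     264         10           3.8

wf$stats$overall
#>     group n_total n_positive yield_percent
#> 1 overall     264        149          56.4

wf$stats$distinct_plp_variants
#> [1] 69

wf$stats$p_syndromic_one_tailed   # syndromic 79.8% vs non-syndromic 18.8%
#> [1] 3.781513e-23

sum(wf$research$final)            # 7 P/LP small variants + 15 candidates
#> [1] 22

wf$cost$comparison
#> $per_trio_panel_first 715
#> $per_trio_wes_only    945
#> $saving_per_trio      230
#> $saving_percent       24.3
```

Reading the output: the panel resolves 139 of 264 patients (52.7%);
exome sequencing of the panel-negative remainder adds 10 diagnoses
(3.8 points of incremental yield) for a 56.4% overall yield across 69
distinct P/LP variants; the research pipeline recovers every
diagnostic small variant and 15 candidate variants; and running the
panel before the exome saves $230 per trio (24.3%) at identical yield.

A command-line wrapper with `simulate`, `qc`, `inherit`, `diagnose`,
`research`, `stats`, `cost` and `run-all` subcommands is installed at
`system.file("scripts", "crstrio.R", package = "crstrio")`; every stage
reads and writes plain tab-separated tables so any step can be replaced
by an external tool's output.

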