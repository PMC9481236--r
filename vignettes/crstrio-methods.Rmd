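---
title: "crstrio: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crstrio: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crstrio)
```

`crstrio` models the analysis layer of a two-tier genetic-testing
programme for craniosynostosis (CRS): a compact gene panel first, then
whole-exome sequencing (WES) of panel-negative patients, with trio
designs where parents are available.  This vignette explains the
procedures, the tunable parameters, what the synthetic cohort does and
does not emulate, and the design choices made where the problem was
genuinely open.

## Genotype quality control

Two post-calling steps are applied to each sample's small-variant
calls.

1. **Depth filter.** Calls with total depth below `min_depth`
   (default 10 reads) are removed.  The filter acts per sample; a site
   is dropped for an entire family only when the *proband's* call
   fails, so adequately covered parental evidence is never discarded
   because of an unrelated shallow call.  This family rule is our
   choice: the alternative (drop the site whenever any member fails)
   needlessly destroys inheritance information.
2. **Depth-ratio re-calling.** The genotype is replaced by the one
   implied by the depth ratio of the alternative allele
   (DPRA = alt-allele depth / total depth): below 0.3 homozygous
   reference, 0.3–0.7 (both ends inclusive) heterozygous, above 0.7
   homozygous alternative.  Comparisons use exact integer arithmetic
   (`10·AD` against `3·DP` and `7·DP`), so boundary depths such as
   21/70 are classified identically on every platform.  Re-calling is
   idempotent.  A missing genotype stays missing: we deliberately do
   not let read ratios resurrect a no-call, because a caller's no-call
   usually encodes evidence the two depth numbers do not carry.

## Trio inheritance and compound heterozygotes

Each proband variant receives a mode (de novo, paternal, maternal,
biparental-homozygous, hemizygous-maternal, uncertain) and a set of
genetic models (AD, AR, XLD, XLR) that the observation is compatible
with.  Three conventions matter:

* **Proband-only cases.** With no parental genotypes, the mode is
  `uncertain` and *every* model is carried forward, flagged as
  assumed.  Downstream filters then evaluate the variant under each
  assumed model; this is the only defensible reading when parents are
  unavailable, and it mirrors how proband-only exomes are analysed in
  practice.
* **Mendelian inconsistencies.** A homozygous-alternative proband
  with a homozygous-reference parent can arise *after* depth-ratio
  re-calling; such calls are kept as `uncertain` for review rather
  than discarded, since discarding them would silently hide re-calling
  artefacts.
* **Phase by transmission only.** Compound-heterozygote pairs are
  formed from two heterozygous variants of one gene with one paternal
  and one maternal allele; no read-backed or statistical phasing is
  attempted.  Every cross-parent combination is emitted (a variant may
  sit in several candidate pairs), and pairs are retained or dropped
  as a unit by later filters.

## Diagnostic triage

ACMG pathogenicity classes (P, LP, VUS, LB, B) are *inputs*: the
package does not re-implement evidence-code classification, which in
the modelled workflow involves manual curation.  Triage is the
inheritance-consistency layer on top: one P/LP allele suffices in a
gene with a dominant or X-linked-dominant model, an X-linked-recessive
gene accepts an effectively hemizygous or unresolved allele, and a
recessive-only gene demands two P/LP alleles (homozygous or a
compound-heterozygous pair).  A lone heterozygous P/LP allele in a
recessive-only gene is negative with rationale
`single_allele_ar_insufficient` — the CDC45-type situation.  VUS
never contributes.  Genes carrying both dominant and recessive models
accept a single allele, consistent with reported monoallelic
diagnoses in such genes.  An unresolved inheritance mode never blocks
positivity: real cohorts report diagnostic variants with uncertain
inheritance, so triage must not require a resolved trio.

P/LP CNVs are diagnostic when they overlap a catalog gene; overlap is
evaluated on the CNV's annotated gene symbol because interval-level
gene models are deliberately out of scope.

## Research pipeline

The candidate-discovery pipeline has two automatic parts whose results
are intersected, then two knowledge-based gates.

**Part one** retains loss-of-function variants (frameshift, nonsense,
splicing) unconditionally and scored protein-altering variants with
deleterious score ≥ `ds_min` (default 4) or CADD ≥ `cadd_min`
(default 20).  In-frame indels are scored like missense: they alter
protein without truncating it, and a diagnostic in-frame deletion
would otherwise be invisible to a pure LoF-plus-missense rule — this
is a deliberate widening of the classic formulation, without which the
pipeline could not recall one of its own diagnostic indels.  The
allele-frequency gate is model-specific and inclusive: dominant
evaluations require ≤ 5·10⁻⁵ (gnomAD) and ≤ 5·10⁻⁴ (Huabiao),
corresponding to allele counts of roughly 20/141,456 and 5/5,000;
recessive and X-linked evaluations default to ≤ 10⁻³ and ≤ 5·10⁻³.
The recessive ceilings are not part of the classic description; we
scale the dominant ones by the same factor that separates the two
databases and expose them as configuration.  Absent frequencies count
as zero.  The deleterious score is treated as an opaque integer
summary of predictor votes; its scale is defined by the upstream
annotation, not by this package.

**Part two** is the phenotype-driven prioritizer: ranks (e.g.
Exomiser hiPhive output) are an input column, one ranking per proband
across all genes, and the top `rank_max = 20` are kept — "top 20" is
read per proband, matching how variant-ranked prioritizer output is
consumed.  Unranked variants cannot enter part two.  The package does
not re-implement the prioritizer.

After the intersection, variants must hit the candidate-gene catalog
(synonym-aware, case-insensitive) and their surviving models must
intersect the gene's OMIM models; a *resolved* single heterozygous
allele cannot satisfy a recessive-only gene, while assumed calls are
given the benefit of the doubt.  Finally a manual-review stand-in
flags (never silently deletes) likely-benign/benign variants and genes
on a review exclusion list (default `APC`, whose disease association
is oncological); review exclusions are a flag column because the
modelled step is human judgement, not an algorithm.

Tightening any threshold can only shrink the final set; this
anti-monotonicity is tested property-style.

## Gene catalog

The catalog is built from flat tab-separated source files (literature
list with OMIM models, HPO craniosynostosis and abnormal-skull gene
sets, PanelApp panels, a 17-gene core panel) with union semantics,
source provenance, and a flat synonym map resolved independently of
file order.  Live database queries are out of scope — they drift with
versions and break offline reproducibility — so the package ships a
compact fixture catalog containing the genes the synthetic cohort
exercises.  It is *not* a reconstruction of any full curated list
(the modelled programme used a 2,259-gene list); users supply their
own source files for real analyses.  Entries without model
annotations match no variant at the concordance gate, which is the
conservative failure mode.

## Statistics

Yields are percentages of patients with a positive diagnosis, rounded
half-up to one decimal (the convention that prints 139/264 as 52.7 and
149/264 as 56.4; banker's rounding would disagree on ties).  Stage
yields keep the whole cohort as denominator, so the exome stage's
figure is the *incremental* yield of the second tier.

The 2×2 exact test is the conditional hypergeometric test; one-tailed
p-values sum the tail in the stated direction, and the two-tailed
p-value uses the point-probability convention (sum of tables no more
probable than the observed one), matching mainstream statistical
software.  The r×c test enumerates all margin-fixed tables exactly
when the table count (computed in closed form for two-row tables) fits
the enumeration bound, and otherwise falls back to seeded Monte-Carlo
sampling from the conditional distribution with the add-one estimate,
reporting which method was used.  No multiple-testing correction is
applied, matching the modelled analysis.

On the default synthetic cohort the syndromic/non-syndromic 2×2 table
assembles to [[130, 33], [19, 82]] and the one-tailed p-value is
3.78·10⁻²³ — this is a consistency check of the test on
fixture-derived counts, not an independent estimate.  The per-suture
contingency table of the real programme is not recoverable from
printed group totals, so suture-type tests are exercised on synthetic
data only and carry no external expectation.

## The synthetic cohort

Because the modelled study's patient-level data are not public, the
generator encodes only printed aggregate structure plus the published
variant payloads, and invents everything else:

* 264 patients: 139 panel-resolved, 102 exome-enrolled (81 trios, 21
  proband-only), 23 lost to follow-up after a negative panel; 163
  syndromic / 101 non-syndromic with the published suture-type
  composition per group.  The syndromic split across stages (33
  exome-enrolled, 123 panel-resolved, hence 7 lost) is forced by the
  group-yield arithmetic and kept configurable.
* The exome stage carries ten diagnostic P/LP payloads (four SNVs,
  three indels, three TWIST1 deletions), fifteen candidate payloads in
  eleven genes (including the IL11RA and DNAH11 compound-heterozygous
  pairs), two potentially pathogenic non-diagnostic payloads (the
  single-allele CDC45 frameshift and the de novo SNRPB nonsense VUS)
  and one review-excluded APC variant.  Published coordinates, scores
  and ranks are used where printed; unprinted values (population
  frequencies everywhere; scores/ranks for the diagnostic set;
  coordinates for CDC45/SNRPB/APC) are synthetic, chosen once to be
  consistent with each variant's reported fate, and flagged as such.
  The SNRPB variant is assigned rank 25 — the only filter consistent
  with its absence from the candidate list — and the CDC45 allele
  fails at model concordance, mirroring its published reasoning.
* Panel-resolved patients carry one causal P/LP variant each, drawn
  from a pool of 59 distinct synthetic variants across nine panel
  genes (five recurrent core genes and four single-patient genes), so
  that both stages together yield 69 distinct P/LP variants in 16
  genes of which 11 contribute a single patient.  The per-gene panel
  composition is unprinted in the source material; these defaults are
  the generator's own choice and only their aggregates are asserted.
* Each exome proband receives 30 decoy variants (default) with
  log-uniform allele frequencies on [10⁻⁶, 0.5], a CADD mixture
  straddling 20, mixed consequence classes, benign/VUS classes, and
  per-proband prioritizer ranks disjoint from the spiked ranks.  Some
  decoy calls are shallow or ratio-discordant so QC has real work.
  Decoy genes are synthetic symbols absent from the catalog.

Spike-in payloads are constants: changing the seed changes only the
decoy background.  Counts in the study-condition columns reproduce the
configuration exactly, by construction, and the whole bundle is
bit-reproducible under a fixed seed, including its serialized form
(per-family VCF 4.2 with GT:DP:AD, 6-column PED, tab-separated
tables, JSON manifest).

What the generator does **not** emulate: raw reads and alignment
artefacts, linkage and haplotype structure, population stratification
of the decoy frequencies, capture chemistry of the panel, batch
effects in CNV calling, and phenotype term structure beyond the
per-patient suture/group labels.  Passing the end-to-end tests
therefore demonstrates that the *analysis logic* is correct under the
published aggregate conditions — not that the pipeline is robust to
the messiness of real sequencing data.

## Numerical conventions and problem sizes

* Allele-frequency, score and rank comparisons are inclusive.
* DPRA boundaries are exact rational comparisons on integer depths.
* Per-trio cost means are rounded half-up to whole currency units
  (172,305/241 → 715); percentage savings half-up to one decimal.
  Patients lost to follow-up are excluded from cost evaluation
  (241 evaluated trios), as a cost model should only price tests that
  were actually ordered.
* The r×c enumeration bound defaults to 2·10⁶ tables; the suite and
  the default workflow use 2,000 Monte-Carlo draws for the suture
  table, whose exact enumeration (~10⁹ tables) is out of proportion
  to its illustrative role.
* The default test and acceptance runs use the full 264-patient
  cohort with 30 decoys per proband (~3,100 exome variants, ~8,000
  genotype rows), which keeps any single stage under a few seconds.

## Known limitations

* The ACMG classification and the phenotype prioritizer are consumed,
  not computed; the pipeline's recall is therefore conditional on the
  quality of those inputs.
* CNV handling is annotation-level (gene symbol, class); no interval
  arithmetic against transcript models is performed.
* The catalog ships as a fixture; real analyses should supply
  version-pinned source files.
* Source descriptions of the diagnostic small-variant count disagree
  internally (seven versus nine P/LP SNVs/indels); the generator and
  the recall checks use seven, the count consistent with the itemised
  payload table.
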