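---
title: "Classifying cancer-specific splice junctions against panels of normals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer-specific splice junctions against panels of normals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juncnov)
library(dplyr)
```

## The problem

Tumor RNA-seq produces exon–exon junctions that are absent from reference
annotation, and such "novel" junctions are attractive as tumor markers and as
sources of candidate neoantigens. But novelty is relative to the comparison
set: a junction absent from the tissue-matched normal samples of one cancer
type may be routinely spliced in another adult tissue, in placental,
embryonic or fetal cells, or in stem cells — contexts in which the immune
system may already have seen the resulting peptides. `juncnov` implements a
hierarchical cancer-specificity analysis over junction evidence from many
cohorts at once: tumor cohorts, a pan-tissue panel of normals, and auxiliary
non-cancer categories grouped as adult, developmental (with placenta as its
own subset), and stem cell.

Junctions are identified by their intron in 0-based closed coordinates —
`start` is the first intronic base and `end` the last — keyed as
`chrom:start-end(strand)`. Unknown strand (`*`) is a distinct key: collapsing
unstranded evidence onto a strand would fabricate information the antisense
analysis depends on.

## The filter hierarchy

Every junction with evidence in a cancer cohort is assigned the highest stage
whose exclusion condition holds:

| stage | definition |
|-------|------------|
| `0`   | all junctions of the cohort |
| `1+`  | not found in the cohort's tissue-matched normal samples |
| `2+`  | not found in *any* core normal sample (all normal tissues plus every cancer cohort's matched normals) |
| `3+`  | additionally not found in any selected non-cancer auxiliary sample |

Two deliberate strictness choices follow the analysis this package
implements. First, a single read in a single sample of a comparison set
counts as presence — there is no coverage threshold on the normal side,
because the cancer-specific designation should not survive any observed
normal usage. Second, the only global evidence requirement is two reads
summed across *all* samples of *all* cohorts, with no per-sample minimum, so
a junction supported by one read in each of two samples is kept. Cohorts
without tissue-matched normals skip stage `1+` and are classed `0` versus
`2+` directly.

Downstream, stage-`2+` junctions are assigned to evidence sets by auxiliary
category. A junction with no adult, developmental, placental or stem-cell
evidence is *unexplained*. Placenta is kept outside the developmental flag:
placenta-only evidence marks a junction explained but not developmental. A
conservative alternative ("two-sample rule") requires two positive samples
across a broad group, with a one-sample exception for developmental subsets
once the group-wide criterion is met; its sets are provably subsets of the
default rule's, so its unexplained class is a superset. Matched auxiliary
*cancer* cohorts never affect unexplained status — they are replication
evidence, feeding only the sharedness comparison.

## Parameters that matter

* `min_total_reads` (default 2): the global evidence floor, in reads summed
  over every sample.
* Panel selection (defaults 1% and 200): a cohort's shared panel is the up
  to 200 most recurrent stage-`2+` junctions at within-cohort prevalence
  ≥ 1%, both bounds inclusive. Ties in the positive-sample count are broken
  by genomic order (chromosome, start, end ascending) — the recurrence rule
  alone does not determine the 200th member, and a deterministic tie-break
  makes panels reproducible byte-for-byte.
* Cross-cohort sharing (defaults 5% and 2 cohorts): a junction is
  cross-cohort shared when its prevalence reaches the threshold in at least
  `min_cohorts` cancer cohorts, inclusive.
* The tissue-match map is configuration, not inference: each cancer cohort
  names its matched normal cohorts, possibly none.

"Average across cancer types" summaries are unweighted (macro) means over
cohorts, each cohort contributing one value; a junction present in several
cohorts contributes one observation per cohort.

## What the generator emulates

`simulate_cohorts()` plants a mutually exclusive truth category per junction
— tissue-matched normal, other core normal, auxiliary adult / developmental
/ placenta / stem, or unexplained — and only emits reads in cohorts that
category permits, so category recovery by the pipeline is exact and all
residual disagreement in recovery tests is the sampling noise of the
category draw. Default fractions encode the cohort structure the analysis
targets: 90% of cancer junctions present in core normals, split 0.50
tissue-matched / 0.40 other-core so that 80% of junctions passing the
tissue-matched comparison are explained by other normals; among the
remaining cancer-specific junctions 26% adult, 15% developmental, 3% stem,
2% placenta-only and the rest unexplained; 53% of cancer-specific junctions
confined to a single tumor sample; 40% antisense and 4.8% in
cancer-associated loci among unexplained junctions (5% and 3% respectively
elsewhere, since explained junctions show far less antisense usage).

Mechanics, chosen once:

* Per-sample inclusion is i.i.d. Bernoulli at the junction's drawn
  prevalence (spectrum default: 4%, 8%, 15%, 40% with weights 0.35, 0.40,
  0.15, 0.10), the simplest model consistent with a prevalence definition.
  Non-singleton cancer-specific junctions are conditioned on at least two
  positive tumor samples so the planted singleton fraction is realized
  exactly; explained junctions are conditioned on at least one.
* Read counts per positive sample are zero-truncated Poisson(λ = 3),
  producing realistic low-coverage evidence including single-read samples.
  The single tumor read of a non-low-evidence singleton is conditioned to
  ≥ 2 so it clears the global filter by design rather than by luck.
* Low-evidence junctions (5% extra) carry exactly one read in one tumor
  sample and exist to exercise the global filter; they are appended beyond
  the nominal junction count so the planted category proportions are
  undisturbed.
* The synthetic genome is a single chromosome `chrS` of non-overlapping
  plus-strand protein-coding genes (200-bp exons on a 1-kb pitch; later
  transcripts skip an internal exon). Antisense junctions are planted on the
  minus strand inside gene boundaries; coordinates are allocated on disjoint
  arithmetic progressions per planting family, which guarantees key
  uniqueness and keeps planted annotation status and gene context exact.
  Every seventh gene is designated cancer-associated; annotated-junction
  plants avoid those genes so the cancer-locus flag stays an independent
  truth.
* One master seed with fixed per-table offsets: any single table can be
  regenerated alone, and identical configs give byte-identical outputs.

What it does **not** emulate: overlapping and nested gene structures,
multi-chromosome genomes (except on request), strand-ambiguous evidence
correlated with gene context, batch effects, coverage–prevalence coupling,
category co-occurrence (real junctions can be both developmental and adult),
or any read-level process — the pipeline consumes pre-called junctions.
Passing recovery tests therefore demonstrates correctness of the filtering
and accounting machinery, not robustness to the messiness of real cohort
data.

## Cohort statistics

* Sharedness comparisons use the Kruskal–Wallis rank test with tie
  correction and the 1-df chi-squared approximation; junction prevalence is
  far from normal and group sizes are very unequal, which this test
  tolerates. At total n around 6–8 the approximation's absolute error
  against the exact permutation law can reach ~0.2 (the tests document
  this); it is used at hundreds of junctions and above.
* Junction burden is `n / (mapped_reads / 10000)` — a per-Mb scaling under
  100-bp reads — regressed on tumor mutational burden (silent plus
  non-silent mutations per Mb) by ordinary least squares.
* Patients are stratified by splicing-gene mutation status under two
  criteria: a supplied splicing-annotation gene list, and the fixed
  five-gene sQTL set (`U2AF1`, `SF3B1`, `TADA1`, `PPP2R1A`, `IDH1`,
  overridable). Only non-synonymous calls count. Counts are assessed by
  two-way ANOVA (cancer type × mutation status); we fit *with* the
  interaction term and report it alongside the main effects, flagged
  non-normative since the factorial decomposition does not dictate it.
  Benjamini–Hochberg correction is applied within each stratification
  criterion across its family of reported per-cohort comparisons — the
  conservative, reproducible reading of "BH-corrected".
* Recurrent-junction concentration in mutated patients uses a two-sided
  Fisher's exact test on the patient-level 2×2 table; junctions must occur
  in at least two patients of the cohort, and the unit is patients, not
  samples. A zero margin yields p = 1 with an explicit flag.
* Survival uses the Kaplan–Meier product-limit estimate with deaths at
  days-to-death and all other patients censored at days-to-last-follow-up;
  patients with neither field are excluded with a warning.

## Numerical and design choices

* **Store.** The working container is an in-memory set of three linked
  tables (evidence, samples, junctions); `write_store()` persists it as a
  single-file SQLite database with indexes on the junction-ID and sample-ID
  columns for ad-hoc querying. Loading the same evidence twice is a no-op;
  conflicting read counts for one (junction, sample) pair keep the maximum
  with a warning rather than silently summing, which would break
  idempotence.
* **Annotation.** "Annotated" means both splice sites belong to the same
  annotated junction; one-site matches are tracked separately. Gene
  boundaries are gene-level start/end (introns included). Sense overlap
  takes precedence over antisense; unknown-strand junctions inside a gene
  default to `protein_coding` (switchable), the conservative choice with
  respect to any antisense claim. A junction spanning two same-strand genes
  attaches all of them.
* **Degenerate inputs.** Identical values across both Kruskal–Wallis groups
  return H = 0, p = 1, flagged; constant TMB flags the regression rather
  than erroring; empty junction sets make the singleton fraction `NA` with a
  message; a cohort with no stage-`2+` junctions yields an empty, warned
  summary.
* **Scale.** Tests and the acceptance script run the generator at 4 cancer
  cohorts × 50 samples, 90 core normals, ~52 auxiliary samples and 2 000
  junctions, with recovery tolerances of three binomial standard errors at
  the relevant denominator — large enough that every planted fraction is
  identifiable, small enough to iterate on comfortably. Oracle-equivalence
  sweeps use 200 randomized studies of at most 50 junctions × 50 samples
  checked exactly against brute-force scans.
* **Clustering of prevalence heatmaps** is presentation only; no linkage or
  distance is validated, and none is asserted by tests.

## Worked example

```{r example}
cfg <- sim_config(seed = 7, n_junctions = 500)
sim <- simulate_cohorts(cfg)
store <- build_junction_store(sim$evidence, sim$phenotypes,
                              annotation = as_annotation_index(sim$annotation))
store <- apply_read_filter(store)
novelty <- assign_novelty(store, cfg$tissue_match_map)
count(novelty, cohort, stage)
```

```{r sets}
sets <- assign_sets(store, novelty, sra_cancer_map = cfg$sra_cancer_map)
upset_summary(sets) |> filter(kind == "set", cohort == "CANCER_01")
```

## Known limitations

The package consumes pre-called junction evidence and cannot compensate for
aligner-specific junction-calling differences, which are known to move the
identity of individual "novel" junctions substantially. The unknown-strand
policy, the tissue-match map, and the auxiliary category taxonomy are
configuration whose defaults are documented choices, not inferences. The
two-way ANOVA treats per-patient junction counts as approximately normal
within groups; for heavily skewed counts the per-cohort rank comparisons are
the more robust companion. No attempt is made to predict reading frames or
neoepitopes from junctions, and survival analysis is a single-factor
product-limit description, not an adjusted model.
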