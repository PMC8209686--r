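#' Simulation configuration for synthetic junction cohorts
#'
#' Defines the multi-cohort study the generator emulates: cancer cohorts with
#' tissue-matched and other core-normal cohorts, SRA-style auxiliary
#' categories partitioned into adult / developmental (including the placenta
#' subset) / stem broad groups, and per-junction planted ground truth
#' (category, prevalence, sharedness, gene context, annotation status).
#'
#' Default fractions encode the cohort structure the analysis was designed
#' around: 90% of cancer junctions present in core normals, split so that
#' 80% of those passing the tissue-matched comparison are explained by other
#' normals (0.50 tissue-matched + 0.40 other core normal); among the
#' remaining putatively cancer-specific junctions, 26% with adult SRA
#' evidence, 15% developmental (non-placenta), 3% stem, 2% placenta-only and
#' the remainder unexplained; 53% of cancer-specific junctions confined to a
#' single tumor sample; 40% antisense among unexplained junctions.
#'
#' Each junction's planted category is mutually exclusive, and emitted reads
#' appear only in cohorts the category permits, so downstream recovery is
#' exact up to the sampling noise of the category draw itself.
#'
#' @param seed Master seed; per-table substreams use fixed offsets.
#' @param n_cancer_cohorts Number of cancer cohorts. All but the last have a
#'   tissue-matched normal pair (a GTEx-style tissue plus a matched-normal
#'   cohort); the last has none, exercising the no-tissue-match path.
#' @param samples_per_cancer_cohort Samples per cancer cohort.
#' @param n_core_normal_samples Total core-normal samples, split evenly
#'   across the tissue and matched-normal cohorts.
#' @param sra_category_sizes Named integer vector of SRA category sample
#'   counts.
#' @param sra_category_groups Named character vector mapping each SRA
#'   category to its broad group (`adult`, `developmental`, `stem`); the
#'   category named `"placenta"` forms the placenta subset.
#' @param sra_cancer_map Named character vector: cancer cohort -> matched
#'   SRA cancer category (absent cohorts have no match).
#' @param sra_cancer_size Samples per matched SRA cancer category.
#' @param n_junctions Number of cancer junctions to plant.
#' @param frac_in_tissue_matched,frac_in_other_core_normal Fractions of
#'   junctions planted in tissue-matched / other core-normal cohorts.
#' @param frac_in_sra_by_group Named fractions (of the remaining
#'   cancer-specific junctions) planted with adult / developmental / stem /
#'   placenta SRA evidence; the unexplained fraction is the remainder.
#' @param prevalence_spectrum Data frame (`prevalence`, `weight`); weights
#'   must sum to 1. Per-sample inclusion is i.i.d. Bernoulli at the drawn
#'   prevalence.
#' @param frac_singleton Fraction of cancer-specific (stage-2+) junctions
#'   confined to exactly one tumor sample.
#' @param frac_multi_cohort Fraction of non-singleton junctions planted in
#'   two cancer cohorts.
#' @param frac_antisense_unexplained,frac_antisense_other Planted antisense
#'   fractions among unexplained / all other junctions.
#' @param frac_cancer_gene_unexplained,frac_cancer_gene_other Planted
#'   fractions of junctions placed (sense) in a cancer-associated gene.
#' @param frac_annotated,frac_one_site Fractions of sense protein-coding
#'   junctions reusing an annotated junction / sharing one annotated splice
#'   site.
#' @param read_count_model List (`family`, parameters); the default
#'   zero-truncated Poisson(lambda = 3) per positive sample produces
#'   realistic low-coverage evidence including single-read samples.
#' @param frac_singleton_reads Fraction of junctions whose total evidence is
#'   exactly one read (removed by the global two-read filter).
#' @param normal_prevalence Bernoulli inclusion rate within normal / SRA
#'   cohorts where a junction is planted present.
#' @param sra_cancer_presence Named probabilities (`nonsingleton`,
#'   `singleton`) that an eligible cancer-specific junction is replicated in
#'   the matched SRA cancer category — higher for shared junctions, planting
#'   the sharedness shift the replication test measures.
#' @param n_genes,transcripts_per_gene,exons_per_transcript Annotation
#'   geometry for [simulate_annotation()].
#' @param n_bone_marrow_excluded Leukemia-cell-line bone-marrow normals to
#'   emit (flagged for exclusion at load).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_cancer_cohorts = 4,
    samples_per_cancer_cohort = 50,
    n_core_normal_samples = 90,
    sra_category_sizes = c(epithelial = 8, fibroblast = 8, blood = 8,
                           embryo = 6, fetus = 6, placenta = 6,
                           esc = 5, ipsc = 5),
    sra_category_groups = c(epithelial = "adult", fibroblast = "adult", blood = "adult",
                            embryo = "developmental", fetus = "developmental",
                            placenta = "developmental",
                            esc = "stem", ipsc = "stem"),
    sra_cancer_map = NULL,
    sra_cancer_size = 10,
    n_junctions = 2000,
    frac_in_tissue_matched = 0.50,
    frac_in_other_core_normal = 0.40,
    frac_in_sra_by_group = c(adult = 0.26, developmental = 0.15,
                             stem = 0.03, placenta = 0.02),
    prevalence_spectrum = data.frame(
      prevalence = c(0.04, 0.08, 0.15, 0.40),
      weight = c(0.35, 0.40, 0.15, 0.10)
    ),
    frac_singleton = 0.53,
    frac_multi_cohort = 0.15,
    frac_antisense_unexplained = 0.40,
    frac_antisense_other = 0.05,
    frac_cancer_gene_unexplained = 0.048,
    frac_cancer_gene_other = 0.03,
    frac_annotated = 0.25,
    frac_one_site = 0.10,
    read_count_model = list(family = "ztpois", lambda = 3),
    frac_singleton_reads = 0.05,
    normal_prevalence = 0.3,
    sra_cancer_presence = c(nonsingleton = 0.6, singleton = 0.1),
    n_genes = 120,
    transcripts_per_gene = 2,
    exons_per_transcript = 5,
    n_bone_marrow_excluded = 2) {

  cancer_cohorts <- sprintf("CANCER_%02d", seq_len(n_cancer_cohorts))
  n_matched <- max(n_cancer_cohorts - 1, 0)
  tissue_cohorts <- sprintf("TISSUE_%02d", seq_len(n_matched))
  matched_cohorts <- sprintf("MATCHED_%02d", seq_len(n_matched))
  tissue_match_map <- stats::setNames(
    c(map(seq_len(n_matched), ~ c(tissue_cohorts[.x], matched_cohorts[.x])),
      rep(list(character(0)), n_cancer_cohorts - n_matched)),
    cancer_cohorts
  )
  if (is.null(sra_cancer_map) && n_cancer_cohorts >= 2) {
    sra_cancer_map <- stats::setNames(
      sprintf("SRA_CANCER_%02d", 1:2), cancer_cohorts[1:2]
    )
  }

  cfg <- structure(list(
    seed = as.integer(seed),
    cancer_cohorts = cancer_cohorts,
    samples_per_cancer_cohort = samples_per_cancer_cohort,
    tissue_cohorts = tissue_cohorts,
    matched_cohorts = matched_cohorts,
    n_core_normal_samples = n_core_normal_samples,
    tissue_match_map = tissue_match_map,
    sra_category_sizes = sra_category_sizes,
    sra_category_groups = sra_category_groups,
    sra_cancer_map = sra_cancer_map,
    sra_cancer_size = sra_cancer_size,
    n_junctions = n_junctions,
    frac_in_tissue_matched = frac_in_tissue_matched,
    frac_in_other_core_normal = frac_in_other_core_normal,
    frac_in_sra_by_group = frac_in_sra_by_group,
    prevalence_spectrum = as_tibble(prevalence_spectrum),
    frac_singleton = frac_singleton,
    frac_multi_cohort = frac_multi_cohort,
    frac_antisense_unexplained = frac_antisense_unexplained,
    frac_antisense_other = frac_antisense_other,
    frac_cancer_gene_unexplained = frac_cancer_gene_unexplained,
    frac_cancer_gene_other = frac_cancer_gene_other,
    frac_annotated = frac_annotated,
    frac_one_site = frac_one_site,
    read_count_model = read_count_model,
    frac_singleton_reads = frac_singleton_reads,
    normal_prevalence = normal_prevalence,
    sra_cancer_presence = sra_cancer_presence,
    n_genes = n_genes,
    transcripts_per_gene = transcripts_per_gene,
    exons_per_transcript = exons_per_transcript,
    n_bone_marrow_excluded = n_bone_marrow_excluded
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fracs <- c(cfg$frac_in_tissue_matched, cfg$frac_in_other_core_normal,
             cfg$frac_in_sra_by_group, cfg$frac_singleton, cfg$frac_multi_cohort,
             cfg$frac_antisense_unexplained, cfg$frac_antisense_other,
             cfg$frac_cancer_gene_unexplained, cfg$frac_cancer_gene_other,
             cfg$frac_annotated, cfg$frac_one_site, cfg$frac_singleton_reads,
             cfg$normal_prevalence, cfg$sra_cancer_presence)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (cfg$frac_in_tissue_matched + cfg$frac_in_other_core_normal > 1) {
    abort("core-normal fractions must sum to at most 1")
  }
  if (sum(cfg$frac_in_sra_by_group) > 1) {
    abort("conditional SRA group fractions must sum to at most 1")
  }
  need <- c("adult", "developmental", "stem", "placenta")
  if (!all(need %in% names(cfg$frac_in_sra_by_group))) {
    abort("frac_in_sra_by_group must name adult, developmental, stem, placenta")
  }
  if (abs(sum(cfg$prevalence_spectrum$weight) - 1) > 1e-8) {
    abort("prevalence_spectrum weights must sum to 1")
  }
  if (any(cfg$prevalence_spectrum$prevalence <= 0 | cfg$prevalence_spectrum$prevalence > 1)) {
    abort("prevalence_spectrum prevalences must lie in (0, 1]")
  }
  declared_normals <- c(cfg$tissue_cohorts, cfg$matched_cohorts)
  ok_map <- all(map_lgl(cfg$tissue_match_map, ~ all(.x %in% declared_normals)))
  if (!setequal(names(cfg$tissue_match_map), cfg$cancer_cohorts) || !ok_map) {
    abort("inconsistent tissue_match_map: keys must be the cancer cohorts and values declared normal cohorts")
  }
  bad_grp <- setdiff(unique(cfg$sra_category_groups), c("adult", "developmental", "stem"))
  if (length(bad_grp) || !setequal(names(cfg$sra_category_groups), names(cfg$sra_category_sizes))) {
    abort("sra_category_groups must label every SRA category with adult/developmental/stem")
  }
  counts <- c(cfg$samples_per_cancer_cohort, cfg$n_core_normal_samples,
              cfg$sra_category_sizes, cfg$n_junctions, cfg$n_genes,
              cfg$transcripts_per_gene, cfg$exons_per_transcript)
  if (any(counts < 0)) abort("counts must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  cancer cohorts:", length(x$cancer_cohorts), "x",
      x$samples_per_cancer_cohort, "samples\n")
  cat("  core normals:", x$n_core_normal_samples, "samples;",
      "SRA samples:", sum(x$sra_category_sizes), "\n")
  cat("  junctions:", x$n_junctions, "\n")
  invisible(x)
}

# seed substream offsets (fixed so a single table can be regenerated alone)
.seed_offsets <- c(annotation = 101L, junctions = 211L, evidence = 307L,
                   phenotypes = 401L, clinical = 503L)
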