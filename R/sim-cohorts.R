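#' Generate the sample phenotype table for a simulated study
#'
#' Emits tumor samples per cancer cohort (with a sprinkle of recurrent and
#' metastatic sample types, all of which remain tumor class), the core-normal
#' cohorts (GTEx-style tissues and per-cancer matched normals), the flagged
#' leukemia-cell-line bone-marrow normals, the SRA non-cancer categories and
#' any matched SRA cancer categories, with clinical fields for tumor samples.
#'
#' @param config A [sim_config()].
#' @return A phenotype tibble (`sample_id`, `cohort`, `cohort_class`,
#'   `sample_type`, `subtype`, clinical columns, `mapped_reads`,
#'   `leukemia_cell_line`).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["phenotypes"]])
  rows <- list()
  mk_ids <- function(cohort, n) sprintf("%s_S%03d", cohort, seq_len(n))

  for (cc in config$cancer_cohorts) {
    n <- config$samples_per_cancer_cohort
    if (n == 0) next
    ids <- mk_ids(cc, n)
    stype <- sample(c("primary_tumor", "recurrent_tumor", "metastatic_tumor"),
                    n, TRUE, prob = c(0.92, 0.04, 0.04))
    dead <- runif(n) < 0.3
    dtd <- ifelse(dead, round(rexp(n, 1 / 800)) + 1, NA_real_)
    dtl <- ifelse(dead, NA_real_, round(runif(n, 30, 3000)))
    rows[[length(rows) + 1]] <- tibble(
      sample_id = ids, cohort = cc, cohort_class = "tumor",
      sample_type = stype, patient_id = paste0("PT_", ids),
      subtype = if (cc == config$cancer_cohorts[1])
        sample(c("alpha", "beta"), n, TRUE) else NA_character_,
      stage_at_dx = sample(c("I", "II", "III", "IV"), n, TRUE),
      gender = sample(c("female", "male"), n, TRUE),
      vital_status = ifelse(dead, "dead", "alive"),
      days_to_death = dtd, days_to_last_followup = dtl,
      mapped_reads = round(runif(n, 5e5, 2e6)),
      leukemia_cell_line = FALSE
    )
  }
  normal_cohorts <- c(config$tissue_cohorts, config$matched_cohorts)
  if (length(normal_cohorts) > 0 && config$n_core_normal_samples > 0) {
    sizes <- rep(config$n_core_normal_samples %/% length(normal_cohorts), length(normal_cohorts))
    extra <- config$n_core_normal_samples %% length(normal_cohorts)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    for (k in seq_along(normal_cohorts)) {
      nc <- normal_cohorts[k]
      if (sizes[k] == 0) next
      rows[[length(rows) + 1]] <- tibble(
        sample_id = mk_ids(nc, sizes[k]), cohort = nc,
        cohort_class = if (nc %in% config$matched_cohorts) "matched_normal" else "gtex_normal",
        sample_type = if (nc %in% config$matched_cohorts) "matched_normal" else "gtex",
        leukemia_cell_line = FALSE
      )
    }
  }
  if (config$n_bone_marrow_excluded > 0) {
    rows[[length(rows) + 1]] <- tibble(
      sample_id = mk_ids("BONE_MARROW_CL", config$n_bone_marrow_excluded),
      cohort = "BONE_MARROW_CL", cohort_class = "gtex_normal",
      sample_type = "gtex", leukemia_cell_line = TRUE
    )
  }
  for (cat in names(config$sra_category_sizes)) {
    n <- config$sra_category_sizes[[cat]]
    if (n == 0) next
    grp <- config$sra_category_groups[[cat]]
    cls <- if (cat == "placenta") "sra_placenta" else paste0("sra_", grp)
    rows[[length(rows) + 1]] <- tibble(
      sample_id = mk_ids(toupper(cat), n), cohort = cat, cohort_class = cls,
      sample_type = "sra", leukemia_cell_line = FALSE
    )
  }
  for (sc in unique(config$sra_cancer_map)) {
    rows[[length(rows) + 1]] <- tibble(
      sample_id = mk_ids(sc, config$sra_cancer_size), cohort = sc,
      cohort_class = "sra_cancer", sample_type = "sra", leukemia_cell_line = FALSE
    )
  }
  bind_rows(rows)
}

#' Generate multi-cohort junction evidence with planted ground truth
#'
#' Draws a mutually exclusive truth category per junction (tissue-matched
#' normal / other core normal / SRA adult / developmental / placenta / stem /
#' unexplained, plus appended low-evidence junctions destined for the global
#' read filter), plants per-cohort prevalences by i.i.d. Bernoulli inclusion,
#' assigns coordinates realizing the planted gene context and annotation
#' status against the synthetic annotation, and emits per-positive-sample
#' read counts from a zero-truncated Poisson. Reads appear only in cohorts
#' the junction's category permits, so an unexplained junction has zero reads
#' in every normal and SRA non-cancer sample.
#'
#' Deterministic given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @param annotation Optional [simulate_annotation()] result; generated from
#'   the config when omitted.
#' @return A list of class `junction_sim`: `evidence` (long canonical
#'   tibble), `phenotypes`, `truth` (one row per generated junction),
#'   `annotation`, `config`.
#' @export
simulate_cohorts <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation %||% simulate_annotation(
    config$n_genes, config$transcripts_per_gene, config$exons_per_transcript,
    seed = config$seed
  )
  phen <- simulate_phenotypes(config)
  empty_truth <- tibble(
    key = character(), chrom = character(), start = integer(), end = integer(),
    strand = character(), category = character(), singleton = logical(),
    low_evidence = logical(), home1 = character(), home2 = character(),
    prevalence = double(), gene_context = character(), cancer_gene = logical(),
    annotation_planted = character(), in_sra_cancer = logical()
  )
  empty_ev <- tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), sample_id = character(), reads = integer())
  if (config$n_junctions == 0 || config$samples_per_cancer_cohort == 0 ||
      length(config$cancer_cohorts) == 0) {
    return(structure(list(evidence = empty_ev, phenotypes = phen, truth = empty_truth,
                          annotation = ann, config = config), class = "junction_sim"))
  }

  set.seed(config$seed + .seed_offsets[["junctions"]])
  n_j <- config$n_junctions
  f_tm <- config$frac_in_tissue_matched
  f_ocn <- config$frac_in_other_core_normal
  r <- 1 - f_tm - f_ocn
  g <- config$frac_in_sra_by_group
  probs <- c(tissue_matched_normal = f_tm, other_core_normal = f_ocn,
             sra_adult = r * g[["adult"]], sra_developmental = r * g[["developmental"]],
             sra_stem = r * g[["stem"]], sra_placenta = r * g[["placenta"]],
             unexplained = r * (1 - sum(g)))
  category <- sample(names(probs), n_j, replace = TRUE, prob = probs)
  stage2_cats <- c("sra_adult", "sra_developmental", "sra_stem", "sra_placenta", "unexplained")
  n_lowev <- round(config$frac_singleton_reads * n_j)
  category <- c(category, rep("low_evidence", n_lowev))
  N <- length(category)
  is_stage2 <- category %in% stage2_cats
  lowev <- category == "low_evidence"
  singleton <- (is_stage2 & runif(N) < config$frac_singleton) | lowev

  matched_ok <- names(config$tissue_match_map)[lengths(config$tissue_match_map) > 0]
  if (any(category == "tissue_matched_normal") && length(matched_ok) == 0) {
    abort("config error: tissue-matched junctions planted but no cancer cohort has tissue-matched normals")
  }
  home1 <- character(N)
  tm_idx <- category == "tissue_matched_normal"
  home1[tm_idx] <- sample(matched_ok, sum(tm_idx), replace = TRUE)
  home1[!tm_idx] <- sample(config$cancer_cohorts, sum(!tm_idx), replace = TRUE)
  multi <- !singleton & runif(N) < config$frac_multi_cohort &
    length(config$cancer_cohorts) > 1
  home2 <- rep(NA_character_, N)
  for (i in which(multi)) {
    pool <- if (tm_idx[i]) matched_ok else config$cancer_cohorts
    pool <- setdiff(pool, home1[i])
    if (length(pool)) home2[i] <- pool[sample.int(length(pool), 1)] else multi[i] <- FALSE
  }
  prevalence <- rep(NA_real_, N)
  spec <- config$prevalence_spectrum
  prevalence[!singleton] <- sample(spec$prevalence, sum(!singleton),
                                   replace = TRUE, prob = spec$weight)

  # planted gene context / cancer-gene / annotation status
  unx <- category == "unexplained"
  p_as <- ifelse(unx, config$frac_antisense_unexplained, config$frac_antisense_other)
  p_cg <- ifelse(unx, config$frac_cancer_gene_unexplained, config$frac_cancer_gene_other)
  p_ig <- 0.15
  u <- runif(N)
  gene_context <- ifelse(u < p_as, "antisense",
                  ifelse(u < p_as + p_ig, "neither", "protein_coding"))
  cancer_gene <- gene_context == "protein_coding" & u >= p_as + p_ig & u < p_as + p_ig + p_cg
  gene_context[lowev] <- "neither"
  cancer_gene[lowev] <- FALSE
  ann_u <- runif(N)
  annotation_planted <- ifelse(
    gene_context != "protein_coding", "neither",
    ifelse(ann_u < config$frac_annotated, "both",
           ifelse(ann_u < config$frac_annotated + config$frac_one_site, "one", "neither"))
  )
  # cancer-gene junctions need novel in-gene coordinates in a designated gene
  annotation_planted[cancer_gene] <- "neither"

  coords <- plant_coordinates(category, gene_context, cancer_gene, annotation_planted, ann)

  # matched SRA cancer replication: more likely for shared junctions
  eligible_sra_cancer <- is_stage2 & home1 %in% names(config$sra_cancer_map)
  pres <- ifelse(singleton, config$sra_cancer_presence[["singleton"]],
                 config$sra_cancer_presence[["nonsingleton"]])
  in_sra_cancer <- eligible_sra_cancer & runif(N) < pres

  truth <- tibble(
    key = junction_key(coords$chrom, coords$start, coords$end, coords$strand),
    chrom = coords$chrom, start = coords$start, end = coords$end, strand = coords$strand,
    category = category, singleton = singleton, low_evidence = lowev,
    home1 = home1, home2 = home2, prevalence = prevalence,
    gene_context = gene_context, cancer_gene = cancer_gene,
    annotation_planted = annotation_planted, in_sra_cancer = in_sra_cancer
  )
  if (anyDuplicated(truth$key)) abort("internal error: duplicate planted junction keys")

  evidence <- plant_evidence(truth, phen, config)
  structure(list(evidence = evidence, phenotypes = phen, truth = truth,
                 annotation = ann, config = config), class = "junction_sim")
}

# deterministic coordinate allocation: families use disjoint arithmetic
# progressions so keys are unique and planted annotation/context labels hold
plant_coordinates <- function(category, gene_context, cancer_gene,
                              annotation_planted, ann) {
  N <- length(category)
  chrom <- rep("chrS", N)
  start <- integer(N)
  end <- integer(N)
  strand <- rep("+", N)
  genes <- ann$genes |> filter(.data$strand == "+")
  plus_ann <- ann$junctions |> filter(.data$strand == "+")
  # annotated plants must not stray into cancer-gene loci, or they would pick
  # up the cancer-relevant flag on top of their planted context
  if (nrow(plus_ann) > 0 && nrow(genes) > 0) {
    gidx <- findInterval(plus_ann$start, genes$start)
    in_cg <- gidx >= 1 & genes$cancer_gene[pmax(gidx, 1)] %in% TRUE
    plus_ann <- plus_ann[!in_cg, ]
  }
  cg_genes <- which(genes$cancer_gene)
  ncg_genes <- which(!genes$cancer_gene)
  gene_counter <- integer(nrow(genes))

  i_both <- which(annotation_planted == "both")
  if (length(i_both) > nrow(plus_ann)) {
    abort("not enough annotated junctions to plant; increase n_genes")
  }
  if (length(i_both)) {
    pick <- sample.int(nrow(plus_ann), length(i_both))
    chrom[i_both] <- plus_ann$chrom[pick]
    start[i_both] <- plus_ann$start[pick]
    end[i_both] <- plus_ann$end[pick]
  }
  i_one <- which(annotation_planted == "one")
  if (length(i_one)) {
    if (nrow(plus_ann) == 0) abort("annotation has no junctions to anchor one-site plants")
    pick <- sample.int(nrow(plus_ann), length(i_one), replace = TRUE)
    chrom[i_one] <- plus_ann$chrom[pick]
    start[i_one] <- plus_ann$start[pick]
    end[i_one] <- plus_ann$end[pick] + 300L + 3L * seq_along(i_one)
  }
  in_gene <- function(i, gidx_pool, minus = FALSE) {
    if (length(gidx_pool) == 0) abort("no genes available for in-gene coordinate planting")
    gi <- gidx_pool[1L + (seq_along(i) - 1L) %% length(gidx_pool)]
    for (k in seq_along(i)) {
      gene_counter[gi[k]] <<- gene_counter[gi[k]] + 1L
      t <- gene_counter[gi[k]]
      off <- if (minus) 40L + 11L * t else 20L + 7L * t
      len <- if (minus) 140L + (t %% 17L) else 150L + (t %% 23L)
      start[i[k]] <<- genes$start[gi[k]] + off
      end[i[k]] <<- start[i[k]] + len
      chrom[i[k]] <<- genes$chrom[gi[k]]
    }
  }
  i_cg <- which(cancer_gene)
  if (length(i_cg)) in_gene(i_cg, cg_genes)
  i_sense_novel <- which(gene_context == "protein_coding" & !cancer_gene &
                           annotation_planted == "neither")
  if (length(i_sense_novel)) in_gene(i_sense_novel, ncg_genes)
  i_anti <- which(gene_context == "antisense")
  if (length(i_anti)) {
    in_gene(i_anti, seq_len(nrow(genes)), minus = TRUE)
    strand[i_anti] <- "-"
  }
  i_inter <- which(gene_context == "neither")
  if (length(i_inter)) {
    base <- if (nrow(genes)) max(genes$end) + 50000L else 100000L
    start[i_inter] <- base + 17L * seq_along(i_inter)
    end[i_inter] <- start[i_inter] + 120L + (seq_along(i_inter) %% 29L)
  }
  tibble(chrom = chrom, start = start, end = end, strand = strand)
}

# zero-truncated Poisson variates, optionally truncated at >= 2 reads
rztpois <- function(n, lambda, min_count = 1L) {
  lo <- ppois(min_count - 1L, lambda)
  qpois(lo + runif(n) * (1 - lo), lambda)
}

plant_evidence <- function(truth, phen, config) {
  set.seed(config$seed + .seed_offsets[["evidence"]])
  cohort_samples <- split(phen$sample_id, phen$cohort)
  grp <- config$sra_category_groups
  adult_cats <- names(grp)[grp == "adult"]
  dev_cats <- setdiff(names(grp)[grp == "developmental"], "placenta")
  stem_cats <- names(grp)[grp == "stem"]
  has_placenta <- "placenta" %in% names(grp) && "placenta" %in% names(cohort_samples)
  normal_cohorts <- c(config$tissue_cohorts, config$matched_cohorts)
  stage2_cats <- c("sra_adult", "sra_developmental", "sra_stem", "sra_placenta", "unexplained")

  bern_pick <- function(pool, p, min_pos) {
    if (length(pool) == 0) return(character(0))
    hit <- pool[runif(length(pool)) < p]
    if (length(hit) < min_pos) {
      hit <- pool[sample.int(length(pool), min(min_pos, length(pool)))]
    }
    hit
  }
  rows_j <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cat_i <- truth$category[i]
    sids <- character(0)
    tags <- character(0)
    homes <- c(truth$home1[i], truth$home2[i])
    homes <- homes[!is.na(homes)]
    for (h in homes) {
      pool <- cohort_samples[[h]]
      if (truth$singleton[i]) {
        pick <- pool[sample.int(length(pool), 1)]
      } else {
        min_pos <- if (cat_i %in% stage2_cats) 2L else 1L
        pick <- bern_pick(pool, truth$prevalence[i], min_pos)
      }
      sids <- c(sids, pick)
      tags <- c(tags, rep("tumor", length(pick)))
      if (truth$singleton[i]) break  # singletons live in one cohort only
    }
    np <- config$normal_prevalence
    extra <- switch(
      cat_i,
      tissue_matched_normal = {
        mcs <- config$tissue_match_map[[truth$home1[i]]]
        bern_pick(cohort_samples[[mcs[sample.int(length(mcs), 1)]]], np, 1L)
      },
      other_core_normal = {
        pool_c <- setdiff(normal_cohorts, config$tissue_match_map[[truth$home1[i]]])
        bern_pick(cohort_samples[[pool_c[sample.int(length(pool_c), 1)]]], np, 1L)
      },
      sra_adult = bern_pick(cohort_samples[[adult_cats[sample.int(length(adult_cats), 1)]]], np, 1L),
      sra_developmental = bern_pick(cohort_samples[[dev_cats[sample.int(length(dev_cats), 1)]]], np, 1L),
      sra_stem = bern_pick(cohort_samples[[stem_cats[sample.int(length(stem_cats), 1)]]], np, 1L),
      sra_placenta = if (has_placenta) bern_pick(cohort_samples[["placenta"]], np, 1L) else character(0),
      character(0)
    )
    sids <- c(sids, extra)
    tags <- c(tags, rep("aux", length(extra)))
    if (truth$in_sra_cancer[i]) {
      sc <- config$sra_cancer_map[[truth$home1[i]]]
      n_sc <- 1L + rbinom(1, 2, 0.5)
      pick <- cohort_samples[[sc]][sample.int(length(cohort_samples[[sc]]), min(n_sc, length(cohort_samples[[sc]])))]
      sids <- c(sids, pick)
      tags <- c(tags, rep("aux", length(pick)))
    }
    rows_j[[i]] <- tibble(jrow = i, sample_id = sids, tag = tags)
  }
  ev <- bind_rows(rows_j)
  lam <- config$read_count_model$lambda %||% 3
  ev$reads <- rztpois(nrow(ev), lam)
  # a lone tumor read must still clear the global two-read filter for
  # non-low-evidence singletons; low-evidence junctions get exactly one read
  force2 <- truth$singleton[ev$jrow] & !truth$low_evidence[ev$jrow] & ev$tag == "tumor"
  ev$reads[force2] <- rztpois(sum(force2), lam, min_count = 2L)
  ev$reads[truth$low_evidence[ev$jrow]] <- 1L
  tibble(
    chrom = truth$chrom[ev$jrow], start = truth$start[ev$jrow],
    end = truth$end[ev$jrow], strand = truth$strand[ev$jrow],
    sample_id = ev$sample_id, reads = as.integer(ev$reads)
  ) |> arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id)
}

#' @export
print.junction_sim <- function(x, ...) {
  cat("<junction_sim>", nrow(x$truth), "junctions,",
      nrow(x$evidence), "evidence rows,", nrow(x$phenotypes), "samples\n")
  invisible(x)
}
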