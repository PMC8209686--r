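#' Assemble a pipeline run configuration
#'
#' Collects everything a full run needs: the output directory, the simulation
#' (or externally supplied input paths), and the filter parameters, whose
#' defaults are the analysis' reference values — a 2-read global evidence
#' filter, 1% panel prevalence, 200-junction panel cap and 5% cross-cohort
#' threshold. Every deviation from a default is echoed into each step's
#' manifest.
#'
#' @param out_dir Output directory (created on demand).
#' @param seed Seed recorded in manifests and used by the simulate step.
#' @param sim A [sim_config()] for the simulate step.
#' @param effect A [mutation_effect()] for the clinical tables.
#' @param min_total_reads,prevalence_threshold,panel_cap,cross_cohort_threshold
#'   Filter parameters.
#' @param two_sample_rule Also emit set assignments under the conservative
#'   two-sample rule.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, sim = sim_config(seed = seed),
                       effect = mutation_effect(),
                       min_total_reads = 2, prevalence_threshold = 0.01,
                       panel_cap = 200, cross_cohort_threshold = 0.05,
                       two_sample_rule = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 effect = effect, min_total_reads = min_total_reads,
                 prevalence_threshold = prevalence_threshold,
                 panel_cap = panel_cap,
                 cross_cohort_threshold = cross_cohort_threshold,
                 two_sample_rule = two_sample_rule),
            class = "run_config")
}

step_dir <- function(config, step) file.path(config$out_dir, step)

write_manifest <- function(config, step, inputs, outputs, params) {
  man <- list(
    step = step,
    package = "juncnov",
    version = as.character(utils::packageVersion("juncnov")),
    seed = config$seed,
    params = params,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(man, file.path(step_dir(config, step), "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_upstream <- function(config, path, prior_step) {
  if (!file.exists(path)) {
    abort(paste0("missing upstream artifact '", path,
                 "': run the '", prior_step, "' step first"))
  }
  path
}

#' Read / write a tissue-match map as YAML
#'
#' @param x Named list: cancer cohort -> character vector of tissue-matched
#'   normal cohorts (possibly empty).
#' @param path YAML file path.
#' @export
write_match_map <- function(x, path) {
  yaml::write_yaml(map(x, as.list), path)
  invisible(path)
}

#' @rdname write_match_map
#' @export
read_match_map <- function(path) {
  map(yaml::read_yaml(path), ~ as.character(unlist(.x)))
}

#' Run one pipeline step (or all of them)
#'
#' Orchestrates the stages end-to-end against an output directory: each step
#' reads the prior steps' files, writes its module's TSV outputs plus a JSON
#' manifest (parameters, input/output checksums, tool version), and reruns
#' byte-identically on unchanged inputs. A missing upstream artifact raises
#' an error naming the required prior step.
#'
#' Steps: `simulate` (synthetic study), `index` (parse annotation, load
#' evidence and phenotypes, build and persist the store), `filter` (global
#' read filter + novelty stages), `prevalence` (prevalence, shared panels,
#' prevalence matrix, cross-cohort sharing), `sets` (SRA set assignments,
#' upset summary, matched-cancer sharedness), `classify` (gene context,
#' cancer-gene flags, antisense fractions), `stats` (burden vs TMB,
#' mutation-stratified ANOVA, Fisher scan, Kaplan-Meier), `all` (chain).
#'
#' @param step Step name.
#' @param config A [run_config()].
#' @return The step's output directory, invisibly.
#' @export
run_step <- function(step = c("all", "simulate", "index", "filter", "prevalence",
                              "sets", "classify", "stats"),
                     config) {
  step <- match.arg(step)
  stopifnot(inherits(config, "run_config"))
  if (step == "all") {
    for (s in c("simulate", "index", "filter", "prevalence", "sets", "classify", "stats")) {
      run_step(s, config)
    }
    return(invisible(config$out_dir))
  }
  dir.create(step_dir(config, step), recursive = TRUE, showWarnings = FALSE)
  switch(step,
         simulate = step_simulate(config),
         index = step_index(config),
         filter = step_filter(config),
         prevalence = step_prevalence(config),
         sets = step_sets(config),
         classify = step_classify(config),
         stats = step_stats(config))
  invisible(step_dir(config, step))
}

#' @rdname run_step
#' @export
run_pipeline <- function(config) run_step("all", config)

sim_paths <- function(config) {
  d <- step_dir(config, "simulate")
  list(gtf = file.path(d, "annotation.gtf"),
       evidence = file.path(d, "evidence.tsv"),
       phenotypes = file.path(d, "phenotypes.tsv"),
       truth = file.path(d, "truth.tsv"),
       match_map = file.path(d, "tissue_match_map.yaml"),
       taxonomy = file.path(d, "sra_taxonomy.yaml"),
       cancer_genes = file.path(d, "cancer_genes.txt"),
       splicing_genes = file.path(d, "splicing_genes.txt"),
       mutations = file.path(d, "mutations.tsv"),
       tmb = file.path(d, "tmb.tsv"),
       survival = file.path(d, "survival.tsv"))
}

step_simulate <- function(config) {
  p <- sim_paths(config)
  sim <- simulate_cohorts(config$sim)
  clin <- simulate_clinical_tables(sim$phenotypes, config$effect, seed = config$sim$seed)
  writeLines(sim$annotation$gtf, p$gtf)
  write_evidence(sim$evidence, p$evidence)
  readr::write_tsv(sim$phenotypes, p$phenotypes)
  readr::write_tsv(sim$truth, p$truth)
  write_match_map(config$sim$tissue_match_map, p$match_map)
  yaml::write_yaml(as.list(config$sim$sra_category_groups), p$taxonomy)
  writeLines(sim$annotation$cancer_genes, p$cancer_genes)
  writeLines(clin$splicing_genes, p$splicing_genes)
  readr::write_tsv(clin$mutations, p$mutations)
  readr::write_tsv(clin$tmb, p$tmb)
  readr::write_tsv(clin$survival, p$survival)
  write_manifest(config, "simulate", inputs = character(0),
                 outputs = unlist(p), params = list(seed = config$sim$seed,
                                                    n_junctions = config$sim$n_junctions))
}

step_index <- function(config) {
  p <- sim_paths(config)
  for (f in c("gtf", "evidence", "phenotypes")) require_upstream(config, p[[f]], "simulate")
  ann <- parse_annotation(p$gtf)
  ev <- read_evidence(p$evidence, dialect = "1-closed")
  phen <- readr::read_tsv(p$phenotypes, show_col_types = FALSE)
  store <- build_junction_store(ev, phen, annotation = ann, dialect = "0-closed")
  out <- file.path(step_dir(config, "index"), "store.sqlite")
  write_store(store, out)
  write_manifest(config, "index", inputs = unlist(p[c("gtf", "evidence", "phenotypes")]),
                 outputs = out, params = list())
  out
}

pipeline_store <- function(config) {
  path <- require_upstream(config, file.path(step_dir(config, "index"), "store.sqlite"), "index")
  read_store(path)
}

step_filter <- function(config) {
  store <- pipeline_store(config)
  mm_path <- require_upstream(config, sim_paths(config)$match_map, "simulate")
  match_map <- read_match_map(mm_path)
  filtered <- apply_read_filter(store, config$min_total_reads)
  nov <- assign_novelty(filtered, match_map)
  d <- step_dir(config, "filter")
  out <- file.path(d, "novelty.tsv")
  nov_out <- nov |>
    inner_join(filtered$junctions, by = "junction_id") |>
    mutate(stage = as.character(.data$stage))
  readr::write_tsv(nov_out, out)
  removed <- file.path(d, "filtered_out.tsv")
  readr::write_tsv(
    store$junctions |> filter(.data$junction_id %in% attr(filtered, "removed_junctions")),
    removed
  )
  write_manifest(config, "filter", inputs = file.path(step_dir(config, "index"), "store.sqlite"),
                 outputs = c(out, removed),
                 params = list(min_total_reads = config$min_total_reads))
}

pipeline_novelty <- function(config) {
  path <- require_upstream(config, file.path(step_dir(config, "filter"), "novelty.tsv"), "filter")
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(stage = factor(.data$stage, levels = c("0", "1+", "2+", "3+"), ordered = TRUE))
}

filtered_store <- function(config) {
  apply_read_filter(pipeline_store(config), config$min_total_reads)
}

step_prevalence <- function(config) {
  store <- filtered_store(config)
  nov <- pipeline_novelty(config)
  d <- step_dir(config, "prevalence")
  prev <- cohort_prevalence(store)
  readr::write_tsv(prev, file.path(d, "prevalence.tsv"))
  cohorts <- sort(unique(nov$cohort))
  panels <- map(cohorts, ~ select_shared_panel(store, nov, .x, cap = config$panel_cap,
                                               min_prevalence = config$prevalence_threshold))
  readr::write_tsv(bind_rows(panels), file.path(d, "panels.tsv"))
  pm <- build_prevalence_matrix(store, panels)
  readr::write_tsv(as_tibble(pm), file.path(d, "prevalence_matrix.tsv"))
  stage2_prev <- prev |> semi_join(nov |> filter(.data$stage >= "2+"),
                                   by = c("cohort", "junction_id"))
  ccs <- cross_cohort_sharing(stage2_prev, threshold = config$cross_cohort_threshold)
  readr::write_tsv(ccs, file.path(d, "cross_cohort.tsv"))
  write_manifest(config, "prevalence",
                 inputs = file.path(step_dir(config, "filter"), "novelty.tsv"),
                 outputs = file.path(d, c("prevalence.tsv", "panels.tsv",
                                          "prevalence_matrix.tsv", "cross_cohort.tsv")),
                 params = list(prevalence_threshold = config$prevalence_threshold,
                               panel_cap = config$panel_cap,
                               cross_cohort_threshold = config$cross_cohort_threshold))
}

step_sets <- function(config) {
  store <- filtered_store(config)
  nov <- pipeline_novelty(config)
  d <- step_dir(config, "sets")
  scm <- config$sim$sra_cancer_map
  asg <- assign_sets(store, nov, sra_cancer_map = scm)
  readr::write_tsv(asg, file.path(d, "assignments.tsv"))
  readr::write_tsv(upset_summary(asg), file.path(d, "upset.tsv"))
  outs <- file.path(d, c("assignments.tsv", "upset.tsv", "matched_cancer_test.tsv"))
  if (config$two_sample_rule) {
    asg2 <- apply_two_sample_rule(store, nov, sra_cancer_map = scm)
    readr::write_tsv(asg2, file.path(d, "assignments_two_sample.tsv"))
    outs <- c(outs, file.path(d, "assignments_two_sample.tsv"))
  }
  mct <- matched_cancer_sharedness_test(store, nov, asg)
  readr::write_tsv(mct, file.path(d, "matched_cancer_test.tsv"))
  write_manifest(config, "sets",
                 inputs = file.path(step_dir(config, "filter"), "novelty.tsv"),
                 outputs = outs,
                 params = list(two_sample_rule = config$two_sample_rule))
}

step_classify <- function(config) {
  p <- sim_paths(config)
  store <- filtered_store(config)
  nov <- pipeline_novelty(config)
  ann <- parse_annotation(require_upstream(config, p$gtf, "simulate"))
  d <- step_dir(config, "classify")
  ctx <- classify_gene_context(store$junctions, ann) |>
    flag_cancer_genes(read_gene_list(p$cancer_genes))
  readr::write_tsv(ctx, file.path(d, "gene_context.tsv"))
  asg_path <- require_upstream(config, file.path(step_dir(config, "sets"), "assignments.tsv"), "sets")
  asg <- readr::read_tsv(asg_path, show_col_types = FALSE)
  categories <- novelty_set_category(nov, asg)
  af <- antisense_fraction_by_category(categories, ctx)
  readr::write_tsv(af, file.path(d, "antisense_by_category.tsv"))
  write_manifest(config, "classify", inputs = c(p$gtf, asg_path),
                 outputs = file.path(d, c("gene_context.tsv", "antisense_by_category.tsv")),
                 params = list())
}

step_stats <- function(config) {
  p <- sim_paths(config)
  store <- filtered_store(config)
  nov <- pipeline_novelty(config)
  d <- step_dir(config, "stats")
  for (f in c("tmb", "mutations", "survival")) require_upstream(config, p[[f]], "simulate")
  phen <- store$samples
  burden <- patient_burden(store, nov) |>
    left_join(phen |> select("sample_id", "patient_id"), by = "sample_id")
  readr::write_tsv(burden, file.path(d, "burden.tsv"))

  tmb <- readr::read_tsv(p$tmb, show_col_types = FALSE)
  reg_in <- burden |> inner_join(tmb |> select("patient_id", "tmb"), by = "patient_id")
  fit <- regress_burden_vs_tmb(reg_in)
  readr::write_tsv(glance(fit), file.path(d, "burden_vs_tmb.tsv"))

  mutations <- readr::read_tsv(p$mutations, show_col_types = FALSE)
  strata <- stratify_by_mutation(mutations, unique(burden$patient_id),
                                 criterion = "sqtl_five_gene")
  counts <- burden |>
    inner_join(strata |> select("patient_id", "mutated"), by = "patient_id") |>
    transmute(.data$patient_id, .data$cohort,
              n_junctions = .data$n_stage2_junctions, .data$mutated)
  av <- stratify_and_test_counts(counts)
  readr::write_tsv(av$anova, file.path(d, "anova.tsv"))
  readr::write_tsv(av$per_cohort, file.path(d, "anova_per_cohort.tsv"))

  fs <- sharedness_fisher_scan(store, nov, strata)
  readr::write_tsv(fs, file.path(d, "fisher.tsv"))

  surv <- readr::read_tsv(p$survival, show_col_types = FALSE)
  km <- km_survival(surv, group = "junction_positive")
  readr::write_tsv(as_tibble(km), file.path(d, "km_curve.tsv"))
  write_manifest(config, "stats",
                 inputs = unlist(p[c("tmb", "mutations", "survival")]),
                 outputs = file.path(d, c("burden.tsv", "burden_vs_tmb.tsv", "anova.tsv",
                                          "anova_per_cohort.tsv", "fisher.tsv", "km_curve.tsv")),
                 params = list())
}

#' Fisher sharedness scan over recurrent junctions
#'
#' For every cancer cohort, selects stage-2+ junctions identified in two or
#' more patients and tests (two-sided Fisher's exact) whether their patient
#' occurrences concentrate among splicing-mutated patients.
#'
#' @param store A `junction_store` (phenotypes must carry `patient_id`).
#' @param novelty Output of [assign_novelty()].
#' @param strata Output of [stratify_by_mutation()].
#' @return A tibble (`cohort`, `junction_id`, `in_mutated`, `n_mutated`,
#'   `total`, `cohort_size`, `odds_ratio`, `p_value`, `flagged`).
#' @export
sharedness_fisher_scan <- function(store, novelty, strata) {
  tumor <- store$samples |> filter(.data$cohort_class == "tumor")
  if (!"patient_id" %in% names(tumor)) abort("phenotypes lack 'patient_id'")
  stage2 <- novelty |> filter(.data$stage >= "2+")
  occ <- store$evidence |>
    inner_join(tumor |> select("sample_id", "cohort", "patient_id"), by = "sample_id") |>
    semi_join(stage2, by = c("junction_id", "cohort")) |>
    distinct(.data$cohort, .data$junction_id, .data$patient_id) |>
    inner_join(strata |> select("patient_id", "mutated"), by = "patient_id")
  sizes <- tumor |>
    inner_join(strata |> select("patient_id", "mutated"), by = "patient_id") |>
    distinct(.data$cohort, .data$patient_id, .data$mutated) |>
    group_by(.data$cohort) |>
    summarise(cohort_size = dplyr::n(), n_mutated = sum(.data$mutated), .groups = "drop")
  tab <- occ |>
    group_by(.data$cohort, .data$junction_id) |>
    summarise(total = dplyr::n(), in_mutated = sum(.data$mutated), .groups = "drop") |>
    filter(.data$total >= 2) |>
    inner_join(sizes, by = "cohort")
  if (nrow(tab) == 0) return(tab)
  bind_cols(tab, fisher_sharedness_test(tab$in_mutated, tab$n_mutated,
                                        tab$total, tab$cohort_size))
}
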