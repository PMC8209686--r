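test_that("junction burden follows the mapped-read scaling exactly", {
  expect_equal(junction_burden(100, 1e6), 1.0)
  expect_equal(junction_burden(0, 1e6), 0)
  expect_equal(junction_burden(37, 2.5e6), 0.148)
  # doubling mapped reads halves burden
  expect_equal(junction_burden(50, 2e6), junction_burden(50, 1e6) / 2)
  expect_error(junction_burden(10, 0), "positive")
  expect_error(junction_burden(-1, 10), "non-negative")
})

test_that("per-patient burden counts each sample's stage-2+ junctions", {
  store <- tiny_store(filtered = TRUE)
  s <- tiny_study()
  nov <- assign_novelty(store, s$match_map)
  b <- patient_burden(store, nov)
  # T1a carries j3 (2+) and j4 (3+) in CAN1; j1/j2 are explained
  expect_equal(b$n_stage2_junctions[b$sample_id == "T1a"], 2L)
  expect_equal(b$burden[b$sample_id == "T1a"], junction_burden(2, 1e6))
  expect_equal(b$n_stage2_junctions[b$sample_id == "T2b"], 0L)
})

test_that("burden-TMB regression recovers an exact line and flags degeneracy", {
  rec <- tibble::tibble(tmb = 1:10, burden = 2 * (1:10) + 1)
  fit <- regress_burden_vs_tmb(rec)
  g <- suppressWarnings(glance(fit))  # lm warns on an exactly perfect fit
  expect_equal(g$slope, 2, tolerance = 1e-10)
  expect_equal(g$intercept, 1, tolerance = 1e-10)
  expect_equal(g$r, 1, tolerance = 1e-10)
  expect_equal(suppressWarnings(tidy(fit))$term, c("(Intercept)", "tmb"))
  deg <- regress_burden_vs_tmb(tibble::tibble(tmb = rep(3, 5), burden = rnorm(5)))
  expect_true(glance(deg)$degenerate)
  expect_error(regress_burden_vs_tmb(rec[1:2, ]), "3 records")
})

test_that("mutation stratification counts only non-synonymous calls in the gene set", {
  muts <- tibble::tibble(
    patient_id = c("p1", "p2", "p2", "p3", "p4"),
    gene = c("SF3B1", "SF3B1", "BG001", "U2AF1", "SRSF1"),
    variant_class = c("Missense_Mutation", "Silent", "Missense_Mutation",
                      "Non-synonymous", "Missense_Mutation"))
  out <- stratify_by_mutation(muts, paste0("p", 1:5), "sqtl_five_gene")
  expect_equal(out$mutated, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # the uniprot criterion takes its gene set as input
  out2 <- stratify_by_mutation(muts, paste0("p", 1:5), "uniprot_splicing",
                               gene_set = c(sqtl_genes, "SRSF1"))
  expect_true(out2$mutated[4])
  expect_error(stratify_by_mutation(muts, "p1", "uniprot_splicing"), "gene_set")
})

test_that("the two-way ANOVA reports factors and BH-corrected per-cohort tests", {
  set.seed(4)
  counts <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:120),
    cohort = rep(c("A", "B", "C"), each = 40),
    mutated = rep(c(TRUE, FALSE), 60),
    n_junctions = rnorm(120, 100, 10) + ifelse(rep(c(TRUE, FALSE), 60), 40, 0))
  res <- stratify_and_test_counts(counts)
  expect_setequal(res$anova$term, c("cohort", "mutated", "cohort:mutated"))
  expect_lt(res$anova$p.value[res$anova$term == "mutated"], 1e-6)
  expect_true(all(res$per_cohort$p.adjusted <= 1))
  # BH monotone in the raw p-values
  ord <- order(res$per_cohort$p.value)
  expect_true(all(diff(res$per_cohort$p.adjusted[ord]) >= -1e-12))
  expect_error(stratify_and_test_counts(dplyr::mutate(counts, cohort = "A")), "2 cohorts")
  expect_error(stratify_and_test_counts(dplyr::mutate(counts, mutated = TRUE)), "strata")
})

test_that("Fisher's exact test matches enumeration and symmetry", {
  expect_equal(fisher_sharedness_test(5, 10, 10, 20)$p_value, 1)
  expect_equal(fisher_sharedness_test(5, 10, 10, 20)$odds_ratio, 1, tolerance = 1e-6)
  p <- fisher_sharedness_test(2, 2, 2, 4)$p_value
  expect_equal(p, 1 / 3, tolerance = 1e-10)
  expect_equal(p, oracle_fisher_p(2, 0, 0, 2), tolerance = 1e-10)
  # transposing the table leaves p unchanged
  p_t <- fisher_sharedness_test(2, 2, 2, 4)
  swapped <- stats::fisher.test(matrix(c(2, 0, 0, 2), 2, byrow = FALSE))
  expect_equal(p_t$p_value, swapped$p.value, tolerance = 1e-12)
  # zero margin: flagged, p = 1
  z <- fisher_sharedness_test(0, 5, 0, 10)
  expect_true(z$flagged)
  expect_equal(z$p_value, 1)
})

test_that("Kaplan-Meier matches the hand product-limit on the 4-patient fixture", {
  surv <- tibble::tibble(days_to_death = c(1, NA, 3, NA),
                         days_to_last_followup = c(NA, 2, NA, 4))
  km <- km_survival(surv)
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 3], 0.375)
  hand <- oracle_km(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km$surv[km$n_event > 0], hand$surv)
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("Kaplan-Meier boundary behavior: no events, simultaneous deaths, exclusions", {
  none <- km_survival(tibble::tibble(days_to_death = rep(NA_real_, 5),
                                     days_to_last_followup = 1:5))
  expect_true(all(none$surv == 1))
  all_t <- km_survival(tibble::tibble(days_to_death = rep(10, 4),
                                      days_to_last_followup = NA_real_))
  expect_equal(nrow(all_t), 1)
  expect_equal(all_t$surv, 0)
  expect_warning(
    km <- km_survival(tibble::tibble(days_to_death = c(1, NA),
                                     days_to_last_followup = c(NA, NA))),
    "excluded")
  expect_equal(sum(km$n_event), 1)
})

test_that("grouped survival separates planted hazard classes", {
  phen <- simulate_phenotypes(sim_config(seed = 3, n_cancer_cohorts = 2,
                                         samples_per_cancer_cohort = 120))
  clin <- simulate_clinical_tables(phen, mutation_effect(hazard_ratio = 4), seed = 3)
  km <- km_survival(clin$survival, group = "junction_positive")
  g <- glance(km)
  expect_setequal(g$group, c("TRUE", "FALSE"))
  expect_lt(g$final_surv[g$group == "TRUE"], g$final_surv[g$group == "FALSE"])
})

test_that("the Fisher scan selects recurrent junctions and fills the 2x2 margins", {
  s <- tiny_study()
  store <- build_junction_store(s$evidence, s$phenotypes)
  nov <- assign_novelty(apply_read_filter(store), s$match_map)
  strata <- tibble::tibble(patient_id = store$samples$patient_id,
                           criterion = "sqtl_five_gene",
                           mutated = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                       rep(FALSE, 9)))
  fs <- sharedness_fisher_scan(apply_read_filter(store), nov, strata)
  # only j4 (start 40) reaches two tumor patients at stage 2+, but in
  # different cohorts, so no single cohort reaches the 2-patient floor
  expect_true(all(fs$total >= 2))
})
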