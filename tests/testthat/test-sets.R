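stage2_novelty <- function(store, match_map) {
  assign_novelty(store, match_map)
}

test_that("default one-sample rule sets flags and the unexplained class", {
  store <- tiny_store(filtered = TRUE)
  s <- tiny_study()
  nov <- stage2_novelty(store, s$match_map)
  asg <- assign_sets(store, nov, sra_cancer_map = s$sra_cancer_map)
  jx <- store$junctions
  row_of <- function(start, cohort) {
    id <- jx$junction_id[jx$start == start]
    asg[asg$junction_id == id & asg$cohort == cohort, ]
  }
  # tumor-only junction -> unexplained
  expect_true(row_of(40, "CAN1")$unexplained)
  expect_equal(row_of(40, "CAN1")$combination, "unexplained")
  # one read in one SRA adult sample -> adult, not unexplained
  expect_true(row_of(30, "CAN1")$in_sra_adult)
  expect_false(row_of(30, "CAN1")$unexplained)
  # placenta-only evidence -> placenta flag, developmental stays FALSE
  expect_true(row_of(50, "CAN1")$in_sra_placenta)
  expect_false(row_of(50, "CAN1")$in_sra_developmental)
  expect_false(row_of(50, "CAN1")$unexplained)
  # stage <2+ junctions never appear
  expect_false(any(asg$junction_id %in% jx$junction_id[jx$start %in% c(10, 20)]))
})

two_sample_fixture <- function(aux) {
  # one tumor-shared junction plus configurable auxiliary evidence
  phen <- tibble::tibble(
    sample_id = c("T1", "T2", "AD1", "AD2", "FE1", "EM1", "PL1", "ST1a", "ST1b"),
    cohort = c("CAN1", "CAN1", "adult1", "adult2", "fetus", "embryo",
               "placenta", "stem1", "stem1"),
    cohort_class = c("tumor", "tumor", "sra_adult", "sra_adult",
                     "sra_developmental", "sra_developmental",
                     "sra_placenta", "sra_stem", "sra_stem"))
  ev <- tibble::tibble(chrom = "c1", start = 10L, end = 20L, strand = "+",
                       sample_id = c("T1", "T2", aux), reads = 2L)
  store <- build_junction_store(ev, phen)
  nov <- assign_novelty(store, list(CAN1 = character(0)))
  list(store = store, nov = nov)
}

test_that("the two-sample rule needs two samples per broad group, with the developmental subset exception", {
  # exactly 1 adult sample: flagged under default, not under two-sample
  f <- two_sample_fixture("AD1")
  d <- assign_sets(f$store, f$nov)
  t2 <- apply_two_sample_rule(f$store, f$nov)
  expect_true(d$in_sra_adult)
  expect_false(t2$in_sra_adult)
  expect_true(t2$unexplained)
  # 1 fetal + 1 embryonic: developmental group reaches 2, subset exception applies
  f <- two_sample_fixture(c("FE1", "EM1"))
  t2 <- apply_two_sample_rule(f$store, f$nov)
  expect_true(t2$in_sra_developmental)
  expect_false(t2$in_sra_placenta)
  # 1 placenta + 1 fetal: group-wide count includes placenta; both subset flags set
  f <- two_sample_fixture(c("PL1", "FE1"))
  t2 <- apply_two_sample_rule(f$store, f$nov)
  expect_true(t2$in_sra_developmental)
  expect_true(t2$in_sra_placenta)
  # placenta alone: one group-wide sample only
  f <- two_sample_fixture("PL1")
  t2 <- apply_two_sample_rule(f$store, f$nov)
  expect_false(t2$in_sra_placenta)
  # two samples within one stem category meet the threshold
  f <- two_sample_fixture(c("ST1a", "ST1b"))
  t2 <- apply_two_sample_rule(f$store, f$nov)
  expect_true(t2$in_sra_stem)
})

test_that("two-sample rule is strictly more conservative and conserves totals", {
  for (seed in 21:25) {
    s <- random_study(seed)
    store <- apply_read_filter(build_junction_store(s$evidence, s$phenotypes))
    nov <- assign_novelty(store, s$match_map)
    d <- assign_sets(store, nov)
    t2 <- apply_two_sample_rule(store, nov)
    key <- c("cohort", "junction_id")
    m <- dplyr::inner_join(d, t2, by = key, suffix = c("_d", "_t"))
    expect_equal(nrow(m), nrow(d))
    for (fl in c("in_sra_adult", "in_sra_developmental", "in_sra_placenta", "in_sra_stem")) {
      expect_true(all(!m[[paste0(fl, "_t")]] | m[[paste0(fl, "_d")]]))
    }
    expect_true(all(m$unexplained_d <= m$unexplained_t))  # superset of unexplained
  }
})

test_that("upset summaries partition exclusively to 100 percent", {
  s <- random_study(33)
  store <- apply_read_filter(build_junction_store(s$evidence, s$phenotypes))
  nov <- assign_novelty(store, s$match_map)
  asg <- assign_sets(store, nov)
  up <- upset_summary(asg)
  for (cc in unique(asg$cohort)) {
    ov <- up[up$cohort == cc & up$kind == "overlap", ]
    expect_equal(sum(ov$percent), 100, tolerance = 1e-9)
    expect_equal(sum(ov$n), sum(asg$cohort == cc))
  }
  # all-unexplained cohort collapses to a single 100% combination
  f <- two_sample_fixture(character(0))
  up1 <- upset_summary(assign_sets(f$store, f$nov))
  ov1 <- up1[up1$kind == "overlap", ]
  expect_equal(ov1$label, "unexplained")
  expect_equal(ov1$percent, 100)
})

test_that("set assignment equals the brute-force oracle under both rules", {
  for (seed in 41:46) {
    s <- random_study(seed)
    store <- apply_read_filter(build_junction_store(s$evidence, s$phenotypes))
    nov <- assign_novelty(store, s$match_map)
    stages <- oracle_stages(s$evidence, s$phenotypes, s$match_map)
    for (rule in c("default", "two_sample")) {
      asg <- assign_sets(store, nov, sra_cancer_map = s$sra_cancer_map, rule = rule) |>
        dplyr::inner_join(store$junctions, by = "junction_id") |>
        dplyr::mutate(key = paste(chrom, start, end, strand)) |>
        dplyr::arrange(cohort, key)
      orc <- oracle_sets(s$evidence, s$phenotypes, stages, rule = rule,
                         sra_cancer_map = s$sra_cancer_map)
      if (is.null(orc)) {
        expect_equal(nrow(asg), 0)
        next
      }
      orc <- orc[order(orc$cohort, orc$key), ]
      expect_equal(asg$key, orc$key)
      expect_equal(asg$in_sra_adult, orc$adult)
      expect_equal(asg$in_sra_developmental, orc$dev)
      expect_equal(asg$in_sra_placenta, orc$pla)
      expect_equal(asg$in_sra_stem, orc$stem)
      expect_equal(asg$unexplained, orc$unexplained)
      expect_equal(asg$in_sra_cancer_matched, orc$in_sra_cancer)
    }
  }
})

test_that("matched-cancer sharedness test skips and degenerates gracefully", {
  store <- tiny_store(filtered = TRUE)
  s <- tiny_study()
  nov <- stage2_novelty(store, s$match_map)
  asg <- assign_sets(store, nov, sra_cancer_map = s$sra_cancer_map)
  expect_message(res <- matched_cancer_sharedness_test(store, nov, asg), "skipped")
  expect_true(all(c("CAN1", "CAN2") %in% res$cohort))
  # CAN2 has no matched SRA cancer evidence
  expect_true(res$skipped[res$cohort == "CAN2"])
})

test_that("matched-cancer replication associates with higher sharedness when planted", {
  cfg <- sim_config(seed = 99, n_junctions = 1500)
  sim <- simulate_cohorts(cfg)
  store <- apply_read_filter(build_junction_store(sim$evidence, sim$phenotypes))
  nov <- assign_novelty(store, cfg$tissue_match_map)
  asg <- assign_sets(store, nov, sra_cancer_map = cfg$sra_cancer_map)
  res <- suppressMessages(matched_cancer_sharedness_test(store, nov, asg))
  tested <- res[!res$skipped & !is.na(res$p_value), ]
  expect_gt(nrow(tested), 0)
  expect_true(all(tested$statistic >= 0))
  # the generator plants replication preferentially on shared junctions
  expect_lt(min(tested$p_value), 0.05)
})
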