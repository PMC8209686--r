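test_that("prevalence is the positive-sample fraction of the cohort", {
  phen <- tibble::tibble(sample_id = sprintf("s%03d", 1:430),
                         cohort = "OV", cohort_class = "tumor")
  ev <- tibble::tibble(chrom = "c16", start = 766903L, end = 768491L, strand = "-",
                       sample_id = sprintf("s%03d", 1:350), reads = 1L)
  store <- build_junction_store(ev, phen)
  prev <- cohort_prevalence(store, "OV")
  expect_equal(prev$n_positive, 350)
  expect_equal(prev$cohort_size, 430)
  expect_equal(prev$prevalence, 350 / 430)  # reported as 81.3%

  # zero and full prevalence via an explicit junction subset
  prev0 <- cohort_prevalence(store, "OV", junction_ids = c(1L, 999L))
  expect_equal(prev0$prevalence[prev0$junction_id == 999], 0)
  full <- build_junction_store(
    tibble::tibble(chrom = "c16", start = 766903L, end = 768491L, strand = "-",
                   sample_id = sprintf("s%03d", 1:430), reads = 1L),
    phen)
  expect_equal(cohort_prevalence(full, "OV")$prevalence, 1)
  expect_error(cohort_prevalence(store, "GHOST"), "no samples")
})

test_that("prevalence conservation: positives sum to presence pairs", {
  s <- random_study(31)
  store <- build_junction_store(s$evidence, s$phenotypes)
  for (cc in unique(s$phenotypes$cohort[s$phenotypes$cohort_class == "tumor"])) {
    prev <- cohort_prevalence(store, cc)
    pairs <- s$evidence |>
      dplyr::distinct(chrom, start, end, strand, sample_id) |>
      dplyr::semi_join(s$phenotypes[s$phenotypes$cohort == cc, ], by = "sample_id")
    expect_equal(sum(prev$n_positive), nrow(pairs))
  }
})

test_that("prevalence equals the brute-force scan", {
  s <- random_study(55)
  store <- build_junction_store(s$evidence, s$phenotypes)
  cc <- s$phenotypes$cohort[s$phenotypes$cohort_class == "tumor"][1]
  prev <- cohort_prevalence(store, cc) |>
    dplyr::inner_join(store$junctions, by = "junction_id") |>
    dplyr::mutate(key = paste(chrom, start, end, strand)) |>
    dplyr::arrange(key)
  orc <- oracle_prevalence(s$evidence, s$phenotypes, cc)
  expect_equal(prev$key, orc$key)
  expect_equal(prev$n_positive, orc$n_positive)
  expect_equal(prev$prevalence, orc$prevalence)
})

test_that("shared panels respect stage, prevalence floor, cap and tie-break", {
  # 30 qualifying junctions, cap at 10, with tied counts to exercise ordering
  n_s <- 100
  phen <- tibble::tibble(sample_id = sprintf("s%03d", 1:n_s),
                         cohort = "CAN", cohort_class = "tumor")
  ev <- purrr::map(1:30, function(j) {
    npos <- c(5, 5, 4, 3, 2)[1 + (j - 1) %% 5]  # many ties
    tibble::tibble(chrom = c("c2", "c1")[1 + j %% 2], start = 1000L - 10L * j,
                   end = 1000L - 10L * j + 5L, strand = "+",
                   sample_id = sample(phen$sample_id, npos), reads = 2L)
  }) |> dplyr::bind_rows()
  # one junction below the 1% floor and one exactly at it
  ev <- dplyr::bind_rows(
    ev,
    tibble::tibble(chrom = "c0", start = 1L, end = 6L, strand = "+",
                   sample_id = "s001", reads = 2L),
    tibble::tibble(chrom = "c0", start = 10L, end = 16L, strand = "+",
                   sample_id = "s001", reads = 2L))
  store <- build_junction_store(ev, phen)
  nov <- tibble::tibble(cohort = "CAN", junction_id = store$junctions$junction_id,
                        stage = factor("2+", levels = c("0", "1+", "2+", "3+"), ordered = TRUE))
  set.seed(1)
  panel <- select_shared_panel(store, nov, "CAN", cap = 10, min_prevalence = 0.01)
  expect_lte(nrow(panel), 10)
  expect_true(all(panel$prevalence >= 0.01))
  # brute-force sort oracle
  prev <- cohort_prevalence(store, "CAN") |>
    dplyr::inner_join(store$junctions, by = "junction_id")
  ord <- prev[order(-prev$n_positive, prev$chrom, prev$start, prev$end), ]
  expect_equal(panel$junction_id, head(ord$junction_id, 10))
  # a junction at exactly 1% prevalence (1/100) is admitted under the cap
  small <- select_shared_panel(store, nov, "CAN", cap = 200, min_prevalence = 0.01)
  expect_true(all(store$junctions$junction_id[store$junctions$chrom == "c0"] %in%
                    small$junction_id))
  # stage filter: junctions below 2+ are excluded
  nov0 <- dplyr::mutate(nov, stage = factor("1+", levels = levels(nov$stage), ordered = TRUE))
  expect_equal(nrow(select_shared_panel(store, nov0, "CAN")), 0)
  # recomputation is byte-identical (deterministic tie-break)
  expect_identical(panel, select_shared_panel(store, nov, "CAN", cap = 10, min_prevalence = 0.01))
})

test_that("cross-cohort sharing uses inclusive thresholds", {
  prev <- tibble::tibble(
    cohort = c("A", "B", "A", "A", "B"),
    junction_id = c(1L, 1L, 2L, 3L, 3L),
    n_positive = c(5L, 5L, 20L, 4L, 1L),
    cohort_size = 100L
  ) |> dplyr::mutate(prevalence = n_positive / cohort_size)
  out <- cross_cohort_sharing(prev, threshold = 0.05, min_cohorts = 2)
  expect_equal(out$junction_id, 1L)   # exactly 5% in two cohorts counts
  expect_false(2L %in% out$junction_id)  # 20% in one cohort only
  expect_error(cross_cohort_sharing(prev, threshold = 0), "threshold")
})

test_that("singleton fraction handles the boundary cases", {
  store <- tiny_store()
  jx <- store$junctions
  # j4 (start 40) is in two tumor samples; j6 (start 60) in one
  ids_single <- jx$junction_id[jx$start == 60]
  ids_multi <- jx$junction_id[jx$start == 40]
  expect_equal(singleton_fraction(store, ids_single), 1)
  expect_equal(singleton_fraction(store, ids_multi), 0)
  expect_message(v <- singleton_fraction(store, integer(0)), "undefined")
  expect_true(is.na(v))
})

test_that("prevalence matrices carry panel unions with zeros for absences", {
  store <- tiny_store(filtered = TRUE)
  s <- tiny_study()
  nov <- assign_novelty(store, s$match_map)
  panels <- purrr::map(c("CAN1", "CAN2"),
                       ~ select_shared_panel(store, nov, .x, min_prevalence = 0.01))
  pm <- build_prevalence_matrix(store, panels)
  m <- as.matrix(pm)
  expect_setequal(colnames(m), c("CAN1", "CAN2"))
  expect_true(all(apply(m, 1, max) >= 0.01))
  # single panel, single cohort: the column equals the panel's prevalences
  pm1 <- build_prevalence_matrix(store, panels[[1]], cohorts = "CAN1")
  p1 <- panels[[1]]
  expect_equal(as.matrix(pm1)[junction_key(p1$chrom, p1$start, p1$end, p1$strand), "CAN1"],
               setNames(p1$prevalence, junction_key(p1$chrom, p1$start, p1$end, p1$strand)))
  expect_error(build_prevalence_matrix(store, list()), "empty")
})

test_that("the rank test matches hand derivation and flags degeneracy", {
  out <- compare_prevalence_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, oracle_kw_h(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-10)
  expect_equal(out$statistic, 3.857143, tolerance = 1e-6)
  same <- compare_prevalence_distributions(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_lt(same$statistic, 0.1)
  expect_gt(same$p_value, 0.9)
  deg <- compare_prevalence_distributions(c(1, 1), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(compare_prevalence_distributions(numeric(0), 1), "nonempty")
})

test_that("chi-squared p approximates the exact permutation distribution", {
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(1, 5, 6), b = c(2, 3, 4)),
    list(a = c(2, 9, 7, 1), b = c(5, 3, 8, 6))
  )
  # at n = 6-8 the 1-df chi-squared approximation has absolute error up to
  # ~0.2 against the exact permutation law; it shrinks with n
  ps <- purrr::map_dfr(cases, function(cs) {
    tibble::tibble(p_chi = compare_prevalence_distributions(cs$a, cs$b)$p_value,
                   p_perm = oracle_kw_perm_p(cs$a, cs$b))
  })
  expect_true(all(abs(ps$p_chi - ps$p_perm) < 0.25))
  # the approximation preserves the ordering of evidence strength
  expect_equal(order(ps$p_chi), order(ps$p_perm))
})
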