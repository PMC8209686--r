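#' Assign stage-2+ junctions to SRA non-cancer evidence sets
#'
#' For every (cancer cohort, stage-2+ junction) pair, records positive-sample
#' counts in each SRA non-cancer broad group — adult, developmental
#' (excluding placenta), placenta, stem — plus the cohort's matched SRA
#' cancer category when one is declared, and derives membership flags and the
#' `unexplained` status (no evidence in any non-cancer group). SRA junctions
#' with no tumor evidence never enter: assignment is restricted to junctions
#' of the novelty table. Matched SRA *cancer* evidence never affects
#' unexplained status; it only feeds the sharedness replication test.
#'
#' Rules:
#' * `"default"`: a group flag is true iff the junction has >= 1 read in >= 1
#'   sample of that group (the developmental flag requires a non-placenta
#'   developmental sample; placenta-only evidence sets only the placenta
#'   flag).
#' * `"two_sample"`: a broad-group flag requires >= 2 positive samples summed
#'   across the group's categories; for subsets of the developmental group
#'   (including placenta), one sample within the subset suffices as long as
#'   the two-sample criterion across the full developmental group (placenta
#'   included) is met.
#'
#' @param store A `junction_store`.
#' @param novelty Output of [assign_novelty()].
#' @param sra_cancer_map Optional named character vector mapping cancer
#'   cohort -> matched SRA cancer cohort name.
#' @param rule `"default"` (one-sample) or `"two_sample"`.
#' @return A tibble (`cohort`, `junction_id`, per-group positive-sample
#'   counts `n_adult`, `n_developmental`, `n_placenta`, `n_stem`,
#'   `n_sra_cancer_matched`, flags `in_sra_adult`, `in_sra_developmental`,
#'   `in_sra_placenta`, `in_sra_stem`, `in_sra_cancer_matched`,
#'   `unexplained`, and the exclusive `combination` label). The rule used is
#'   stored in attribute `"rule"`.
#' @export
assign_sets <- function(store, novelty, sra_cancer_map = NULL,
                        rule = c("default", "two_sample")) {
  rule <- match.arg(rule)
  samples <- store$samples
  if (any(is.na(samples$cohort) | !nzchar(samples$cohort))) {
    abort("sample(s) with no category label")
  }
  stage2 <- novelty |> filter(.data$stage >= "2+") |> select("cohort", "junction_id")

  sra <- store$evidence |>
    inner_join(samples |> filter(.data$cohort_class %in% c(sra_noncancer_classes, "sra_cancer")) |>
                 select("sample_id", sra_cohort = "cohort", "cohort_class"),
               by = "sample_id") |>
    semi_join(stage2, by = "junction_id")
  counts <- sra |>
    filter(.data$cohort_class != "sra_cancer") |>
    count(.data$junction_id, .data$cohort_class, name = "n_samples") |>
    pivot_wider(names_from = "cohort_class", values_from = "n_samples", values_fill = 0L)
  for (cl in sra_noncancer_classes) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  out <- stage2 |>
    left_join(counts, by = "junction_id") |>
    mutate(across(all_of(sra_noncancer_classes), ~ replace_na(.x, 0L))) |>
    rename(n_adult = "sra_adult", n_developmental = "sra_developmental",
           n_placenta = "sra_placenta", n_stem = "sra_stem")

  # matched SRA cancer counts are cohort-specific
  out$n_sra_cancer_matched <- 0L
  if (!is.null(sra_cancer_map) && length(sra_cancer_map)) {
    cancer_counts <- sra |>
      filter(.data$cohort_class == "sra_cancer") |>
      count(.data$junction_id, .data$sra_cohort, name = "n")
    for (cc in intersect(unique(out$cohort), names(sra_cancer_map))) {
      hits <- cancer_counts |> filter(.data$sra_cohort == sra_cancer_map[[cc]])
      idx <- out$cohort == cc
      m <- match(out$junction_id[idx], hits$junction_id)
      out$n_sra_cancer_matched[idx] <- ifelse(is.na(m), 0L, hits$n[m])
    }
  }

  if (rule == "default") {
    out <- out |>
      mutate(
        in_sra_adult = .data$n_adult >= 1,
        in_sra_developmental = .data$n_developmental >= 1,
        in_sra_placenta = .data$n_placenta >= 1,
        in_sra_stem = .data$n_stem >= 1
      )
  } else {
    # developmental group total includes placenta (a developmental subset)
    out <- out |>
      mutate(
        dev_group = .data$n_developmental + .data$n_placenta,
        in_sra_adult = .data$n_adult >= 2,
        in_sra_developmental = .data$n_developmental >= 1 & .data$dev_group >= 2,
        in_sra_placenta = .data$n_placenta >= 1 & .data$dev_group >= 2,
        in_sra_stem = .data$n_stem >= 2
      ) |>
      select(-"dev_group")
  }
  out <- out |>
    mutate(
      in_sra_cancer_matched = .data$n_sra_cancer_matched >= 1,
      unexplained = !(.data$in_sra_adult | .data$in_sra_developmental |
                        .data$in_sra_placenta | .data$in_sra_stem),
      combination = set_combination_label(
        .data$in_sra_adult, .data$in_sra_developmental,
        .data$in_sra_placenta, .data$in_sra_stem
      )
    )
  attr(out, "rule") <- rule
  out
}

set_combination_label <- function(adult, developmental, placenta, stem) {
  lab <- mapply(function(a, d, p, s) {
    parts <- c("adult", "developmental", "placenta", "stem")[c(a, d, p, s)]
    if (length(parts) == 0) "unexplained" else paste(parts, collapse = "+")
  }, adult, developmental, placenta, stem)
  as.character(lab)
}

#' Re-derive set assignments under the two-sample rule
#'
#' Convenience wrapper around [assign_sets()] with `rule = "two_sample"`: a
#' strictly more conservative filter whose flagged sets are subsets of the
#' default rule's, so its unexplained set is a superset.
#'
#' @inheritParams assign_sets
#' @export
apply_two_sample_rule <- function(store, novelty, sra_cancer_map = NULL) {
  assign_sets(store, novelty, sra_cancer_map, rule = "two_sample")
}

#' Upset-style summary of set memberships
#'
#' Per cancer cohort, reports junction counts and percentages of the cohort's
#' stage-2+ junctions for every observed exclusive set combination
#' (`kind = "overlap"`; these partition to 100%) and for each set marginal
#' (`kind = "set"`; marginals overlap and need not sum to 100%).
#'
#' @param assignments Output of [assign_sets()].
#' @return A tibble (`cohort`, `kind`, `label`, `n`, `percent`).
#' @export
upset_summary <- function(assignments) {
  cohorts <- unique(assignments$cohort)
  res <- map(cohorts, function(cc) {
    a <- assignments |> filter(.data$cohort == cc)
    if (nrow(a) == 0) {
      warn(paste0("cohort ", cc, " has no stage-2+ junctions"))
      return(NULL)
    }
    overlaps <- a |>
      count(.data$combination, name = "n") |>
      transmute(cohort = cc, kind = "overlap", label = .data$combination,
                n = .data$n, percent = 100 * .data$n / nrow(a))
    sets <- tibble(
      cohort = cc, kind = "set",
      label = c("adult", "developmental", "placenta", "stem", "unexplained"),
      n = c(sum(a$in_sra_adult), sum(a$in_sra_developmental),
            sum(a$in_sra_placenta), sum(a$in_sra_stem), sum(a$unexplained))
    ) |> mutate(percent = 100 * .data$n / nrow(a))
    bind_rows(sets, overlaps)
  })
  bind_rows(res)
}

#' Sharedness of junctions replicated in matched SRA cancer cohorts
#'
#' For a cancer cohort with a declared matched SRA cancer category, compares
#' the within-cohort positive-sample counts (sharedness) of stage-2+
#' junctions that are vs are not present in the matched SRA cancer set, via
#' the Kruskal-Wallis test. Cohorts without a matched category are skipped
#' with a notice; single-junction groups yield a flagged degenerate result
#' rather than an error.
#'
#' @param store A `junction_store`.
#' @param novelty Output of [assign_novelty()].
#' @param assignments Output of [assign_sets()] computed with the matching
#'   `sra_cancer_map`.
#' @param cohorts Cohorts to test (default: all cohorts in `assignments`).
#' @return A tibble (`cohort`, `statistic`, `df`, `p_value`, `n_in`, `n_out`,
#'   `degenerate`, `skipped`).
#' @export
matched_cancer_sharedness_test <- function(store, novelty, assignments, cohorts = NULL) {
  cohorts <- cohorts %||% sort(unique(assignments$cohort))
  res <- map(cohorts, function(cc) {
    a <- assignments |> filter(.data$cohort == cc)
    if (nrow(a) == 0 || all(!a$in_sra_cancer_matched)) {
      inform(paste0("cohort ", cc, " has no matched SRA cancer evidence; skipped"))
      return(tibble(cohort = cc, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, n_in = sum(a$in_sra_cancer_matched),
                    n_out = sum(!a$in_sra_cancer_matched),
                    degenerate = NA, skipped = TRUE))
    }
    prev <- cohort_prevalence(store, cohorts = cc, junction_ids = a$junction_id)
    x <- prev$n_positive[match(a$junction_id, prev$junction_id)]
    grp_in <- x[a$in_sra_cancer_matched]
    grp_out <- x[!a$in_sra_cancer_matched]
    if (length(grp_out) == 0) {
      return(tibble(cohort = cc, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, n_in = length(grp_in), n_out = 0L,
                    degenerate = TRUE, skipped = FALSE))
    }
    kw <- compare_prevalence_distributions(grp_in, grp_out)
    tibble(cohort = cc, statistic = kw$statistic, df = kw$df, p_value = kw$p_value,
           n_in = length(grp_in), n_out = length(grp_out),
           degenerate = kw$degenerate | length(grp_in) < 2 | length(grp_out) < 2,
           skipped = FALSE)
  })
  bind_rows(res)
}
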