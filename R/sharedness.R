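#' Junction prevalence within cohorts
#'
#' Prevalence of a junction in a cohort is the fraction of the cohort's
#' samples with at least one supporting read. One row is returned per
#' (junction, cohort); when `junction_ids` is supplied, junctions absent from
#' a cohort get an explicit zero row.
#'
#' @param store A `junction_store`.
#' @param cohorts Cohorts to evaluate (default: all tumor cohorts).
#' @param junction_ids Optional junction subset; default: junctions with any
#'   evidence in the cohort.
#' @return A tibble (`cohort`, `junction_id`, `n_positive`, `cohort_size`,
#'   `prevalence`).
#' @export
cohort_prevalence <- function(store, cohorts = NULL, junction_ids = NULL) {
  samples <- store$samples
  cohorts <- cohorts %||% sort(unique(samples$cohort[samples$cohort_class == "tumor"]))
  sizes <- samples |> filter(.data$cohort %in% cohorts) |> count(.data$cohort, name = "cohort_size")
  empty <- setdiff(cohorts, sizes$cohort)
  if (length(empty)) {
    abort(paste0("cohort(s) with no samples: ", paste(empty, collapse = ", ")))
  }
  counts <- store$evidence |>
    inner_join(samples |> filter(.data$cohort %in% cohorts) |> select("sample_id", "cohort"),
               by = "sample_id") |>
    distinct(.data$junction_id, .data$cohort, .data$sample_id) |>
    count(.data$cohort, .data$junction_id, name = "n_positive")
  if (!is.null(junction_ids)) {
    counts <- counts |>
      filter(.data$junction_id %in% junction_ids) |>
      complete(cohort = cohorts, junction_id = junction_ids,
               fill = list(n_positive = 0L))
  }
  counts |>
    inner_join(sizes, by = "cohort") |>
    mutate(prevalence = .data$n_positive / .data$cohort_size) |>
    arrange(.data$cohort, .data$junction_id)
}

#' Select a cohort's shared-junction panel
#'
#' The panel comprises up to `cap` most highly recurring junctions that occur
#' in at least `min_prevalence` of the cohort's samples and are not found in
#' any core normal sample (novelty stage 2+ or higher in this cohort).
#' Ordering is by descending positive-sample count with a deterministic
#' genomic tie-break (chromosome, start, end ascending).
#'
#' @param store A `junction_store`.
#' @param novelty Output of [assign_novelty()].
#' @param cohort Cancer cohort name.
#' @param cap Maximum panel size (default 200).
#' @param min_prevalence Minimum within-cohort prevalence (default 0.01,
#'   inclusive).
#' @return A tibble (`cohort`, `rank`, `junction_id`, coordinates,
#'   `n_positive`, `cohort_size`, `prevalence`).
#' @export
select_shared_panel <- function(store, novelty, cohort, cap = 200, min_prevalence = 0.01) {
  stage2 <- novelty |>
    filter(.data$cohort == !!cohort, .data$stage >= "2+")
  prev <- cohort_prevalence(store, cohorts = cohort) |>
    semi_join(stage2, by = "junction_id") |>
    filter(.data$prevalence >= min_prevalence)
  prev |>
    inner_join(store$junctions, by = "junction_id") |>
    arrange(desc(.data$n_positive), .data$chrom, .data$start, .data$end) |>
    head(cap) |>
    mutate(rank = row_number(), .after = "cohort") |>
    select("cohort", "rank", "junction_id", "chrom", "start", "end", "strand",
           "n_positive", "cohort_size", "prevalence")
}

#' Junctions shared across cancer cohorts
#'
#' Counts junctions whose prevalence reaches `threshold` in at least
#' `min_cohorts` cancer cohorts (both comparisons inclusive: "at least 5% of
#' samples each across two or more cohorts").
#'
#' @param prevalence A prevalence tibble from [cohort_prevalence()].
#' @param threshold Per-cohort prevalence threshold (default 0.05).
#' @param min_cohorts Minimum number of qualifying cohorts (default 2).
#' @return A tibble (`junction_id`, `n_cohorts`, `cohorts`) of qualifying
#'   junctions; the count is `nrow()` of the result.
#' @export
cross_cohort_sharing <- function(prevalence, threshold = 0.05, min_cohorts = 2) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  prevalence |>
    filter(.data$prevalence >= threshold) |>
    group_by(.data$junction_id) |>
    summarise(n_cohorts = dplyr::n_distinct(.data$cohort),
              cohorts = paste(sort(unique(.data$cohort)), collapse = ";"),
              .groups = "drop") |>
    filter(.data$n_cohorts >= min_cohorts)
}

#' Fraction of junctions confined to individual samples
#'
#' Among a set of junctions (typically the union of stage-2+ junctions over
#' cohorts), the fraction whose total positive-sample count across all tumor
#' samples equals one.
#'
#' @param store A `junction_store`.
#' @param junction_ids Junction IDs to assess.
#' @return A single fraction, or `NA` (with a message) for an empty set.
#' @export
singleton_fraction <- function(store, junction_ids) {
  junction_ids <- unique(junction_ids)
  if (length(junction_ids) == 0) {
    inform("empty junction set: singleton fraction is undefined")
    return(NA_real_)
  }
  tumor <- store$samples$sample_id[store$samples$cohort_class == "tumor"]
  counts <- store$evidence |>
    filter(.data$junction_id %in% junction_ids, .data$sample_id %in% tumor) |>
    count(.data$junction_id)
  n_single <- sum(counts$n == 1)
  n_single / length(junction_ids)
}

#' Prevalence matrix over shared-junction panels
#'
#' Builds the junction-by-cohort prevalence matrix underlying the clustering
#' heatmaps: rows are the deduplicated union of the given panels' junctions,
#' columns the requested cohorts, cells the within-cohort prevalence (0 when a
#' junction is absent from a cohort). Row and column order is deterministic
#' (genomic order; cohort name order).
#'
#' @param store A `junction_store`.
#' @param panels A list of panels from [select_shared_panel()] (or one tibble).
#' @param cohorts Cohorts for the columns (default: all tumor cohorts).
#' @return A tibble of class `prevalence_matrix` with a `junction_id` +
#'   coordinate columns and one prevalence column per cohort; `as.matrix()`
#'   drops the coordinate columns.
#' @export
build_prevalence_matrix <- function(store, panels, cohorts = NULL) {
  if (is.data.frame(panels)) panels <- list(panels)
  ids <- sort(unique(unlist(map(panels, ~ .x$junction_id))))
  if (length(ids) == 0) abort("union of panel junctions is empty")
  cohorts <- cohorts %||% sort(unique(store$samples$cohort[store$samples$cohort_class == "tumor"]))
  prev <- cohort_prevalence(store, cohorts = cohorts, junction_ids = ids)
  wide <- prev |>
    select("cohort", "junction_id", "prevalence") |>
    pivot_wider(names_from = "cohort", values_from = "prevalence", values_fill = 0) |>
    inner_join(store$junctions |> select("junction_id", "chrom", "start", "end", "strand"),
               by = "junction_id") |>
    relocate("chrom", "start", "end", "strand", .after = "junction_id") |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  structure(wide, class = c("prevalence_matrix", class(wide)))
}

#' @export
as.matrix.prevalence_matrix <- function(x, ...) {
  meta <- c("junction_id", "chrom", "start", "end", "strand")
  m <- as.matrix(as.data.frame(x)[, setdiff(names(x), meta), drop = FALSE])
  rownames(m) <- junction_key(x$chrom, x$start, x$end, x$strand)
  m
}

#' Compare two prevalence (sharedness) distributions
#'
#' Rank-based Kruskal-Wallis H test with tie correction; for two groups the
#' p-value uses the chi-squared approximation with 1 degree of freedom. Used
#' both for the decreased sharedness of junctions absent from core normals
#' and for the increased sharedness of junctions replicated in matched
#' auxiliary cancer cohorts.
#'
#' @param group_a,group_b Nonempty numeric vectors (prevalences or
#'   positive-sample counts).
#' @return A one-row tibble (`statistic`, `df`, `p_value`, `n_a`, `n_b`,
#'   `degenerate`). When every value across both groups is identical the
#'   result is the degenerate H = 0, p = 1, flagged.
#' @export
compare_prevalence_distributions <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be nonempty")
  }
  vals <- c(group_a, group_b)
  if (length(unique(vals)) == 1) {
    return(tibble(statistic = 0, df = 1L, p_value = 1,
                  n_a = length(group_a), n_b = length(group_b), degenerate = TRUE))
  }
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  kt <- kruskal.test(vals, grp)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_a = length(group_a), n_b = length(group_b),
         degenerate = FALSE)
}
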