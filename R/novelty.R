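#' Global evidence filter
#'
#' Retains junctions whose read counts summed over *all* samples of *all*
#' cohorts (tumor, normal and auxiliary alike) reach `min_total_reads`. The
#' default of 2 excludes single-read false positives while allowing splicing
#' noise; there is deliberately no per-sample minimum, so one read in a tumor
#' sample plus one read in a normal sample passes.
#'
#' @param store A `junction_store`.
#' @param min_total_reads Minimum summed read count (default 2).
#' @return The store restricted to retained junctions, with the removed
#'   junction IDs in attribute `"removed_junctions"`.
#' @export
apply_read_filter <- function(store, min_total_reads = 2) {
  stopifnot(min_total_reads >= 1)
  totals <- store$evidence |>
    group_by(.data$junction_id) |>
    summarise(total = sum(.data$reads), .groups = "drop")
  keep <- totals$junction_id[totals$total >= min_total_reads]
  out <- new_junction_store(
    junctions = store$junctions |> filter(.data$junction_id %in% keep),
    evidence = store$evidence |> filter(.data$junction_id %in% keep),
    samples = store$samples
  )
  attr(out, "removed_junctions") <- setdiff(store$junctions$junction_id, keep)
  out
}

#' Presence of junctions in a set of cohorts
#'
#' A junction is "in" a cohort set when it has at least one read in at least
#' one sample of any of the cohorts — presence at any coverage level in a
#' single sample counts. Presence over a union of cohorts is the OR of
#' per-cohort presences.
#'
#' @param store A `junction_store`.
#' @param cohorts Character vector of cohort names (must exist in the store).
#' @param junction_ids Optional subset of junction IDs (default: all).
#' @return A tibble (`junction_id`, `present`).
#' @export
cohort_presence <- function(store, cohorts, junction_ids = NULL) {
  if (length(cohorts) == 0) abort("cohort set must be nonempty")
  unknown <- setdiff(cohorts, unique(store$samples$cohort))
  if (length(unknown)) {
    abort(paste0("unknown cohort(s): ", paste(unknown, collapse = ", ")))
  }
  ids <- junction_ids %||% store$junctions$junction_id
  in_set <- store$evidence |>
    semi_join(store$samples |> filter(.data$cohort %in% cohorts), by = "sample_id") |>
    distinct(.data$junction_id)
  tibble(junction_id = ids, present = ids %in% in_set$junction_id)
}

core_normal_classes <- c("matched_normal", "gtex_normal")
sra_noncancer_classes <- c("sra_adult", "sra_developmental", "sra_placenta", "sra_stem")

#' Assign junction novelty stages per cancer cohort
#'
#' Classifies every junction present in each cancer cohort through the
#' hierarchical cancer-specificity filter:
#'
#' * stage `0`: all junctions of the cohort;
#' * stage `1+`: not found in the cohort's tissue-matched normal samples
#'   (per `match_map`);
#' * stage `2+`: not found in *any* core normal sample (all GTEx-style normal
#'   tissues plus the matched-normal samples of every cancer cohort);
#' * stage `3+`: additionally not found in any selected SRA non-cancer sample
#'   (adult, developmental, placenta or stem-cell categories).
#'
#' Exclusion is strict: a single read in one sample of the target normal set
#' eliminates the junction from the stage. Cancer cohorts with an empty match
#' set have no tissue-matched comparison; their junctions are classed 0 vs 2+
#' directly and flagged `stage1_evaluable = FALSE`.
#'
#' @param store A `junction_store`, normally after [apply_read_filter()].
#' @param match_map Named list: cancer cohort -> character vector of
#'   tissue-matched normal cohorts (may be empty). Every tumor cohort in the
#'   store must appear as a key, and match sets may only reference declared
#'   cohorts.
#' @return A tibble (`cohort`, `junction_id`, `stage` (ordered factor
#'   `0 < 1+ < 2+ < 3+`), `in_tissue_matched`, `in_core_normal`,
#'   `in_sra_noncancer`, `stage1_evaluable`).
#' @export
assign_novelty <- function(store, match_map) {
  samples <- store$samples
  cancers <- sort(unique(samples$cohort[samples$cohort_class == "tumor"]))
  missing <- setdiff(cancers, names(match_map))
  if (length(missing)) {
    abort(paste0("match_map lacks key(s) for cancer cohort(s): ",
                 paste(missing, collapse = ", ")))
  }
  declared <- unique(samples$cohort)
  bad <- setdiff(unlist(match_map, use.names = FALSE), declared)
  if (length(bad)) {
    abort(paste0("match_map references undeclared cohort(s): ",
                 paste(bad, collapse = ", ")))
  }

  pres <- store$evidence |>
    inner_join(samples |> select("sample_id", "cohort", "cohort_class"), by = "sample_id") |>
    distinct(.data$junction_id, .data$cohort, .data$cohort_class)
  in_core <- unique(pres$junction_id[pres$cohort_class %in% core_normal_classes])
  in_sra <- unique(pres$junction_id[pres$cohort_class %in% sra_noncancer_classes])

  out <- map(cancers, function(cc) {
    ids <- sort(unique(pres$junction_id[pres$cohort == cc & pres$cohort_class == "tumor"]))
    if (length(ids) == 0) return(NULL)
    matched <- match_map[[cc]]
    evaluable <- length(matched) > 0
    in_tm <- if (evaluable) {
      ids %in% unique(pres$junction_id[pres$cohort %in% matched])
    } else {
      rep(NA, length(ids))
    }
    core <- ids %in% in_core
    sra <- ids %in% in_sra
    stage <- ifelse(!core & !sra, "3+",
             ifelse(!core, "2+",
             ifelse(evaluable & !(in_tm %in% TRUE), "1+", "0")))
    tibble(cohort = cc, junction_id = ids,
           stage = stage, in_tissue_matched = in_tm,
           in_core_normal = core, in_sra_noncancer = sra,
           stage1_evaluable = evaluable)
  })
  bind_rows(out) |>
    mutate(stage = factor(.data$stage, levels = c("0", "1+", "2+", "3+"), ordered = TRUE))
}
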