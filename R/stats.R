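#' Per-patient junction burden
#'
#' The burden is the number of a patient's junctions absent from all core
#' normals divided by the sample's mapped read count over 10 000 — a per-Mb
#' scaling under the assumption of 100-bp reads.
#'
#' @param n_junctions Count(s) of stage-2+ junctions per patient.
#' @param mapped_reads Mapped read count(s); must be positive.
#' @return Numeric burden value(s): `n_junctions / (mapped_reads / 10000)`.
#' @examples
#' junction_burden(100, 1e6) # 1.0
#' @export
junction_burden <- function(n_junctions, mapped_reads) {
  if (any(mapped_reads <= 0)) abort("mapped_reads must be positive")
  if (any(n_junctions < 0)) abort("n_junctions must be non-negative")
  n_junctions / (mapped_reads / 10000)
}

#' Per-patient burden table from a store
#'
#' Counts, for each tumor sample, its junctions at novelty stage 2+ in the
#' sample's cohort, and scales by the sample's mapped read count (phenotype
#' column `mapped_reads`).
#'
#' @param store A `junction_store` whose phenotypes carry `mapped_reads`.
#' @param novelty Output of [assign_novelty()].
#' @return A tibble (`sample_id`, `cohort`, `n_stage2_junctions`,
#'   `mapped_reads`, `burden`).
#' @export
patient_burden <- function(store, novelty) {
  tumor <- store$samples |> filter(.data$cohort_class == "tumor")
  if (!"mapped_reads" %in% names(tumor)) abort("phenotypes lack 'mapped_reads'")
  stage2 <- novelty |> filter(.data$stage >= "2+")
  counts <- store$evidence |>
    inner_join(tumor |> select("sample_id", "cohort"), by = "sample_id") |>
    semi_join(stage2, by = c("junction_id", "cohort")) |>
    count(.data$sample_id, name = "n_stage2_junctions")
  tumor |>
    select("sample_id", "cohort", "mapped_reads") |>
    left_join(counts, by = "sample_id") |>
    mutate(n_stage2_junctions = replace_na(.data$n_stage2_junctions, 0L),
           burden = junction_burden(.data$n_stage2_junctions, .data$mapped_reads)) |>
    relocate("n_stage2_junctions", .after = "cohort")
}

#' Ordinary least squares of junction burden on tumor mutational burden
#'
#' @param records A tibble with numeric columns `burden` and `tmb` (silent +
#'   non-silent mutations per Mb).
#' @return An object of class `burden_tmb_fit` with [generics::tidy()] and
#'   [generics::glance()] methods. A constant-TMB input yields a degenerate
#'   fit, flagged rather than an error.
#' @export
regress_burden_vs_tmb <- function(records) {
  stopifnot(all(c("burden", "tmb") %in% names(records)))
  if (nrow(records) < 3) abort("need at least 3 records")
  degenerate <- var(records$tmb) == 0
  fit <- if (degenerate) NULL else lm(burden ~ tmb, data = records)
  structure(list(fit = fit, n = nrow(records), degenerate = degenerate),
            class = "burden_tmb_fit")
}

#' @export
print.burden_tmb_fit <- function(x, ...) {
  cat("<burden_tmb_fit> n =", x$n, if (x$degenerate) "(degenerate: constant TMB)" else "", "\n")
  if (!x$degenerate) print(glance(x))
  invisible(x)
}

#' @rdname regress_burden_vs_tmb
#' @param x A `burden_tmb_fit`.
#' @param ... Unused.
#' @export
tidy.burden_tmb_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble(term = c("(Intercept)", "tmb"), estimate = NA_real_,
                  std.error = NA_real_, statistic = NA_real_, p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname regress_burden_vs_tmb
#' @export
glance.burden_tmb_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                  r.squared = NA_real_, p.value = NA_real_, n = x$n, degenerate = TRUE))
  }
  s <- summary(x$fit)
  co <- coef(x$fit)
  slope <- unname(co["tmb"])
  tibble(slope = slope, intercept = unname(co["(Intercept)"]),
         r = sign(slope) * sqrt(s$r.squared), r.squared = s$r.squared,
         p.value = unname(s$coefficients["tmb", 4]), n = x$n, degenerate = FALSE)
}

#' The sQTL-associated splicing gene set
#'
#' The five genes previously identified as sQTL associated in the TCGA
#' cohort, used as the second patient-stratification criterion.
#' @export
sqtl_genes <- c("U2AF1", "SF3B1", "TADA1", "PPP2R1A", "IDH1")

#' Stratify patients by splicing-gene mutation status
#'
#' Marks each patient mutated under a criterion when they carry at least one
#' *non-synonymous* mutation in the criterion's gene set (`"sqtl_five_gene"`:
#' the fixed five-gene sQTL set, overridable; `"uniprot_splicing"`: a
#' supplied splicing-annotated gene list). Synonymous/silent calls never
#' count. Multi-sample patients collapse to one row.
#'
#' @param mutations Mutation-call tibble (`patient_id`, `gene`,
#'   `variant_class`); classes containing "silent"/"synonymous"
#'   (case-insensitive, but not "non-synonymous") are ignored.
#' @param patients Character vector of all patient IDs (so unmutated patients
#'   get explicit FALSE rows).
#' @param criterion `"sqtl_five_gene"` or `"uniprot_splicing"`.
#' @param gene_set Gene set for the criterion; defaults to [sqtl_genes] for
#'   `"sqtl_five_gene"`, required for `"uniprot_splicing"`.
#' @return A tibble (`patient_id`, `criterion`, `mutated`).
#' @export
stratify_by_mutation <- function(mutations, patients,
                                 criterion = c("sqtl_five_gene", "uniprot_splicing"),
                                 gene_set = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(gene_set)) {
    if (criterion == "sqtl_five_gene") gene_set <- sqtl_genes
    else abort("uniprot_splicing criterion requires a gene_set")
  }
  silent <- grepl("silent|synonymous", mutations$variant_class, ignore.case = TRUE) &
    !grepl("non[-_ ]?synonymous", mutations$variant_class, ignore.case = TRUE)
  hit <- mutations |>
    filter(!silent, .data$gene %in% gene_set) |>
    distinct(.data$patient_id)
  tibble(patient_id = patients, criterion = criterion,
         mutated = patients %in% hit$patient_id)
}

#' Two-way ANOVA of junction counts by cancer type and mutation status
#'
#' Fits `n_junctions ~ cohort * mutated` and reports the factor table with
#' BH-adjusted p-values, plus per-cohort two-sample comparisons of mutated vs
#' non-mutated patients, BH-corrected across the family of per-cohort tests.
#' Factor levels with zero patients are dropped with a warning.
#'
#' @param counts A tibble (`patient_id`, `cohort`, `n_junctions`, `mutated`).
#' @return An object of class `mutation_anova`: list with `anova` (term,
#'   df, sumsq, statistic, p.value, p.adjusted) and `per_cohort` (cohort,
#'   n_mutated, n_unmutated, estimate, p.value, p.adjusted) tibbles.
#' @export
stratify_and_test_counts <- function(counts) {
  stopifnot(all(c("cohort", "n_junctions", "mutated") %in% names(counts)))
  counts <- counts |> filter(!is.na(.data$n_junctions))
  empties <- counts |> count(.data$cohort) |> filter(.data$n == 0)
  if (length(unique(counts$cohort)) < 2) abort("need >= 2 cohorts")
  if (length(unique(counts$mutated)) < 2) abort("both mutation strata must be nonempty")
  fit <- aov(n_junctions ~ cohort * mutated, data = counts)
  a <- anova(fit)
  terms <- rownames(a) != "Residuals"
  tab <- tibble(term = trimws(rownames(a)[terms]),
                df = a$Df[terms], sumsq = a$`Sum Sq`[terms],
                statistic = a$`F value`[terms], p.value = a$`Pr(>F)`[terms]) |>
    mutate(p.adjusted = p.adjust(.data$p.value, method = "BH"))
  per <- counts |>
    group_by(.data$cohort) |>
    group_map(function(g, key) {
      n_mut <- sum(g$mutated); n_un <- sum(!g$mutated)
      if (n_mut < 2 || n_un < 2) {
        warn(paste0("cohort ", key$cohort, ": a mutation stratum has < 2 patients; comparison dropped"))
        return(NULL)
      }
      tt <- t.test(n_junctions ~ mutated, data = g)
      tibble(cohort = key$cohort, n_mutated = n_mut, n_unmutated = n_un,
             estimate = unname(diff(rev(tt$estimate))), p.value = tt$p.value)
    }) |>
    bind_rows()
  if (nrow(per) > 0) per$p.adjusted <- p.adjust(per$p.value, method = "BH")
  structure(list(anova = tab, per_cohort = per, fit = fit), class = "mutation_anova")
}

#' @export
print.mutation_anova <- function(x, ...) {
  cat("<mutation_anova>\n")
  print(x$anova)
  invisible(x)
}

#' @export
tidy.mutation_anova <- function(x, ...) x$anova

#' @export
glance.mutation_anova <- function(x, ...) {
  tibble(p_mutation = x$anova$p.value[x$anova$term == "mutated"],
         p_cohort = x$anova$p.value[x$anova$term == "cohort"],
         p_interaction = x$anova$p.value[x$anova$term == "cohort:mutated"],
         n_per_cohort_tests = nrow(x$per_cohort))
}

#' Fisher's exact test of junction sharedness vs mutation status
#'
#' For a junction observed in a cancer cohort, tests whether its occurrences
#' concentrate in splicing-mutated patients: a two-sided Fisher's exact test
#' on the 2x2 table of junction-positive/negative by mutated/non-mutated
#' patients. Intended for junctions seen in two or more patients of the
#' cohort. The unit is patients, not samples.
#'
#' @param in_mutated Junction occurrences among mutated patients.
#' @param n_mutated Number of mutated patients in the cohort.
#' @param total Total junction occurrences in the cohort.
#' @param cohort_size Number of patients in the cohort.
#' @return A tibble (`odds_ratio`, `p_value`, `flagged`) with one row per
#'   input element; a zero table margin yields p = 1, odds ratio `NA`,
#'   flagged.
#' @export
fisher_sharedness_test <- function(in_mutated, n_mutated, total, cohort_size) {
  args <- vctrs::vec_recycle_common(in_mutated = in_mutated, n_mutated = n_mutated,
                                    total = total, cohort_size = cohort_size)
  n <- length(args$in_mutated)
  a <- args$in_mutated
  b <- args$n_mutated - a
  c_ <- args$total - a
  d <- (args$cohort_size - args$n_mutated) - c_
  if (any(c(a, b, c_, d) < 0)) abort("inconsistent 2x2 counts")
  odds_ratio <- rep(NA_real_, n)
  p_value <- rep(1, n)
  flagged <- (a + b) == 0 | (c_ + d) == 0 | (a + c_) == 0 | (b + d) == 0
  for (i in which(!flagged)) {
    ft <- fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2, byrow = TRUE),
                      alternative = "two.sided", conf.int = FALSE)
    odds_ratio[i] <- unname(ft$estimate)
    p_value[i] <- ft$p.value
  }
  tibble(odds_ratio = odds_ratio, p_value = p_value, flagged = flagged)
}

#' Kaplan-Meier survival for junction-positive patients
#'
#' Product-limit estimate with the censoring convention: patients with a
#' days-to-death value are events at that time; patients without are censored
#' at days to last follow-up. Patients with neither field are excluded with a
#' warning.
#'
#' @param survival_data A tibble with `days_to_death`, `days_to_last_followup`
#'   (either may be `NA`) and optionally the grouping column named by
#'   `group`.
#' @param group Optional name of a grouping column (e.g. a junction-positive
#'   flag).
#' @return An object of class `km_curve`: a tibble (`group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`) with the `survfit` object in
#'   attribute `"survfit"`. Curves start at 1 and are monotone
#'   non-increasing.
#' @export
km_survival <- function(survival_data, group = NULL) {
  d <- as_tibble(survival_data)
  stopifnot(all(c("days_to_death", "days_to_last_followup") %in% names(d)))
  no_data <- is.na(d$days_to_death) & is.na(d$days_to_last_followup)
  if (any(no_data)) {
    warn(paste0(sum(no_data), " patient(s) with neither days-to-death nor ",
                "days-to-last-follow-up excluded"))
    d <- d[!no_data, ]
  }
  d$time <- ifelse(!is.na(d$days_to_death), d$days_to_death, d$days_to_last_followup)
  d$event <- as.integer(!is.na(d$days_to_death))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    groups <- factor(rep("all", nrow(d)))
  } else {
    d$.group <- d[[group]]
    fit <- survival::survfit(survival::Surv(time, event) ~ .group, data = d)
    groups <- d$.group
  }
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep("all", length(s$time)) else
    sub("^\\.group=", "", as.character(s$strata))
  out <- tibble(group = strata, time = s$time, n_risk = s$n.risk,
                n_event = s$n.event, n_censor = s$n.censor, surv = s$surv)
  structure(out, class = c("km_curve", class(out)), survfit = fit)
}

#' @rdname km_survival
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) as_tibble(x)

#' @rdname km_survival
#' @export
glance.km_curve <- function(x, ...) {
  x |>
    group_by(.data$group) |>
    summarise(n_events = sum(.data$n_event), n_censored = sum(.data$n_censor),
              final_surv = .data$surv[which.max(.data$time)], .groups = "drop")
}
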