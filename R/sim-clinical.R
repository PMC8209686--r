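#' Describe planted clinical effects
#'
#' Bundles the planted effects the clinical generator realizes: the additive
#' shift in cancer-specific junction counts for splicing-mutated patients,
#' the baseline count distribution, the fraction of patients mutated, and the
#' survival hazard ratio for junction-positive patients.
#'
#' @param frac_mutated Fraction of patients with at least one non-synonymous
#'   splicing-gene mutation.
#' @param burden_mean,burden_sd Baseline per-patient cancer-specific junction
#'   count (normal, truncated at 0).
#' @param burden_shift Additive shift applied to mutated patients' counts
#'   (0 = planted null).
#' @param hazard_ratio Hazard ratio of junction-positive vs negative patients
#'   (1 = no survival effect).
#' @param frac_junction_positive Fraction of patients carrying the junction
#'   of interest.
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param censor_time Administrative censoring horizon (days).
#' @return A list of class `mutation_effect`.
#' @export
mutation_effect <- function(frac_mutated = 0.5, burden_mean = 100, burden_sd = 10,
                            burden_shift = 0, hazard_ratio = 1,
                            frac_junction_positive = 0.5,
                            baseline_hazard = 1 / 1500, censor_time = 3000) {
  structure(list(frac_mutated = frac_mutated, burden_mean = burden_mean,
                 burden_sd = burden_sd, burden_shift = burden_shift,
                 hazard_ratio = hazard_ratio,
                 frac_junction_positive = frac_junction_positive,
                 baseline_hazard = baseline_hazard, censor_time = censor_time),
            class = "mutation_effect")
}

#' Generate mutation, TMB and survival tables with planted effects
#'
#' Produces per-patient clinical fixtures keyed to the simulated tumor
#' samples: somatic mutation calls (non-synonymous splicing-gene mutations
#' for the planted mutated stratum, plus background and silent calls that
#' must not count), a mutational-burden table (silent and non-silent
#' mutations per Mb, mapped reads, and the planted cancer-specific junction
#' count realizing `burden_shift`), and a survival table with days-to-death
#' for deceased patients and censoring at days to last follow-up otherwise,
#' realizing `hazard_ratio` for junction-positive patients. TMB is drawn
#' independently of the junction count (no planted association).
#'
#' @param phenotypes Phenotype tibble from [simulate_phenotypes()] (or a
#'   `junction_sim`'s `$phenotypes`).
#' @param effect A [mutation_effect()].
#' @param seed Seed (defaults derive from nothing else; pass the study seed).
#' @param patients Optional explicit patient IDs; must exist in
#'   `phenotypes`, otherwise a consistency error is raised.
#' @return A list of class `clinical_sim` with tibbles `mutations`
#'   (`patient_id`, `gene`, `variant_class`), `tmb` (`patient_id`, `cohort`,
#'   `silent_per_mb`, `non_silent_per_mb`, `tmb`, `mapped_reads`,
#'   `n_stage2_junctions`, `mutated`), `survival` (`patient_id`,
#'   `junction_positive`, `days_to_death`, `days_to_last_followup`) and the
#'   splicing gene list used.
#' @export
simulate_clinical_tables <- function(phenotypes, effect = mutation_effect(),
                                     seed = 1, patients = NULL) {
  stopifnot(inherits(effect, "mutation_effect"))
  tumor <- phenotypes |> filter(.data$cohort_class == "tumor")
  if (!"patient_id" %in% names(tumor)) tumor$patient_id <- tumor$sample_id
  if (!"mapped_reads" %in% names(tumor)) tumor$mapped_reads <- NA_real_
  ids <- unique(tumor$patient_id)
  if (!is.null(patients)) {
    unknown <- setdiff(patients, ids)
    if (length(unknown)) {
      abort(paste0("unknown sample/patient ID(s): ", paste(unknown, collapse = ", ")))
    }
    tumor <- tumor |> filter(.data$patient_id %in% patients)
    ids <- patients
  }
  n <- length(ids)
  if (n == 0) abort("no tumor patients in phenotypes")
  set.seed(seed + .seed_offsets[["clinical"]])
  cohort_of <- tumor$cohort[match(ids, tumor$patient_id)]
  mapped <- tumor$mapped_reads[match(ids, tumor$patient_id)]
  if (all(is.na(mapped))) mapped <- round(runif(n, 5e5, 2e6))

  splicing_genes <- unique(c(sqtl_genes, "SRSF1", "SRSF2", "HNRNPA1", "RBM10", "PRPF8"))
  background_genes <- sprintf("BG%03d", 1:50)
  mutated <- runif(n) < effect$frac_mutated
  mut_rows <- list()
  for (k in seq_len(n)) {
    genes <- sample(background_genes, 1 + rbinom(1, 3, 0.4))
    cls <- sample(c("Missense_Mutation", "Nonsense_Mutation", "Silent"),
                  length(genes), TRUE, prob = c(0.6, 0.1, 0.3))
    if (mutated[k]) {
      sg <- sample(splicing_genes, 1 + rbinom(1, 1, 0.3))
      genes <- c(genes, sg)
      cls <- c(cls, rep("Missense_Mutation", length(sg)))
    } else if (runif(1) < 0.15) {
      # silent splicing-gene calls that must never flip the stratum
      genes <- c(genes, sample(splicing_genes, 1))
      cls <- c(cls, "Silent")
    }
    mut_rows[[k]] <- tibble(patient_id = ids[k], gene = genes, variant_class = cls)
  }
  mutations <- bind_rows(mut_rows)

  n_stage2 <- pmax(0, round(rnorm(n, effect$burden_mean + effect$burden_shift * mutated,
                                  effect$burden_sd)))
  tmb_tab <- tibble(
    patient_id = ids, cohort = cohort_of,
    silent_per_mb = round(rexp(n, 1 / 0.8), 3),
    non_silent_per_mb = round(rexp(n, 1 / 2.5), 3),
    mapped_reads = mapped,
    n_stage2_junctions = as.integer(n_stage2),
    mutated = mutated
  ) |> mutate(tmb = .data$silent_per_mb + .data$non_silent_per_mb,
              .after = "non_silent_per_mb")

  jpos <- runif(n) < effect$frac_junction_positive
  haz <- effect$baseline_hazard * ifelse(jpos, effect$hazard_ratio, 1)
  tdeath <- rexp(n, haz)
  tcens <- runif(n, 30, effect$censor_time)
  dead <- tdeath <= tcens
  survival_tab <- tibble(
    patient_id = ids, junction_positive = jpos,
    days_to_death = ifelse(dead, round(tdeath) + 1, NA_real_),
    days_to_last_followup = ifelse(dead, NA_real_, round(tcens))
  )
  structure(list(mutations = mutations, tmb = tmb_tab, survival = survival_tab,
                 splicing_genes = splicing_genes, effect = effect),
            class = "clinical_sim")
}

#' @export
print.clinical_sim <- function(x, ...) {
  cat("<clinical_sim>", nrow(x$tmb), "patients,", nrow(x$mutations), "mutation calls\n")
  invisible(x)
}
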