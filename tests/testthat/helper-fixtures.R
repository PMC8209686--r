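# In-code fixtures: tiny hand-built stores and randomized small studies.

# a minimal deterministic store: 2 cancer cohorts, matched + other normals,
# SRA categories, with junctions covering each novelty stage
tiny_study <- function() {
  phen <- tibble::tibble(
    sample_id = c("T1a", "T1b", "T1c", "T2a", "T2b",
                  "N1a", "N1b", "G1a", "G2a",
                  "A1", "D1", "P1", "S1", "C1"),
    cohort = c("CAN1", "CAN1", "CAN1", "CAN2", "CAN2",
               "MATCH1", "MATCH1", "TIS1", "TIS2",
               "adult_ep", "fetus", "placenta", "esc", "sra_can1"),
    cohort_class = c(rep("tumor", 5),
                     rep("matched_normal", 2), rep("gtex_normal", 2),
                     "sra_adult", "sra_developmental", "sra_placenta",
                     "sra_stem", "sra_cancer"),
    patient_id = paste0("P_", c("T1a", "T1b", "T1c", "T2a", "T2b",
                                "N1a", "N1b", "G1a", "G2a",
                                "A1", "D1", "P1", "S1", "C1")),
    mapped_reads = 1e6
  )
  # junction j1: in tissue-matched normal (stage 0)
  # j2: in other core normal only (stage 1+ for CAN1)
  # j3: absent core normals, in SRA adult (stage 2+, adult set)
  # j4: tumor-only (stage 3+, unexplained)
  # j5: placenta-only SRA evidence (stage 2+, placenta set)
  # j6: single read total (removed by the global filter)
  ev <- tibble::tibble(
    chrom = "c1",
    start = c(10, 10, 20, 20, 30, 30, 40, 40, 50, 50, 60),
    end = c(15, 15, 25, 25, 35, 35, 45, 45, 55, 55, 65),
    strand = "+",
    sample_id = c("T1a", "N1a",
                  "T1a", "G2a",
                  "T1a", "A1",
                  "T1a", "T2a",
                  "T1b", "P1",
                  "T1c"),
    reads = c(3L, 1L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L)
  )
  match_map <- list(CAN1 = c("TIS1", "MATCH1"), CAN2 = character(0))
  list(evidence = ev, phenotypes = phen, match_map = match_map,
       sra_cancer_map = c(CAN1 = "sra_can1"))
}

tiny_store <- function(filtered = FALSE) {
  s <- tiny_study()
  store <- build_junction_store(s$evidence, s$phenotypes)
  if (filtered) store <- apply_read_filter(store)
  store
}

# randomized small study for oracle-equivalence sweeps (<= 50 x 50)
random_study <- function(seed) {
  set.seed(seed)
  n_can <- sample(1:3, 1)
  cohorts <- tibble::tibble(
    cohort = c(paste0("CAN", seq_len(n_can)), "MN1", "GN1", "GN2",
               "ADU1", "DEV1", "PLA1", "STE1", "SCA1"),
    cohort_class = c(rep("tumor", n_can), "matched_normal", "gtex_normal",
                     "gtex_normal", "sra_adult", "sra_developmental",
                     "sra_placenta", "sra_stem", "sra_cancer")
  )
  n_s <- sample(15:50, 1)
  # every declared cohort gets at least one sample
  assigned <- c(cohorts$cohort,
                sample(cohorts$cohort, n_s - nrow(cohorts), replace = TRUE,
                       prob = c(rep(3, n_can), rep(1, 8))))
  phen <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_s)),
    cohort = assigned
  ) |> dplyr::inner_join(cohorts, by = "cohort")
  phen$patient_id <- paste0("P", phen$sample_id)
  n_j <- sample(5:50, 1)
  ev <- purrr::map(seq_len(n_j), function(j) {
    pos <- sample(phen$sample_id, sample(1:min(8, n_s), 1))
    tibble::tibble(chrom = "c1", start = 10L * j, end = 10L * j + 5L,
                   strand = sample(c("+", "-", "*"), 1),
                   sample_id = pos, reads = sample(1:4, length(pos), replace = TRUE))
  }) |> dplyr::bind_rows()
  normals <- cohorts$cohort[cohorts$cohort_class %in% c("matched_normal", "gtex_normal")]
  match_map <- stats::setNames(lapply(seq_len(n_can), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) character(0) else sample(normals, k)
  }), paste0("CAN", seq_len(n_can)))
  list(evidence = ev, phenotypes = phen, match_map = match_map,
       sra_cancer_map = c(CAN1 = "SCA1"))
}

# a hand-built annotation index without going through GTF text
manual_index <- function(genes, junctions = NULL) {
  if (is.null(junctions)) {
    junctions <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), strand = character())
  }
  juncnov:::new_annotation_index(junctions = junctions, genes = genes)
}
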