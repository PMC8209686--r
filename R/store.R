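#' Build the three-table junction store
#'
#' Mirrors the indexing design of the analysis: three linked tables holding
#' (i) per-sample junction evidence, (ii) sample phenotypes and (iii) junction
#' information (canonical coordinates, annotation status, gene context). The
#' working container is an in-memory list of tibbles; [write_store()] persists
#' it as a single-file SQLite database with indexes on the junction-ID and
#' sample-ID columns.
#'
#' Evidence tables from different sources are merged on the canonical
#' coordinate key: identical (junction, sample, reads) rows collapse to one
#' (loading the same file twice is a no-op), and per-sample counts from
#' different tables union. Conflicting read counts for the same (junction,
#' sample) pair keep the maximum, with a warning.
#'
#' Samples flagged as bone-marrow normals derived from leukemia cell lines
#' (logical phenotype column `leukemia_cell_line`) are excluded at load, along
#' with their evidence.
#'
#' @param evidence A long evidence tibble (`chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `reads`) or a list of such tibbles.
#' @param phenotypes Sample phenotype tibble with at least `sample_id`,
#'   `cohort`, `cohort_class`; clinical columns are carried through.
#' @param annotation Optional [annotation_index][parse_annotation]; when given,
#'   junction annotation status is recorded.
#' @param dialect Coordinate dialect of the evidence table(s); a single value
#'   or one per table.
#' @return A `junction_store` object.
#' @export
build_junction_store <- function(evidence, phenotypes, annotation = NULL,
                                 dialect = "0-closed") {
  if (is.data.frame(evidence)) evidence <- list(evidence)
  dialect <- rep_len(dialect, length(evidence))
  ev <- bind_rows(map2(evidence, dialect, function(tab, dia) {
    tab <- as_tibble(tab)
    need <- c("chrom", "start", "end", "sample_id", "reads")
    if (!all(need %in% names(tab))) {
      abort(paste0("evidence table must have columns: ", paste(need, collapse = ", ")))
    }
    if (any(tab$reads < 1)) abort("read counts must be >= 1 (absence is encoded by omission)")
    coords <- convert_coordinates(tab[c("chrom", "start", "end", intersect("strand", names(tab)))],
                                  dialect = dia)
    tibble(chrom = coords$chrom, start = coords$start, end = coords$end,
           strand = coords$strand, sample_id = as.character(tab$sample_id),
           reads = as.integer(tab$reads))
  }))
  ev <- distinct(ev)
  dup <- ev |> count(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(paste0(nrow(dup), " (junction, sample) pair(s) had conflicting read counts; keeping the maximum"))
    ev <- ev |>
      group_by(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id) |>
      summarise(reads = max(.data$reads), .groups = "drop")
  }

  phen <- as_tibble(phenotypes)
  need <- c("sample_id", "cohort", "cohort_class")
  if (!all(need %in% names(phen))) {
    abort(paste0("phenotype table must have columns: ", paste(need, collapse = ", ")))
  }
  phen$sample_id <- as.character(phen$sample_id)
  if ("leukemia_cell_line" %in% names(phen)) {
    drop <- phen$sample_id[phen$leukemia_cell_line %in% TRUE]
    if (length(drop)) {
      inform(paste0("excluding ", length(drop),
                    " leukemia-cell-line-derived bone-marrow sample(s) at load"))
      phen <- phen |> filter(!.data$sample_id %in% drop)
      ev <- ev |> filter(!.data$sample_id %in% drop)
    }
  }
  known_class <- c("tumor", "matched_normal", "gtex_normal", "sra_adult",
                   "sra_developmental", "sra_stem", "sra_placenta", "sra_cancer")
  bad_class <- setdiff(unique(phen$cohort_class), known_class)
  if (length(bad_class)) {
    abort(paste0("unknown cohort_class value(s): ", paste(bad_class, collapse = ", ")))
  }
  missing <- setdiff(unique(ev$sample_id), phen$sample_id)
  if (length(missing)) {
    abort(paste0("evidence names sample(s) absent from phenotypes: ",
                 paste(sort(missing), collapse = ", ")))
  }

  junctions <- ev |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand) |>
    mutate(junction_id = row_number(), .before = 1)
  if (!is.null(annotation)) {
    junctions$annotation_status <- annotation_status(junctions, annotation)
  } else {
    junctions$annotation_status <- NA_character_
  }
  evidence_idx <- ev |>
    inner_join(junctions, by = c("chrom", "start", "end", "strand")) |>
    select("junction_id", "sample_id", "reads") |>
    arrange(.data$junction_id, .data$sample_id)

  new_junction_store(junctions, evidence_idx, phen)
}

new_junction_store <- function(junctions, evidence, samples) {
  structure(list(junctions = junctions, evidence = evidence, samples = samples),
            class = "junction_store")
}

#' @export
print.junction_store <- function(x, ...) {
  cat("<junction_store>\n")
  cat("  junctions:", nrow(x$junctions), "\n")
  cat("  evidence pairs:", nrow(x$evidence), "\n")
  cat("  samples:", nrow(x$samples), "across",
      length(unique(x$samples$cohort)), "cohorts\n")
  invisible(x)
}

#' Junctions of one sample / samples of one junction
#'
#' Transposed store queries: the set of junctions with evidence in a sample,
#' and the set of samples with evidence for a junction.
#'
#' @param store A `junction_store`.
#' @param sample_id,junction_id Identifier to query.
#' @return A tibble of evidence rows joined to junction or sample info.
#' @export
junctions_of_sample <- function(store, sample_id) {
  store$evidence |>
    filter(.data$sample_id == !!sample_id) |>
    inner_join(store$junctions, by = "junction_id")
}

#' @rdname junctions_of_sample
#' @export
samples_of_junction <- function(store, junction_id) {
  store$evidence |>
    filter(.data$junction_id == !!junction_id) |>
    inner_join(store$samples, by = "sample_id")
}

#' Persist / load a junction store as a single-file SQLite database
#'
#' Writes the three linked tables (`junctions`, `evidence`, `samples`) with
#' SQL indexes on junction-ID and sample-ID columns.
#'
#' @param store A `junction_store`.
#' @param path Database file path.
#' @return `write_store` returns `path` invisibly; `read_store` returns the
#'   `junction_store`.
#' @export
write_store <- function(store, path) {
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "junctions", as.data.frame(store$junctions))
  DBI::dbWriteTable(con, "evidence", as.data.frame(store$evidence))
  DBI::dbWriteTable(con, "samples", as.data.frame(store$samples))
  DBI::dbExecute(con, "CREATE INDEX idx_evidence_junction ON evidence (junction_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_evidence_sample ON evidence (sample_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_junctions_id ON junctions (junction_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_samples_id ON samples (sample_id)")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  new_junction_store(
    junctions = as_tibble(DBI::dbReadTable(con, "junctions")),
    evidence = as_tibble(DBI::dbReadTable(con, "evidence")),
    samples = as_tibble(DBI::dbReadTable(con, "samples"))
  )
}

#' Refine cancer cohorts into histological subtypes
#'
#' Re-labels samples of selected cancer cohorts by a clinical subtype field
#' (e.g. splitting sarcoma into leiomyosarcoma, myxofibrosarcoma, ...). Only
#' cohorts listed in the map are touched; a sample whose subtype value is
#' absent from the map keeps its parent cohort label with a warning. Sample
#' counts are conserved.
#'
#' @param phenotypes Phenotype tibble with `cohort` and a `subtype` column.
#' @param subtype_map Tibble with columns `cohort`, `subtype`,
#'   `refined_cohort`.
#' @return The phenotype tibble with refined `cohort` labels.
#' @export
refine_subtypes <- function(phenotypes, subtype_map) {
  phen <- as_tibble(phenotypes)
  smap <- as_tibble(subtype_map)
  stopifnot(all(c("cohort", "subtype", "refined_cohort") %in% names(smap)))
  if (!"subtype" %in% names(phen)) abort("phenotypes lack a 'subtype' column")
  out <- phen |>
    left_join(smap, by = c("cohort", "subtype")) |>
    mutate(refined = coalesce(.data$refined_cohort, .data$cohort)) |>
    select(-"refined_cohort")
  unmapped <- out |>
    filter(.data$cohort %in% unique(smap$cohort), .data$refined == .data$cohort)
  if (nrow(unmapped) > 0) {
    warn(paste0(nrow(unmapped), " sample(s) in mapped cohorts had subtype values ",
                "absent from the map; parent cohort label retained"))
  }
  out |> mutate(cohort = .data$refined) |> select(-"refined")
}

#' Read / write junction evidence in the Snaptron-like dialect
#'
#' Tab-separated columns `chrom`, `start`, `end`, `strand`, `samples`, where
#' `samples` holds comma-separated `sample_id:read_count` pairs and raw
#' coordinates are 1-based closed (converted on read to the canonical 0-based
#' closed system unless another dialect is declared).
#'
#' @param path File path.
#' @param dialect Coordinate dialect of the file (default `"1-closed"`, the
#'   raw dump convention).
#' @return `read_evidence` returns a long evidence tibble in canonical
#'   coordinates; `write_evidence` returns `path` invisibly.
#' @export
read_evidence <- function(path, dialect = "1-closed") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), strand = readr::col_character(),
    samples = readr::col_character()
  ))
  long <- raw |>
    mutate(pair = strsplit(.data$samples, ",", fixed = TRUE)) |>
    select(-"samples") |>
    unnest("pair") |>
    tidyr::separate_wider_delim("pair", ":", names = c("sample_id", "reads")) |>
    mutate(reads = as.integer(.data$reads))
  convert_coordinates(long, dialect = dialect)
}

#' @rdname read_evidence
#' @param evidence Long canonical evidence tibble (`chrom`, `start`, `end`,
#'   `strand`, `sample_id`, `reads`).
#' @export
write_evidence <- function(evidence, path) {
  out <- evidence |>
    mutate(start = .data$start + 1L, end = .data$end + 1L) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id) |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(samples = paste0(.data$sample_id, ":", .data$reads, collapse = ","),
              .groups = "drop")
  readr::write_tsv(out, path)
  invisible(path)
}
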