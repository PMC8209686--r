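#' Classify the gene context of junctions
#'
#' A junction is `protein_coding` when at least one of its splice sites lies
#' within a protein-coding gene's boundaries (gene-level start/end, introns
#' included) on the same strand; `antisense` when its only gene-boundary
#' overlaps are on the opposite strand; `neither` otherwise. Sense overlap
#' takes precedence over antisense when both exist. Unknown-strand junctions
#' overlapping any gene are labeled per `unknown_strand` (conservatively
#' `protein_coding` by default, so the antisense class is never inflated by
#' unstranded evidence).
#'
#' Stabbing queries run against interval trees ([IRanges::IRanges]) built per
#' chromosome from the annotation index.
#'
#' @param junctions A data frame of canonical junctions with `junction_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param index An [annotation_index][parse_annotation] whose `genes` table
#'   holds protein-coding gene boundaries.
#' @param unknown_strand Label for unknown-strand junctions that overlap a
#'   gene: `"protein_coding"` (default) or `"antisense"`.
#' @return A tibble (`junction_id`, `gene_context`, `genes`) where `genes` is
#'   a `";"`-joined list of attached gene names (all overlapping sense genes
#'   for `protein_coding`; opposite-strand genes for `antisense`).
#' @export
classify_gene_context <- function(junctions, index,
                                  unknown_strand = c("protein_coding", "antisense")) {
  unknown_strand <- match.arg(unknown_strand)
  stopifnot(inherits(index, "annotation_index"))
  x <- as_tibble(junctions)
  genes <- index$genes
  n <- nrow(x)
  res <- tibble(junction_id = x$junction_id, gene_context = rep("neither", n),
                genes = rep("", n))
  if (n == 0 || nrow(genes) == 0) {
    if (nrow(genes) == 0 && n > 0) warn("annotation has no protein-coding genes; all contexts 'neither'")
    return(res)
  }
  # site hits: for each junction, genes whose boundary interval contains the
  # left or right splice site on the same chromosome
  sites <- bind_rows(
    tibble(row = seq_len(n), chrom = x$chrom, pos = x$start),
    tibble(row = seq_len(n), chrom = x$chrom, pos = x$end)
  )
  hits <- map(split(seq_len(nrow(genes)), genes$chrom), function(gidx) {
    gsub <- genes[gidx, ]
    ssub <- sites |> filter(.data$chrom == gsub$chrom[1])
    if (nrow(ssub) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = ssub$pos, width = 1L),
      IRanges::IRanges(start = gsub$start, end = gsub$end)
    )
    tibble(row = ssub$row[S4Vectors::queryHits(ov)],
           gene = gidx[S4Vectors::subjectHits(ov)])
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) return(res)
  hits <- hits |>
    distinct(.data$row, .data$gene) |>
    mutate(gene_strand = genes$strand[.data$gene],
           gene_name = genes$gene_name[.data$gene],
           jx_strand = x$strand[.data$row],
           sense = .data$jx_strand == "*" | .data$gene_strand == .data$jx_strand)
  summ <- hits |>
    group_by(.data$row) |>
    summarise(
      any_sense = any(.data$sense),
      unknown = .data$jx_strand[1] == "*",
      sense_genes = paste(sort(unique(.data$gene_name[.data$sense])), collapse = ";"),
      anti_genes = paste(sort(unique(.data$gene_name[!.data$sense])), collapse = ";"),
      .groups = "drop"
    )
  lab <- ifelse(summ$any_sense,
                ifelse(summ$unknown & unknown_strand == "antisense", "antisense", "protein_coding"),
                "antisense")
  res$gene_context[summ$row] <- lab
  res$genes[summ$row] <- ifelse(lab == "protein_coding" | summ$unknown,
                                summ$sense_genes, summ$anti_genes)
  res
}

#' Flag junctions in cancer-associated loci
#'
#' A junction is associated with a cancer-relevant locus when any of its
#' attached sense protein-coding genes is on the cancer-associated gene list
#' (the union of curated cancer gene census lists).
#'
#' @param contexts Output of [classify_gene_context()].
#' @param cancer_genes Character vector of cancer-associated gene names (e.g.
#'   read with [read_gene_list()]).
#' @return `contexts` with a logical `cancer_gene` column.
#' @export
flag_cancer_genes <- function(contexts, cancer_genes) {
  if (length(cancer_genes) == 0) {
    warn("empty cancer gene list: all junctions flagged FALSE")
  }
  gene_sets <- strsplit(contexts$genes, ";", fixed = TRUE)
  contexts |>
    mutate(cancer_gene = .data$gene_context == "protein_coding" &
             map_lgl(gene_sets, ~ any(.x %in% cancer_genes)))
}

#' Read a one-gene-per-line gene list
#'
#' @param path Text file with one gene name per line (blank lines and `#`
#'   comments ignored).
#' @return Character vector of gene names.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Percent of antisense junctions per novelty/set category
#'
#' For each (cohort, category) cell of a junction categorisation (e.g. core
#' normal / SRA adult / developmental / stem / unexplained), the percent of
#' junctions classified antisense. Input order of junctions is irrelevant.
#'
#' @param data A tibble with columns `cohort`, `category`, `junction_id` (one
#'   row per junction and cohort).
#' @param contexts Output of [classify_gene_context()].
#' @return A tibble (`cohort`, `category`, `n`, `n_antisense`,
#'   `pct_antisense`); categories with no junctions are simply absent.
#' @export
antisense_fraction_by_category <- function(data, contexts) {
  data |>
    inner_join(contexts |> select("junction_id", "gene_context"), by = "junction_id") |>
    group_by(.data$cohort, .data$category) |>
    summarise(n = dplyr::n(),
              n_antisense = sum(.data$gene_context == "antisense"),
              .groups = "drop") |>
    mutate(pct_antisense = 100 * .data$n_antisense / .data$n)
}

#' Five-way junction categorisation across novelty and SRA sets
#'
#' Assigns each (cohort, junction) of a novelty table to one of
#' `core_normal` (stage below 2+), `adult`, `developmental` (placenta
#' included at this resolution), `stem` or `unexplained`, with the
#' adult-before-developmental-before-stem precedence used when a junction
#' carries evidence in several groups.
#'
#' @param novelty Output of [assign_novelty()].
#' @param assignments Output of [assign_sets()].
#' @return A tibble (`cohort`, `junction_id`, `category`).
#' @export
novelty_set_category <- function(novelty, assignments) {
  core <- novelty |>
    filter(.data$stage < "2+") |>
    transmute(.data$cohort, .data$junction_id, category = "core_normal")
  sets <- assignments |>
    transmute(.data$cohort, .data$junction_id,
              category = case_when(
                in_sra_adult ~ "adult",
                in_sra_developmental | in_sra_placenta ~ "developmental",
                in_sra_stem ~ "stem",
                TRUE ~ "unexplained"
              ))
  bind_rows(core, sets)
}
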