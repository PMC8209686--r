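#' Parse a GENCODE-style GTF into an annotation index
#'
#' Collects (i) the set of annotated junctions, derived from consecutive exons
#' of each transcript, (ii) the annotated left and right splice-site sets keyed
#' by chromosome and strand, and (iii) protein-coding gene boundary intervals
#' (gene-level lines with `gene_type "protein_coding"`), organized for interval
#' stabbing queries. All coordinates are converted from the GTF's 1-based
#' closed convention to the canonical 0-based closed system.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines.
#' @return An object of class `annotation_index`: a list with tibbles
#'   `junctions` (chrom, start, end, strand), `genes` (gene_id, gene_name,
#'   chrom, strand, start, end) and character-set fields `left_sites`,
#'   `right_sites`.
#' @export
parse_annotation <- function(gtf) {
  if (length(gtf) == 1 && !grepl("\n", gtf) && file.exists(gtf)) {
    lines <- readLines(gtf)
    path <- gtf
  } else {
    lines <- unlist(strsplit(gtf, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".gtf")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
  }
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    bad <- which(body)[which(nfield != 9)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated fields"))
  }
  if (!any(body)) {
    return(new_annotation_index(
      junctions = tibble(chrom = character(), start = integer(), end = integer(), strand = character()),
      genes = tibble(gene_id = character(), gene_name = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer())
    ))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id %||% NA_character_,
    gene_name = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
    gene_type = gr$gene_type %||% NA_character_,
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id else NA_character_
  )
  if (any(df$end < df$start)) {
    abort("GTF data error: feature with end < start")
  }
  exons <- df |> filter(.data$type == "exon")
  if (nrow(exons) > 0 && anyNA(exons$transcript_id)) {
    abort("GTF data error: exon line without transcript_id")
  }
  juncs <- exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    reframe(
      jstart = .data$end[-dplyr::n()],          # 1-based intron start - 1 = exon end (0-based closed)
      jend = .data$start[-1] - 2L               # 1-based intron end - 1
    ) |>
    distinct(.data$chrom, .data$strand, .data$jstart, .data$jend) |>
    transmute(
      chrom = .data$chrom, start = as.integer(.data$jstart),
      end = as.integer(.data$jend), strand = .data$strand
    ) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  genes <- df |>
    filter(.data$type == "gene", .data$gene_type == "protein_coding") |>
    transmute(
      gene_id = .data$gene_id, gene_name = .data$gene_name,
      chrom = .data$chrom, strand = .data$strand,
      start = as.integer(.data$start - 1L), end = as.integer(.data$end - 1L)
    )
  new_annotation_index(junctions = juncs, genes = genes)
}

new_annotation_index <- function(junctions, genes) {
  structure(
    list(
      junctions = junctions,
      genes = genes,
      junction_keys = junction_key(junctions$chrom, junctions$start, junctions$end, junctions$strand),
      left_sites = unique(paste(junctions$chrom, junctions$strand, junctions$start)),
      right_sites = unique(paste(junctions$chrom, junctions$strand, junctions$end))
    ),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("<annotation_index>\n")
  cat("  annotated junctions:", nrow(x$junctions), "\n")
  cat("  protein-coding genes:", nrow(x$genes), "\n")
  invisible(x)
}

#' Annotation status of junctions
#'
#' A junction is `"both"` when its two splice sites belong to the same
#' annotated junction (i.e. the junction itself is annotated), `"one"` when
#' exactly one of its sites coincides with an annotated splice site of the
#' same chromosome and strand, and `"neither"` otherwise. Unknown-strand
#' junctions never match stranded annotation and are `"neither"`.
#'
#' @param x A data frame of canonical junctions (`chrom`, `start`, `end`,
#'   `strand`).
#' @param index An [annotation_index][parse_annotation].
#' @return Character vector, one of `"both"`, `"one"`, `"neither"` per row.
#' @export
annotation_status <- function(x, index) {
  stopifnot(inherits(index, "annotation_index"))
  key <- junction_key(x$chrom, x$start, x$end, x$strand)
  both <- key %in% index$junction_keys
  left <- paste(x$chrom, x$strand, x$start) %in% index$left_sites
  right <- paste(x$chrom, x$strand, x$end) %in% index$right_sites
  ifelse(both, "both", ifelse(left | right, "one", "neither"))
}
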