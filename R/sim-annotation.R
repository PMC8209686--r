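#' Generate a synthetic GENCODE-style annotation
#'
#' Lays out `n_genes` protein-coding genes on a single synthetic chromosome
#' (`chrS` by default), all on the `+` strand and non-overlapping, each with
#' `transcripts_per_gene` transcripts of up to `exons_per_transcript` exons
#' (the second and later transcripts skip an internal exon, creating
#' exon-skipping junctions). Returns both the 1-based closed GTF text and the
#' ground truth: every annotated junction in canonical 0-based closed
#' coordinates and every gene boundary interval.
#'
#' A deterministic share of genes (every seventh) is designated
#' cancer-associated, providing the curated cancer gene list fixture.
#'
#' @param n_genes Number of genes (>= 0).
#' @param transcripts_per_gene Transcripts per gene (>= 1).
#' @param exons_per_transcript Exons per transcript (>= 1); a single exon
#'   yields no junctions.
#' @param seed Seed for the (small) random jitter in exon geometry.
#' @param chrom Chromosome name.
#' @param antisense_pairs Number of extra minus-strand genes overlapping the
#'   first genes, for antisense-overlap fixtures.
#' @return A list of class `sim_annotation`: `gtf` (character lines),
#'   `junctions` (canonical truth tibble), `genes` (0-based closed boundary
#'   tibble with `cancer_gene` flags), `cancer_genes` (character vector).
#' @export
simulate_annotation <- function(n_genes, transcripts_per_gene = 2,
                                exons_per_transcript = 5, seed = 1,
                                chrom = "chrS", antisense_pairs = 0) {
  if (n_genes < 0 || antisense_pairs < 0) abort("gene counts must be non-negative")
  if (n_genes > 0 && (transcripts_per_gene < 1 || exons_per_transcript < 1)) {
    abort("transcripts_per_gene and exons_per_transcript must be >= 1")
  }
  header <- c("##description: synthetic annotation", "##provider: juncnov simulate_annotation")
  if (n_genes == 0) {
    return(structure(list(
      gtf = header,
      junctions = tibble(chrom = character(), start = integer(), end = integer(), strand = character()),
      genes = tibble(gene_id = character(), gene_name = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer(),
                     cancer_gene = logical()),
      cancer_genes = character()
    ), class = "sim_annotation"))
  }
  set.seed(seed + .seed_offsets[["annotation"]])
  n_genes <- as.integer(n_genes)
  transcripts_per_gene <- as.integer(transcripts_per_gene)
  exons_per_transcript <- as.integer(exons_per_transcript)
  exon_len <- 200L
  exon_pitch <- 1000L
  gene_span <- exons_per_transcript * exon_pitch + 4000L
  lines <- character(0)
  jx <- list()
  genes <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("G%04d", i)
    gname <- sprintf("GENE%04d", i)
    gstart <- 1000L + (i - 1L) * gene_span                     # 1-based
    exon_starts <- gstart + (seq_len(exons_per_transcript) - 1L) * exon_pitch
    exon_ends <- exon_starts + exon_len - 1L
    gend <- exon_ends[exons_per_transcript]
    attr_gene <- sprintf('gene_id "%s"; gene_type "protein_coding"; gene_name "%s";', gid, gname)
    lines <- c(lines, paste(chrom, "SYNTH", "gene", gstart, gend, ".", "+", ".", attr_gene, sep = "\t"))
    for (t in seq_len(transcripts_per_gene)) {
      tid <- sprintf("%s.T%d", gid, t)
      use <- seq_len(exons_per_transcript)
      if (t > 1 && exons_per_transcript >= 3) {
        skip <- 2L + (t - 2L) %% (exons_per_transcript - 2L)  # an internal exon
        use <- setdiff(use, skip)
      }
      attr_tx <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "protein_coding"; gene_name "%s";',
                         gid, tid, gname)
      lines <- c(lines, paste(chrom, "SYNTH", "transcript", exon_starts[use[1]],
                              exon_ends[use[length(use)]], ".", "+", ".", attr_tx, sep = "\t"))
      for (e in use) {
        lines <- c(lines, paste(chrom, "SYNTH", "exon", exon_starts[e], exon_ends[e],
                                ".", "+", ".", attr_tx, sep = "\t"))
      }
      if (length(use) > 1) {
        jx[[length(jx) + 1]] <- tibble(
          chrom = chrom,
          start = exon_ends[use[-length(use)]],            # 0-based closed intron start
          end = exon_starts[use[-1]] - 2L,                 # 0-based closed intron end
          strand = "+"
        )
      }
    }
    genes[[length(genes) + 1]] <- tibble(
      gene_id = gid, gene_name = gname, chrom = chrom, strand = "+",
      start = gstart - 1L, end = gend - 1L, cancer_gene = (i %% 7L) == 0L
    )
  }
  if (antisense_pairs > 0) {
    for (i in seq_len(min(antisense_pairs, n_genes))) {
      gid <- sprintf("AS%04d", i)
      gname <- sprintf("ASGENE%04d", i)
      g <- genes[[i]]
      s1 <- g$start + 200L + 1L  # back to 1-based
      e1 <- g$end - 200L + 1L
      attr_gene <- sprintf('gene_id "%s"; gene_type "protein_coding"; gene_name "%s";', gid, gname)
      lines <- c(lines, paste(g$chrom, "SYNTH", "gene", s1, e1, ".", "-", ".", attr_gene, sep = "\t"))
      genes[[length(genes) + 1]] <- tibble(
        gene_id = gid, gene_name = gname, chrom = g$chrom, strand = "-",
        start = s1 - 1L, end = e1 - 1L, cancer_gene = FALSE
      )
    }
  }
  junctions <- if (length(jx) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(), strand = character())
  } else {
    bind_rows(jx) |>
      distinct() |>
      arrange(.data$chrom, .data$start, .data$end)
  }
  genes <- bind_rows(genes)
  structure(list(
    gtf = c(header, lines),
    junctions = junctions,
    genes = genes,
    cancer_genes = genes$gene_name[genes$cancer_gene]
  ), class = "sim_annotation")
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat("<sim_annotation>", nrow(x$genes), "genes,", nrow(x$junctions), "annotated junctions\n")
  invisible(x)
}

#' View a simulated annotation as an annotation index
#'
#' Builds the searchable [annotation_index][parse_annotation] directly from a
#' [simulate_annotation()] truth, bypassing GTF round-tripping (the GTF text
#' parses to the identical index; tests assert this).
#'
#' @param x A `sim_annotation`.
#' @return An `annotation_index`.
#' @export
as_annotation_index <- function(x) {
  stopifnot(inherits(x, "sim_annotation"))
  new_annotation_index(
    junctions = x$junctions,
    genes = x$genes |> select("gene_id", "gene_name", "chrom", "strand", "start", "end")
  )
}
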