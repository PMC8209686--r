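gtf_lines <- function(exons, strand = "+", gene_type = "protein_coding",
                      gene = "G1", tx = "T1", chrom = "chr1") {
  g <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";', gene, gene_type, gene)
  t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s"; gene_name "%s";',
               gene, tx, gene_type, gene)
  c(paste(chrom, "X", "gene", min(exons[, 1]), max(exons[, 2]), ".", strand, ".", g, sep = "\t"),
    paste(chrom, "X", "transcript", min(exons[, 1]), max(exons[, 2]), ".", strand, ".", t, sep = "\t"),
    apply(exons, 1, function(e)
      paste(chrom, "X", "exon", e[1], e[2], ".", strand, ".", t, sep = "\t")))
}

test_that("annotated junctions derive from consecutive exons with coordinate shift", {
  idx <- parse_annotation(paste(gtf_lines(rbind(c(100, 200), c(301, 400))), collapse = "\n"))
  expect_equal(nrow(idx$junctions), 1)
  expect_equal(idx$junctions$start, 200L)
  expect_equal(idx$junctions$end, 299L)
  expect_equal(nrow(idx$genes), 1)
  expect_equal(idx$genes$start, 99L)
})

test_that("single-exon transcripts contribute no junctions and shared introns collapse", {
  idx1 <- parse_annotation(paste(gtf_lines(rbind(c(100, 400))), collapse = "\n"))
  expect_equal(nrow(idx1$junctions), 0)
  two <- c(gtf_lines(rbind(c(100, 200), c(301, 400)), tx = "T1"),
           gtf_lines(rbind(c(100, 200), c(301, 400)), tx = "T2")[-(1:2)])
  idx2 <- parse_annotation(paste(two, collapse = "\n"))
  expect_equal(nrow(idx2$junctions), 1)
})

test_that("non-protein-coding genes are excluded from boundary intervals", {
  idx <- parse_annotation(paste(gtf_lines(rbind(c(100, 200), c(301, 400)),
                                          gene_type = "lincRNA"), collapse = "\n"))
  expect_equal(nrow(idx$genes), 0)
  expect_equal(nrow(idx$junctions), 1)  # junctions come from any transcript
})

test_that("malformed GTF lines are reported with their line number", {
  bad <- c("# header", "chr1\tX\texon\t1\t10", "chr1\tX\tgene\t1\t10\t.\t+\t.\tg")
  expect_error(parse_annotation(paste(bad, collapse = "\n")), "line 2")
})

test_that("parsed GTF equals the simulated annotation truth", {
  ann <- simulate_annotation(8, 2, 5, seed = 3)
  idx <- parse_annotation(paste(ann$gtf, collapse = "\n"))
  direct <- as_annotation_index(ann)
  expect_equal(idx$junctions, direct$junctions)
  expect_equal(idx$genes |> dplyr::arrange(gene_id),
               direct$genes |> dplyr::arrange(gene_id))
})

test_that("annotation status distinguishes both, one and neither sites", {
  ann <- simulate_annotation(4, 2, 5, seed = 2)
  idx <- as_annotation_index(ann)
  j_both <- ann$junctions[1, ]
  j_one <- dplyr::mutate(j_both, end = end + 137L)
  j_neither <- tibble::tibble(chrom = "chrS", start = 1L, end = 7L, strand = "+")
  j_unknown <- dplyr::mutate(j_both, strand = "*")
  x <- dplyr::bind_rows(j_both, j_one, j_neither, j_unknown)
  expect_equal(annotation_status(x, idx), c("both", "one", "neither", "neither"))
})

test_that("store build merges duplicate tables idempotently", {
  s <- tiny_study()
  once <- build_junction_store(s$evidence, s$phenotypes)
  twice <- build_junction_store(list(s$evidence, s$evidence), s$phenotypes)
  expect_identical(once$junctions, twice$junctions)
  expect_identical(once$evidence, twice$evidence)
})

test_that("evidence for the same junction in different samples merges to one record", {
  phen <- tibble::tibble(sample_id = c("a", "b"), cohort = "CAN1", cohort_class = "tumor")
  t1 <- tibble::tibble(chrom = "c1", start = 10L, end = 20L, strand = "+",
                       sample_id = "a", reads = 1L)
  t2 <- dplyr::mutate(t1, sample_id = "b")
  store <- build_junction_store(list(t1, t2), phen)
  expect_equal(nrow(store$junctions), 1)
  expect_equal(sum(store$evidence$reads), 2)
})

test_that("conflicting read counts for one pair keep the maximum with a warning", {
  phen <- tibble::tibble(sample_id = "a", cohort = "CAN1", cohort_class = "tumor")
  t1 <- tibble::tibble(chrom = "c1", start = 10L, end = 20L, strand = "+",
                       sample_id = "a", reads = 1L)
  t2 <- dplyr::mutate(t1, reads = 3L)
  expect_warning(store <- build_junction_store(list(t1, t2), phen), "maximum")
  expect_equal(store$evidence$reads, 3L)
})

test_that("evidence samples missing from phenotypes abort with offenders listed", {
  s <- tiny_study()
  expect_error(build_junction_store(s$evidence, s$phenotypes[-1, ]), "T1a")
})

test_that("flagged leukemia-cell-line bone-marrow samples are dropped at load", {
  s <- tiny_study()
  s$phenotypes <- dplyr::bind_rows(
    s$phenotypes,
    tibble::tibble(sample_id = "BM1", cohort = "bone_marrow", cohort_class = "gtex_normal",
                   patient_id = "P_BM1", mapped_reads = 1e6, leukemia_cell_line = TRUE))
  s$evidence <- dplyr::bind_rows(
    s$evidence,
    tibble::tibble(chrom = "c1", start = 10, end = 15, strand = "+",
                   sample_id = "BM1", reads = 2L))
  expect_message(store <- build_junction_store(s$evidence, s$phenotypes), "leukemia")
  expect_false("BM1" %in% store$samples$sample_id)
  expect_false("BM1" %in% store$evidence$sample_id)
})

test_that("store round-trips through the single-file SQLite database", {
  store <- tiny_store()
  path <- withr::local_tempfile(fileext = ".sqlite")
  write_store(store, path)
  back <- read_store(path)
  expect_equal(as.data.frame(back$junctions), as.data.frame(store$junctions))
  expect_equal(as.data.frame(back$evidence), as.data.frame(store$evidence))
  expect_equal(as.data.frame(back$samples)[, c("sample_id", "cohort", "cohort_class")],
               as.data.frame(store$samples)[, c("sample_id", "cohort", "cohort_class")])
})

test_that("store queries round-trip against the raw input and transpose", {
  s <- random_study(42)
  store <- build_junction_store(s$evidence, s$phenotypes)
  for (sid in sample(unique(s$evidence$sample_id), 3)) {
    got <- junctions_of_sample(store, sid)
    want <- s$evidence[s$evidence$sample_id == sid, ]
    expect_setequal(junction_key(got$chrom, got$start, got$end, got$strand),
                    junction_key(want$chrom, want$start, want$end, want$strand))
  }
  # transpose: (junction, sample) pairs agree in both directions
  jid <- sample(store$junctions$junction_id, 1)
  via_j <- samples_of_junction(store, jid)$sample_id
  via_s <- purrr::map_lgl(via_j, function(sid) jid %in% junctions_of_sample(store, sid)$junction_id)
  expect_true(all(via_s))
})

test_that("evidence pair count is conserved through the store", {
  s <- random_study(7)
  store <- build_junction_store(s$evidence, s$phenotypes)
  expect_equal(nrow(store$evidence), nrow(dplyr::distinct(
    s$evidence, chrom, start, end, strand, sample_id)))
})

test_that("snaptron-dialect evidence files round-trip", {
  s <- tiny_study()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(s$evidence, path)
  back <- read_evidence(path, dialect = "1-closed")
  expect_equal(
    dplyr::arrange(back, chrom, start, end, strand, sample_id),
    dplyr::arrange(dplyr::mutate(s$evidence, start = as.integer(start), end = as.integer(end),
                                 reads = as.integer(reads)),
                   chrom, start, end, strand, sample_id) |>
      dplyr::select(chrom, start, end, strand, sample_id, reads)
  )
})

test_that("subtype refinement relabels only mapped cohorts and conserves samples", {
  phen <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    cohort = c("sarcoma", "sarcoma", "sarcoma", "ovarian"),
    cohort_class = "tumor",
    subtype = c("leiomyosarcoma", "myxofibrosarcoma", "odd_one", NA))
  smap <- tibble::tibble(cohort = "sarcoma",
                         subtype = c("leiomyosarcoma", "myxofibrosarcoma"),
                         refined_cohort = c("leiomyosarcoma", "myxofibrosarcoma"))
  expect_warning(out <- refine_subtypes(phen, smap), "parent cohort")
  expect_equal(out$cohort, c("leiomyosarcoma", "myxofibrosarcoma", "sarcoma", "ovarian"))
  expect_equal(nrow(out), nrow(phen))
})
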