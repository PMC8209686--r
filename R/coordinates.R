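#' Convert junction coordinates to the canonical 0-based closed system
#'
#' Junctions are represented by their intron: `start` is the first base of the
#' intron and `end` its last base, both 0-based and inclusive. Upstream sources
#' disagree on conventions, so every table entering the index declares its
#' dialect and is converted here.
#'
#' Dialects:
#' * `"1-closed"`: 1-based, both ends inclusive (GTF-style); subtract 1 from
#'   both ends.
#' * `"0-half-open"`: 0-based start, exclusive end (BED-style); subtract 1 from
#'   the end only.
#' * `"0-closed"`: already canonical; identity.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (one of `"+"`, `"-"`, `"*"` for unknown; missing strand is
#'   treated as unknown).
#' @param dialect Coordinate dialect of the input (see above).
#' @return A tibble with the same rows, `start`/`end` in 0-based closed
#'   coordinates, and a `strand` column (defaulted to `"*"` when absent).
#' @examples
#' convert_coordinates(
#'   data.frame(chrom = "chrS", start = 201, end = 300, strand = "+"),
#'   dialect = "1-closed"
#' )
#' @export
convert_coordinates <- function(x, dialect = c("0-closed", "1-closed", "0-half-open")) {
  dialect <- match.arg(dialect)
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    abort(paste0("coordinate table must have columns: ", paste(req, collapse = ", ")))
  }
  if (!"strand" %in% names(x)) x$strand <- "*"
  x$strand <- ifelse(is.na(x$strand) | x$strand %in% c("?", "."), "*", x$strand)
  bad_strand <- setdiff(unique(x$strand), c("+", "-", "*"))
  if (length(bad_strand)) {
    abort(paste0("unknown strand value(s): ", paste(bad_strand, collapse = ", ")))
  }
  if (dialect == "0-half-open") {
    if (any(x$start >= x$end)) abort("half-open intervals require start < end")
    x$end <- x$end - 1L
  } else if (dialect == "1-closed") {
    if (any(x$start > x$end)) abort("closed intervals require start <= end")
    x$start <- x$start - 1L
    x$end <- x$end - 1L
  } else {
    if (any(x$start > x$end)) abort("closed intervals require start <= end")
  }
  if (any(x$start < 0)) abort("canonical start coordinates must be >= 0")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Canonical textual key of a junction
#'
#' The key `"chrom:start-end(strand)"` (0-based closed coordinates) is unique
#' per junction; strand `"*"` denotes unknown strand and is kept distinct from
#' `"+"`/`"-"` so that unstranded evidence is never silently merged onto a
#' strand.
#'
#' @param chrom,start,end,strand Vectors of canonical junction fields.
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, start, end, strand = "*") {
  paste0(chrom, ":", start, "-", end, "(", strand, ")")
}

#' Export canonical junctions as BED intervals
#'
#' Converts 0-based closed intron coordinates to BED's 0-based half-open
#' convention (end + 1) for genome-browser use.
#'
#' @param x A data frame with canonical `chrom`, `start`, `end`, `strand`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` in BED conventions.
#' @export
to_bed <- function(x) {
  x <- as_tibble(x)
  tibble(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end) + 1L,
    name = junction_key(x$chrom, x$start, x$end, x$strand %||% "*"),
    score = 0L,
    strand = if ("strand" %in% names(x)) ifelse(x$strand == "*", ".", x$strand) else "."
  )
}
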