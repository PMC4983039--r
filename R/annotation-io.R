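# Gene annotation input and promoter-window derivation.
#
# All coordinates are 0-based half-open internally (UCSC table convention);
# the Wiggle parser converts its 1-based starts at the edge. The TSS of a
# transcript is its strand-oriented first transcribed base: tx_start on "+",
# tx_end - 1 on "-".

#' Read a UCSC refGene-style gene annotation table
#'
#' Parses a tab-delimited refGene-like file into a gene table, one row per
#' transcript, deriving the strand-oriented transcription start site (TSS).
#' The standard UCSC refGene layout (with a leading `bin` column) is assumed
#' by default; a layout without the `bin` column is autodetected from the
#' first data line (a refGene `name` such as `NM_000014` in column 1 instead
#' of an integer bin).
#'
#' @param path Path to a tab-delimited annotation file. Plain text or gzip.
#' @param cols Optional named integer vector overriding the 1-based column
#'   positions of `name`, `chrom`, `strand`, `txStart`, `txEnd` and `name2`.
#' @return A tibble with columns `transcript_id`, `gene_symbol`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tx_start`, `tx_end` (0-based half-open) and
#'   `tss` (0-based position of the first transcribed base).
#'   Duplicate transcript ids are dropped keeping the first occurrence, with
#'   a warning.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c(
#'   "0\tNM_1\tchr1\t+\t1000\t2000\t1000\t2000\t1\t1000,\t2000,\t0\tGENEA\tcmpl\tcmpl\t0,",
#'   "0\tNM_2\tchr1\t-\t1000\t2000\t1000\t2000\t1\t1000,\t2000,\t0\tGENEB\tcmpl\tcmpl\t0,"
#' ), f)
#' read_refgene(f)
#' @seealso [read_bed_genes()] for BED6 annotation, [promoter_windows()]
#' @export
read_refgene <- function(path, cols = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (is.null(cols)) {
    # UCSC refGene carries a leading integer `bin`; genePred dumps omit it.
    has_bin <- grepl("^[0-9]+$", fields[[1]][1])
    base <- c(name = 1L, chrom = 2L, strand = 3L, txStart = 4L, txEnd = 5L, name2 = 12L)
    cols <- if (has_bin) base + 1L else base
  }
  need <- c("name", "chrom", "strand", "txStart", "txEnd", "name2")
  if (!all(need %in% names(cols))) {
    abort(paste("`cols` must name positions for:", paste(need, collapse = ", ")))
  }

  n_fields <- lengths(fields)
  min_needed <- max(cols[c("name", "chrom", "strand", "txStart", "txEnd")])
  bad <- which(n_fields < min_needed)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: expected at least %d tab-separated columns, found %d",
                  bad[1], min_needed, n_fields[bad[1]]))
  }
  grab <- function(key) vapply(fields, `[[`, character(1), cols[[key]])
  name <- grab("name")
  chrom <- grab("chrom")
  strand <- grab("strand")
  tx_start <- suppressWarnings(as.integer(grab("txStart")))
  tx_end <- suppressWarnings(as.integer(grab("txEnd")))
  # name2 is absent in minimal layouts; fall back to the transcript id
  name2 <- vapply(fields, function(f) {
    if (length(f) >= cols[["name2"]]) f[[cols[["name2"]]]] else NA_character_
  }, character(1))
  name2 <- ifelse(is.na(name2) | name2 == "", name, name2)

  validate_gene_rows(chrom, strand, tx_start, tx_end)
  build_gene_table(name, name2, chrom, strand, tx_start, tx_end)
}

#' Read gene annotation from a BED6 file
#'
#' Alternate annotation source: a BED6 file (chrom, start, end, name, score,
#' strand) where each record is one transcript. The score column is ignored;
#' the name doubles as both transcript id and gene symbol.
#'
#' @param path Path to a BED6 file (plain or gzipped).
#' @return A gene table in the same shape as [read_refgene()].
#' @export
read_bed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$|track\\s|browser\\s)", lines)]
  if (length(lines) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 6L)
  if (length(short) > 0L) {
    abort(sprintf("line %d: BED6 annotation needs 6 columns, found %d",
                  short[1], lengths(fields)[short[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  name <- vapply(fields, `[[`, character(1), 4L)
  strand <- vapply(fields, `[[`, character(1), 6L)
  validate_gene_rows(chrom, strand, start, end)
  build_gene_table(name, name, chrom, strand, start, end)
}

validate_gene_rows <- function(chrom, strand, tx_start, tx_end) {
  bad <- which(is.na(tx_start) | is.na(tx_end))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: non-integer transcript coordinate", bad[1]))
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: strand must be '+' or '-', found '%s'", bad[1], strand[bad[1]]))
  }
  bad <- which(tx_start >= tx_end)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: txStart (%d) must be < txEnd (%d)",
                  bad[1], tx_start[bad[1]], tx_end[bad[1]]))
  }
  bad <- which(is.na(chrom) | chrom == "")
  if (length(bad) > 0L) {
    abort(sprintf("line %d: empty chromosome name", bad[1]))
  }
  invisible(NULL)
}

build_gene_table <- function(transcript_id, gene_symbol, chrom, strand, tx_start, tx_end) {
  genes <- tibble(
    transcript_id = transcript_id,
    gene_symbol = gene_symbol,
    chrom = chrom,
    strand = strand,
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end)
  )
  dup <- duplicated(genes$transcript_id)
  if (any(dup)) {
    warn(sprintf("%d duplicate transcript id(s) dropped, keeping first occurrence (e.g. %s)",
                 sum(dup), genes$transcript_id[which(dup)[1]]))
    genes <- genes[!dup, ]
  }
  genes %>%
    mutate(tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end - 1L)) %>%
    mutate(tss = as.integer(.data$tss))
}

empty_gene_table <- function() {
  tibble(
    transcript_id = character(), gene_symbol = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(), tss = integer()
  )
}

#' Derive promoter windows around each TSS
#'
#' For each transcript the promoter window is the `2L + 1` bp interval
#' `[TSS - L, TSS + L + 1)` on the transcript's strand, where `L` is
#' `half_width`. Windows may extend below position 0 or past a chromosome
#' end; they are not clipped here — out-of-range bases contribute signal 0
#' at extraction, so the gene universe does not depend on chromosome sizes.
#'
#' @param genes A gene table from [read_refgene()], [read_bed_genes()] or
#'   [simulate_genome()].
#' @param half_width Half window length `L` in bp (> 0). Default 10000,
#'   i.e. a 20 kb region centered on the TSS.
#' @return The gene table with added integer columns `window_start` and
#'   `window_end` (0-based half-open).
#' @export
promoter_windows <- function(genes, half_width = 10000) {
  assert_genes(genes)
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width <= 0) {
    abort("`half_width` must be a single positive number of base pairs")
  }
  L <- as.integer(half_width)
  genes %>%
    mutate(
      window_start = .data$tss - L,
      window_end = .data$tss + L + 1L
    )
}
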