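# Optional peak annotation: locate binding-peak summits inside the promoter
# windows of called target genes and report their strength.

#' Read a BED / narrowPeak peak file
#'
#' Accepts any BED3+ file. When a 10th column is present (narrowPeak), a
#' nonnegative value is taken as the summit offset within the peak; `-1`
#' means no summit was called.
#'
#' @param path Path to a BED3+/narrowPeak file (plain or gzipped).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `bed_score` and `summit_offset` (NA when absent).
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\t", fixed = TRUE)
  if (length(fields) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), bed_score = numeric(), summit_offset = integer()))
  }
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("line %d: BED needs at least 3 columns", lineno[short[1]]))
  }
  col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  }
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: non-integer peak coordinate", lineno[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: peak end must exceed start", lineno[bad[1]]))
  }
  summit <- suppressWarnings(as.integer(col(10L)))
  summit[!is.na(summit) & summit < 0L] <- NA_integer_
  tibble(
    chrom = col(1L),
    start = start,
    end = end,
    name = col(4L),
    bed_score = suppressWarnings(as.numeric(col(5L))),
    summit_offset = summit
  )
}

#' Annotate target promoters with binding-peak summits
#'
#' For every called target, every peak overlapping its promoter window (any
#' base of overlap) yields one hit. The summit is the one given in the peak
#' file when available and inside the window; otherwise it is the position
#' of maximum track signal within the peak-window intersection (ties go to
#' the smallest coordinate). The summit location is reported relative to
#' the TSS in gene orientation (negative = upstream), and the peak height
#' is the track value at the summit. Targets with no overlapping peak
#' simply yield no rows — a target without a called peak is an expected,
#' informative outcome, not an error.
#'
#' @param peaks Peak tibble from [read_narrowpeak()].
#' @param targets Target rows from [call_targets()] (any gene table subset
#'   works).
#' @param genes Full gene table (used for windows; `targets` rows must
#'   appear here).
#' @param half_width Half window length `L` in bp used for scoring.
#' @param track Signal-track tibble, used to infer summits and heights.
#' @return A tibble with one row per (target, overlapping peak):
#'   `transcript_id`, `gene_symbol`, `peak_chrom`, `peak_start`,
#'   `peak_end`, `summit_pos` (absolute, 0-based), `summit_from_tss`
#'   (signed bp in gene orientation), `peak_height`, `bed_score`, and
#'   `is_primary` flagging the highest peak per target.
#' @export
annotate_peaks <- function(peaks, targets, genes, half_width = 10000, track = NULL) {
  assert_genes(genes)
  win <- promoter_windows(genes, half_width)
  win <- win[win$transcript_id %in% targets$transcript_id, ]
  hits <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    w <- win[i, ]
    ov <- peaks[peaks$chrom == w$chrom & peaks$start < w$window_end & peaks$end > w$window_start, ]
    if (nrow(ov) == 0L) next
    summit_pos <- integer(nrow(ov))
    height <- numeric(nrow(ov))
    for (j in seq_len(nrow(ov))) {
      lo <- max(ov$start[j], w$window_start)
      hi <- min(ov$end[j], w$window_end) # half-open
      given <- if (!is.na(ov$summit_offset[j])) ov$start[j] + ov$summit_offset[j] else NA_integer_
      if (!is.na(given) && given >= lo && given < hi) {
        summit_pos[j] <- given
      } else {
        # argmax of signal over the peak-window intersection; ties -> smallest coord
        pos <- seq.int(lo, hi - 1L)
        vals <- track_values_at(track, w$chrom, pos)
        summit_pos[j] <- pos[which.max(vals)]
      }
      height[j] <- track_values_at(track, w$chrom, summit_pos[j])
    }
    from_tss <- if (w$strand == "+") summit_pos - w$tss else w$tss - summit_pos
    hits[[i]] <- tibble(
      transcript_id = w$transcript_id,
      gene_symbol = w$gene_symbol,
      peak_chrom = ov$chrom,
      peak_start = ov$start,
      peak_end = ov$end,
      summit_pos = summit_pos,
      summit_from_tss = as.integer(from_tss),
      peak_height = height,
      bed_score = ov$bed_score
    )
  }
  out <- bind_rows(c(list(tibble(
    transcript_id = character(), gene_symbol = character(), peak_chrom = character(),
    peak_start = integer(), peak_end = integer(), summit_pos = integer(),
    summit_from_tss = integer(), peak_height = numeric(), bed_score = numeric()
  )), hits))
  out %>%
    group_by(.data$transcript_id) %>%
    mutate(is_primary = row_number(desc(.data$peak_height)) == 1L) %>%
    ungroup()
}

track_values_at <- function(track, chrom, pos) {
  if (is.null(track)) {
    return(numeric(length(pos)))
  }
  ti <- which(track$chrom == chrom)
  if (length(ti) == 0L) {
    return(numeric(length(pos)))
  }
  o <- order(track$start[ti])
  s <- track$start[ti][o]
  e <- track$end[ti][o]
  v <- track$value[ti][o]
  idx <- findInterval(pos, s)
  out <- numeric(length(pos))
  hit <- idx >= 1L
  hit[hit] <- pos[hit] < e[idx[hit]]
  out[hit] <- v[idx[hit]]
  out
}
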