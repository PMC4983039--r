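# Signal-track input/output and per-gene signal extraction.
#
# A signal track is a tibble (chrom, start, end, value): per-chromosome
# sorted, non-overlapping 0-based half-open intervals of piecewise-constant
# signal. Overlaps in the input are resolved last-writer-wins at parse time.
# Wiggle's 1-based starts are converted here; everything downstream is
# 0-based half-open.

# -- parsing ----------------------------------------------------------------

#' Read a BedGraph signal track
#'
#' @param path Path to a BedGraph file (`chrom start end value`, 0-based
#'   half-open). `track`/`browser`/comment lines are skipped. Gzip-compressed
#'   files are decompressed transparently.
#' @return A signal-track tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open integers) and `value` (double), sorted and
#'   non-overlapping within each chromosome. Overlapping input intervals are
#'   resolved last-writer-wins with a warning; negative values are kept and
#'   counted in a warning.
#' @seealso [read_track()] for format autodetection
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(fields) == 0L) {
    return(finalize_track(empty_track()))
  }
  short <- which(lengths(fields) < 4L)
  if (length(short) > 0L) {
    abort(sprintf("line %d: BedGraph needs 4 whitespace-separated columns", lineno[short[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: non-integer interval coordinate", lineno[bad[1]]))
  }
  bad <- which(is.na(value))
  if (length(bad) > 0L) {
    abort(sprintf("line %d: non-numeric signal value", lineno[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: interval end (%d) must exceed start (%d)",
                  lineno[bad[1]], end[bad[1]], start[bad[1]]))
  }
  finalize_track(tibble(chrom = chrom, start = start, end = end, value = value))
}

#' Read a Wiggle signal track (fixedStep and variableStep)
#'
#' Both Wiggle dialects, freely mixed in one file, are supported. Wiggle
#' coordinates are 1-based; they are converted to the package's 0-based
#' half-open convention on parse. In `variableStep` a missing `span`
#' defaults to 1 (the UCSC default). In `fixedStep` a missing `span`
#' defaults to `step` — contiguous coverage, which is what files in the
#' wild almost always mean; set `strict_span = TRUE` for the formal UCSC
#' default of `span = 1`.
#'
#' @param path Path to a Wiggle file (plain or gzipped).
#' @param strict_span Use `span = 1` when a `fixedStep` declaration omits
#'   `span`, instead of `span = step`.
#' @inherit read_bedgraph return
#' @export
read_wiggle <- function(path, strict_span = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  is_decl <- grepl("^(fixedStep|variableStep)\\b", lines)
  if (length(lines) > 0L && !is_decl[1]) {
    abort(sprintf("line %d: data line before any fixedStep/variableStep declaration", lineno[1]))
  }
  out <- vector("list", sum(is_decl))
  decl_at <- which(is_decl)
  block_end <- c(decl_at[-1] - 1L, length(lines))
  for (b in seq_along(decl_at)) {
    i <- decl_at[b]
    decl <- parse_wig_declaration(lines[i], lineno[i], strict_span)
    if (block_end[b] < i + 1L) next
    data <- lines[(i + 1L):block_end[b]]
    dn <- lineno[(i + 1L):block_end[b]]
    if (decl$type == "fixedStep") {
      value <- suppressWarnings(as.numeric(data))
      bad <- which(is.na(value))
      if (length(bad) > 0L) {
        abort(sprintf("line %d: non-numeric fixedStep value '%s'", dn[bad[1]], data[bad[1]]))
      }
      start <- (decl$start - 1L) + (seq_along(value) - 1L) * decl$step
    } else {
      fl <- strsplit(data, "\\s+")
      short <- which(lengths(fl) < 2L)
      if (length(short) > 0L) {
        abort(sprintf("line %d: variableStep line needs 'position value'", dn[short[1]]))
      }
      pos <- suppressWarnings(as.integer(vapply(fl, `[[`, character(1), 1L)))
      value <- suppressWarnings(as.numeric(vapply(fl, `[[`, character(1), 2L)))
      bad <- which(is.na(pos) | is.na(value))
      if (length(bad) > 0L) {
        abort(sprintf("line %d: malformed variableStep line '%s'", dn[bad[1]], data[bad[1]]))
      }
      start <- pos - 1L
    }
    out[[b]] <- tibble(
      chrom = decl$chrom,
      start = as.integer(start),
      end = as.integer(start + decl$span),
      value = value
    )
  }
  finalize_track(bind_rows(c(list(empty_track()), out)))
}

parse_wig_declaration <- function(line, lineno, strict_span) {
  type <- sub("\\s.*$", "", line)
  kv <- regmatches(line, gregexpr("[A-Za-z]+=\\S+", line, perl = TRUE))[[1]]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  p <- as.list(setNames(vals, keys))
  if (is.null(p$chrom)) {
    abort(sprintf("line %d: %s declaration lacks chrom=", lineno, type))
  }
  if (type == "fixedStep") {
    if (is.null(p$start) || is.null(p$step)) {
      abort(sprintf("line %d: fixedStep declaration needs start= and step=", lineno))
    }
    step <- as.integer(p$step)
    span <- if (!is.null(p$span)) as.integer(p$span) else if (strict_span) 1L else step
    list(type = type, chrom = p$chrom, start = as.integer(p$start), step = step, span = span)
  } else {
    span <- if (!is.null(p$span)) as.integer(p$span) else 1L
    list(type = type, chrom = p$chrom, span = span)
  }
}

#' Read a bigWig signal track
#'
#' Thin wrapper around `rtracklayer::import()` returning the same
#' signal-track tibble as the text parsers (0-based half-open).
#'
#' @param path Path to a bigWig file.
#' @inherit read_bedgraph return
#' @export
read_bigwig <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading bigWig requires the rtracklayer package")
  }
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "BigWig")),
    error = function(e) abort(sprintf("cannot read bigWig file '%s': %s", path, conditionMessage(e)))
  )
  finalize_track(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  ))
}

#' Read a signal track with format autodetection
#'
#' Dispatches to [read_bedgraph()], [read_wiggle()] or [read_bigwig()] based
#' on the file extension (`.bedgraph`/`.bdg`, `.wig`/`.wiggle`, `.bw`/
#' `.bigwig`; a trailing `.gz` is stripped first) or, failing that, on the
#' file content (a `fixedStep`/`variableStep` declaration means Wiggle; a
#' 4-column numeric line means BedGraph). Gzip text input is decompressed
#' transparently; rar archives are not supported and must be extracted
#' beforehand.
#'
#' @param path Path to a signal track file.
#' @param format One of `"auto"`, `"bedgraph"`, `"wiggle"`, `"bigwig"`.
#' @inherit read_bedgraph return
#' @export
read_track <- function(path, format = c("auto", "bedgraph", "wiggle", "bigwig")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_track_format(path)
  switch(format,
    bedgraph = read_bedgraph(path),
    wiggle = read_wiggle(path),
    bigwig = read_bigwig(path)
  )
}

sniff_track_format <- function(path) {
  base <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub("^.*\\.", "", base))
  known <- c(
    bedgraph = "bedgraph", bdg = "bedgraph",
    wig = "wiggle", wiggle = "wiggle",
    bw = "bigwig", bigwig = "bigwig"
  )
  if (ext %in% names(known)) {
    return(known[[ext]])
  }
  # content sniffing: bigWig magic, wiggle declaration, or 4-column numerics
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4L)
  close(con)
  if (length(magic) == 4L) {
    m <- paste(as.character(magic), collapse = "")
    if (m %in% c("26fc8f88", "888ffc26")) {
      return("bigwig")
    }
  }
  head_lines <- tryCatch(readLines(path, n = 50L), error = function(e) character())
  head_lines <- trimws(head_lines[!grepl("^\\s*(#|$|track\\b|browser\\b)", head_lines)])
  if (any(grepl("^(fixedStep|variableStep)\\b", head_lines))) {
    return("wiggle")
  }
  if (length(head_lines) > 0L) {
    f <- strsplit(head_lines[1], "\\s+")[[1]]
    if (length(f) >= 4L && !is.na(suppressWarnings(as.integer(f[2]))) &&
        !is.na(suppressWarnings(as.integer(f[3]))) &&
        !is.na(suppressWarnings(as.numeric(f[4])))) {
      return("bedgraph")
    }
  }
  abort(sprintf(
    "cannot determine track format of '%s'; supported formats: BedGraph, Wiggle (fixedStep/variableStep), bigWig",
    path
  ))
}

empty_track <- function() {
  tibble(chrom = character(), start = integer(), end = integer(), value = numeric())
}

# Sort, resolve overlaps (last interval in file order wins) and warn about
# negative values. The fast path covers well-formed files with no overlaps.
finalize_track <- function(track) {
  neg <- sum(track$value < 0)
  if (neg > 0L) {
    warn(sprintf("%d interval(s) carry negative signal values; kept as-is (log-ratio input?)", neg))
  }
  parts <- split(seq_len(nrow(track)), track$chrom)
  resolved <- lapply(names(parts), function(ch) {
    idx <- parts[[ch]]
    out <- resolve_chrom_overlaps(track$start[idx], track$end[idx], track$value[idx])
    n_over <- attr(out, "n_overlapping")
    out$chrom <- ch
    out <- out[, c("chrom", "start", "end", "value")]
    attr(out, "n_overlapping") <- n_over
    out
  })
  n_clobbered <- sum(vapply(resolved, attr, numeric(1), "n_overlapping"))
  if (n_clobbered > 0L) {
    warn(sprintf("%d overlapping interval(s) resolved last-writer-wins", n_clobbered))
  }
  out <- bind_rows(c(list(empty_track()), resolved[order(names(parts))]))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

resolve_chrom_overlaps <- function(start, end, value) {
  o <- order(start, seq_along(start))
  s <- start[o]
  e <- end[o]
  n <- length(s)
  n_over <- if (n > 1L) sum(s[-1] < cummax(e[-n])) else 0L
  if (n_over == 0L) {
    out <- tibble(start = s, end = e, value = value[o])
  } else {
    # elementary segments between all breakpoints; later file lines overwrite
    bp <- sort(unique(c(start, end)))
    winner <- integer(length(bp) - 1L)
    first_seg <- match(start, bp)
    last_seg <- match(end, bp) - 1L
    for (i in seq_along(start)) {
      winner[first_seg[i]:last_seg[i]] <- i
    }
    covered <- winner > 0L
    out <- tibble(
      start = bp[-length(bp)][covered],
      end = bp[-1][covered],
      value = value[winner[covered]]
    )
  }
  attr(out, "n_overlapping") <- n_over
  out
}

# -- extraction -------------------------------------------------------------

#' Extract per-base signal matrix over promoter windows
#'
#' Builds the genes-by-position signal matrix that both the characteristic
#' binding profile and the regulatory scores are computed from. Each row is
#' one transcript's promoter window read 5'→3' in gene orientation: column 1
#' is `-L` bp upstream of the TSS, the middle column is the TSS itself, the
#' last column `+L` downstream. Minus-strand windows are reversed so that
#' orientation holds for every gene. Bases without track coverage — or below
#' position 0 or on chromosomes absent from the track — contribute 0.
#'
#' @param track A signal-track tibble (see [read_track()]).
#' @param windows A gene table with `window_start`/`window_end` columns from
#'   [promoter_windows()]; all windows must share one width.
#' @return A numeric matrix with one row per transcript (rownames =
#'   `transcript_id`) and `2L + 1` columns. Chromosomes present in the
#'   windows but absent from the track trigger one summary warning.
#' @export
signal_matrix <- function(track, windows) {
  assert_track(track)
  assert_genes(windows, "windows")
  if (!all(c("window_start", "window_end") %in% names(windows))) {
    abort("`windows` must carry window_start/window_end; call promoter_windows() first")
  }
  width <- unique(windows$window_end - windows$window_start)
  if (length(width) != 1L) {
    abort("all promoter windows must have the same width")
  }
  mat <- matrix(0, nrow = nrow(windows), ncol = width)
  missing_chroms <- character()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    o <- order(track$start[ti])
    s <- track$start[ti][o]
    e <- track$end[ti][o]
    v <- track$value[ti][o]
    pos <- rep(windows$window_start[wi], each = width) + rep.int(0:(width - 1L), length(wi))
    idx <- findInterval(pos, s)
    val <- numeric(length(pos))
    hit <- idx >= 1L
    hit[hit] <- pos[hit] < e[idx[hit]]
    val[hit] <- v[idx[hit]]
    m <- matrix(val, ncol = width, byrow = TRUE)
    neg <- windows$strand[wi] == "-"
    if (any(neg)) m[neg, ] <- m[neg, width:1, drop = FALSE]
    mat[wi, ] <- m
  }
  if (length(missing_chroms) > 0L) {
    warn(sprintf(
      "chromosome(s) %s absent from the signal track; their genes get all-zero signal. Track chromosomes: %s",
      paste(missing_chroms, collapse = ", "),
      paste(sort(unique(track$chrom)), collapse = ", ")
    ))
  }
  rownames(mat) <- windows$transcript_id
  mat
}

#' Extract the signal vector for one promoter window
#'
#' Convenience single-window version of [signal_matrix()]: returns the
#' strand-oriented per-base values over one `2L + 1` bp window.
#'
#' @inheritParams signal_matrix
#' @param window A one-row gene table with `window_start`/`window_end` (from
#'   [promoter_windows()]).
#' @return Numeric vector of length `2L + 1`, index `L + 1` being the TSS.
#' @export
extract_signal <- function(track, window) {
  if (nrow(window) != 1L) abort("`window` must be a single row")
  as.numeric(signal_matrix(track, window)[1L, ])
}

# -- writers ----------------------------------------------------------------

track_value_fmt <- function(x) {
  sub("\\.?0+$", "", sprintf("%.10f", x)) # stable decimal text, no sci notation
}

#' Write a signal track as BedGraph
#'
#' @param track A signal-track tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  assert_track(track)
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   track_value_fmt(track$value))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a signal track as Wiggle
#'
#' Emits `fixedStep` blocks for runs of abutting equal-width intervals, or
#' `variableStep` blocks (one declaration per run of equal span). Either
#' dialect reproduces the track's per-base signal exactly.
#'
#' @inheritParams write_bedgraph
#' @param style `"fixedStep"` or `"variableStep"`.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path, style = c("fixedStep", "variableStep")) {
  assert_track(track)
  style <- match.arg(style)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(track) == 0L) {
    return(invisible(path))
  }
  w <- track$end - track$start
  n <- nrow(track)
  if (style == "fixedStep") {
    new_block <- c(TRUE, track$chrom[-1] != track$chrom[-n] |
                     w[-1] != w[-n] |
                     track$start[-1] != track$end[-n])
  } else {
    new_block <- c(TRUE, track$chrom[-1] != track$chrom[-n] | w[-1] != w[-n])
  }
  block <- cumsum(new_block)
  for (b in unique(block)) {
    i <- which(block == b)
    if (style == "fixedStep") {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         track$chrom[i[1]], track$start[i[1]] + 1L, w[i[1]], w[i[1]]), con)
      writeLines(track_value_fmt(track$value[i]), con)
    } else {
      writeLines(sprintf("variableStep chrom=%s span=%d", track$chrom[i[1]], w[i[1]]), con)
      writeLines(sprintf("%d %s", track$start[i] + 1L, track_value_fmt(track$value[i])), con)
    }
  }
  invisible(path)
}

#' Write a signal track as bigWig
#'
#' @inheritParams write_bedgraph
#' @param chrom_sizes Optional named vector of chromosome lengths; defaults
#'   to the largest interval end seen per chromosome.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(track, path, chrom_sizes = NULL) {
  assert_track(track)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("writing bigWig requires the rtracklayer package")
  }
  if (is.null(chrom_sizes)) {
    sizes <- tapply(track$end, track$chrom, max)
    chrom_sizes <- setNames(as.integer(sizes), names(sizes))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value,
    seqlengths = chrom_sizes[sort(unique(track$chrom))]
  )
  rtracklayer::export(gr, path, format = "BigWig")
  invisible(path)
}
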