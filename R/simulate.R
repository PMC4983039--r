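# Synthetic fixtures with known ground truth: toy genomes, signal tracks
# with implanted promoter binding, matching peak files and GMT gene sets.
# Everything is deterministic under `seed`, so end-to-end behavior of the
# scoring and significance machinery can be validated without any external
# download.

#' Simulate a toy genome annotation
#'
#' Lays `n_genes` transcripts round-robin across `n_chroms` chromosomes at
#' regular spacing (with random strands), far enough apart that promoter
#' windows of neighboring genes never overlap.
#'
#' @param n_genes Number of transcripts (>= 2); default 200.
#' @param n_chroms Number of chromosomes; default 2.
#' @param spacing Distance between consecutive TSSs on a chromosome in bp;
#'   must be at least `2 * half_width + 1`. Default 25000.
#' @param half_width The half window length the genome must accommodate;
#'   default 10000.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return A gene table (as from [read_refgene()]) with chromosome sizes in
#'   `attr(, "chrom_sizes")`.
#' @export
simulate_genome <- function(n_genes = 200, n_chroms = 2, spacing = 25000,
                            half_width = 10000, seed = 1) {
  if (n_genes < 2L) abort("`n_genes` must be at least 2")
  if (spacing < 2 * half_width + 1) {
    abort(sprintf("`spacing` (%d) too small for half_width %d: need at least %d bp between TSSs",
                  spacing, half_width, 2 * as.integer(half_width) + 1L))
  }
  withr::with_seed(seed, {
    i <- seq_len(n_genes)
    chrom <- sprintf("chr%d", ((i - 1L) %% n_chroms) + 1L)
    slot <- ((i - 1L) %/% n_chroms) # position index on own chromosome
    tss <- as.integer(half_width + spacing * slot + spacing %/% 2)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tx_len <- sample(1000:5000, n_genes, replace = TRUE)
    tx_start <- ifelse(strand == "+", tss, tss - tx_len + 1L)
    tx_end <- ifelse(strand == "+", tss + tx_len, tss + 1L)
    genes <- tibble(
      transcript_id = sprintf("NM_%04d", i),
      gene_symbol = sprintf("GENE%04d", i),
      chrom = chrom,
      strand = strand,
      tx_start = as.integer(tx_start),
      tx_end = as.integer(tx_end),
      tss = tss
    )
    sizes <- tapply(genes$tss, genes$chrom, max) + spacing
    attr(genes, "chrom_sizes") <- sizes[sort(unique(genes$chrom))]
    genes
  })
}

#' Simulate a TF binding signal track with implanted targets
#'
#' Emulates a coverage-like ChIP signal: i.i.d. exponential background noise
#' on 10 bp tiles (nonnegative and right-skewed, like read coverage), plus a
#' Gaussian bump of given amplitude and width implanted near the TSS of a
#' random subset of "true target" genes. The defaults — 10% targets,
#' amplitude 10 over noise mean 1, bump sd 200 bp — produce a sharp
#' TSS-proximal aggregate profile with clear but not trivial separation
#' between targets and background.
#'
#' @param genes Gene table from [simulate_genome()] (needs `chrom_sizes`
#'   attribute or chromosome sizes are taken as `max(tx_end) + 2 * 10^4`).
#' @param target_fraction Fraction of genes made true targets, in (0, 1).
#' @param amplitude Peak height of the implanted Gaussian bump; 0 gives a
#'   pure-noise null track.
#' @param noise Mean of the exponential background per tile; 0 disables
#'   noise.
#' @param bump_sd Standard deviation of the bump in bp.
#' @param bump_offset Mean bump-center offset from the TSS in gene
#'   orientation (bp; positive = downstream).
#' @param jitter Standard deviation of per-gene random bump-center jitter
#'   (bp); 0 places every bump exactly at `TSS + bump_offset`.
#' @param tile Background noise tile width in bp.
#' @param quantize Optional grid to which all signal values are rounded
#'   (e.g. `1/64`); useful when the track must survive a float32 round trip
#'   (bigWig) without loss.
#' @param seed Integer seed.
#' @return A list of class `"tip_simulation"`: `track` (signal tibble),
#'   `truth` (per-gene tibble with `is_target`, `bump_center`,
#'   `bump_amplitude`), and `params`.
#' @export
simulate_track <- function(genes, target_fraction = 0.1, amplitude = 10,
                           noise = 1, bump_sd = 200, bump_offset = 0,
                           jitter = 0, tile = 10, quantize = NULL, seed = 1) {
  assert_genes(genes)
  if (target_fraction <= 0 || target_fraction >= 1) {
    abort("`target_fraction` must be in (0, 1)")
  }
  sizes <- attr(genes, "chrom_sizes")
  if (is.null(sizes)) {
    sizes <- tapply(pmax(genes$tx_end, genes$tss), genes$chrom, max) + 20000
    sizes <- sizes[sort(unique(genes$chrom))]
  }
  withr::with_seed(seed, {
    n <- nrow(genes)
    n_targets <- max(1L, round(n * target_fraction))
    target_idx <- sort(sample.int(n, n_targets))
    is_target <- seq_len(n) %in% target_idx

    sign <- ifelse(genes$strand == "+", 1L, -1L)
    jit <- if (jitter > 0) round(rnorm(n, 0, jitter)) else rep(0, n)
    center <- genes$tss + sign * (bump_offset + jit)
    center <- ifelse(is_target, as.integer(center), NA_integer_)

    rows <- vector("list", length(sizes))
    for (ci in seq_along(sizes)) {
      ch <- names(sizes)[ci]
      size <- as.integer(ceiling(sizes[[ci]]))
      vals <- numeric(size)
      if (noise > 0) {
        n_tiles <- ceiling(size / tile)
        vals <- rep(rexp(n_tiles, rate = 1 / noise), each = tile)[seq_len(size)]
      }
      if (amplitude > 0) {
        for (gi in which(is_target & genes$chrom == ch)) {
          c0 <- center[gi]
          lo <- max(0L, c0 - 4L * as.integer(bump_sd))
          hi <- min(size - 1L, c0 + 4L * as.integer(bump_sd))
          if (hi < lo) next
          x <- lo:hi
          vals[x + 1L] <- vals[x + 1L] + amplitude * exp(-0.5 * ((x - c0) / bump_sd)^2)
        }
      }
      if (!is.null(quantize)) vals <- round(vals / quantize) * quantize
      r <- rle(vals)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      rows[[ci]] <- tibble(
        chrom = ch,
        start = as.integer(starts[keep]),
        end = as.integer(ends[keep]),
        value = r$values[keep]
      )
    }
    track <- bind_rows(rows)
    truth <- tibble(
      transcript_id = genes$transcript_id,
      gene_symbol = genes$gene_symbol,
      is_target = is_target,
      bump_center = center,
      bump_amplitude = ifelse(is_target, amplitude, 0)
    )
    structure(
      list(
        track = track,
        truth = truth,
        params = list(
          target_fraction = target_fraction, amplitude = amplitude, noise = noise,
          bump_sd = bump_sd, bump_offset = bump_offset, jitter = jitter,
          tile = tile, quantize = quantize, seed = seed, chrom_sizes = sizes
        )
      ),
      class = "tip_simulation"
    )
  })
}

#' Simulated narrowPeak calls for the implanted bumps
#'
#' Emits one peak per implanted bump, centered on the true bump center with
#' the exact summit offset, so downstream summit annotation can be checked
#' against ground truth.
#'
#' @param sim A `tip_simulation` from [simulate_track()].
#' @param genes The gene table the simulation was built from.
#' @param width Peak width in bp (summit sits at `width / 2`).
#' @return A peak tibble in the shape of [read_narrowpeak()].
#' @export
simulate_peaks <- function(sim, genes, width = 400) {
  truth <- sim$truth
  half <- as.integer(width %/% 2)
  t2 <- truth[truth$is_target, ]
  chrom <- genes$chrom[match(t2$transcript_id, genes$transcript_id)]
  tibble(
    chrom = chrom,
    start = as.integer(t2$bump_center - half),
    end = as.integer(t2$bump_center + half),
    name = paste0("peak_", t2$transcript_id),
    bed_score = t2$bump_amplitude * 100,
    summit_offset = half
  )
}

#' Simulate a GMT annotation with enriched terms
#'
#' Background terms draw members uniformly from the gene universe; enriched
#' terms draw a configurable share of their members from the true targets,
#' so an end-to-end run should rank them first. Optionally emits one
#' deliberately oversized term — padded with clearly synthetic placeholder
#' symbols to exceed the size filter — to exercise the `< 1000` exclusion.
#'
#' @param genes Gene table (universe = its gene symbols).
#' @param sim A `tip_simulation` (for the true target set), or `NULL` for
#'   purely uniform terms.
#' @param n_terms Number of background terms.
#' @param n_enriched Number of target-enriched terms.
#' @param enriched_size Genes per enriched term.
#' @param enriched_target_frac Share of each enriched term drawn from true
#'   targets (capped by their number).
#' @param size_range Min/max size of background terms.
#' @param oversize_term Also emit `GO:BIG` with 1000 members (universe genes
#'   plus `SYNTHFILLnnn` placeholders); must be filtered out downstream.
#' @param seed Integer seed.
#' @return A long annotation tibble as from [read_gmt()].
#' @export
simulate_gmt <- function(genes, sim = NULL, n_terms = 20, n_enriched = 1,
                         enriched_size = 20, enriched_target_frac = 0.75,
                         size_range = c(5, 40), oversize_term = FALSE, seed = 1) {
  universe <- unique(toupper(genes$gene_symbol))
  targets <- if (!is.null(sim)) {
    toupper(sim$truth$gene_symbol[sim$truth$is_target])
  } else {
    character()
  }
  withr::with_seed(seed, {
    out <- list()
    for (t in seq_len(n_enriched)) {
      n_from_targets <- min(length(targets), round(enriched_size * enriched_target_frac))
      members <- c(
        sample(targets, n_from_targets),
        sample(setdiff(universe, targets), enriched_size - n_from_targets)
      )
      out[[length(out) + 1L]] <- tibble(
        term_id = sprintf("GO:ENR%03d", t),
        term_name = sprintf("synthetic enriched term %d", t),
        gene_symbol = unique(members)
      )
    }
    for (t in seq_len(n_terms)) {
      sz <- sample(size_range[1]:size_range[2], 1)
      out[[length(out) + 1L]] <- tibble(
        term_id = sprintf("GO:BG%04d", t),
        term_name = sprintf("synthetic background term %d", t),
        gene_symbol = sample(universe, min(sz, length(universe)))
      )
    }
    if (oversize_term) {
      filler <- sprintf("SYNTHFILL%04d", seq_len(max(0, 1000 - length(universe))))
      out[[length(out) + 1L]] <- tibble(
        term_id = "GO:BIG",
        term_name = "synthetic oversized term (size filter fixture)",
        gene_symbol = c(universe, filler)
      )
    }
    bind_rows(out)
  })
}

#' Write a gene table as a UCSC refGene-style file
#'
#' Emits the 16-column refGene layout (with leading `bin`); exon structure
#' is collapsed to a single exon spanning the transcript, which is all the
#' promoter-window machinery needs.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refgene <- function(genes, path) {
  assert_genes(genes)
  lines <- sprintf(
    "0\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t1\t%d,\t%d,\t0\t%s\tcmpl\tcmpl\t0,",
    genes$transcript_id, genes$chrom, genes$strand,
    genes$tx_start, genes$tx_end, genes$tx_start, genes$tx_end,
    genes$tx_start, genes$tx_end, genes$gene_symbol
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write peaks as a narrowPeak file
#'
#' @param peaks Peak tibble (as from [read_narrowpeak()] or
#'   [simulate_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
  score <- ifelse(is.na(peaks$bed_score), 0, peaks$bed_score)
  name <- if ("name" %in% names(peaks)) peaks$name else "."
  name[is.na(name)] <- "."
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t.\t0\t-1\t-1\t%d",
    peaks$chrom, peaks$start, peaks$end, name,
    track_value_fmt(score), as.integer(summit)
  )
  writeLines(lines, path)
  invisible(path)
}
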