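test_that("BedGraph parsing loads 0-based half-open intervals as-is", {
  f <- write_tmp(c(
    "track type=bedGraph name=x",
    "chr1\t0\t10\t2.0",
    "chr1\t10\t20\t2.0"
  ), ".bedgraph")
  tr <- read_bedgraph(f)
  expect_equal(nrow(tr), 2L) # abutting equal-value intervals are not merged
  expect_equal(tr$start, c(0L, 10L))
  expect_equal(per_base(tr, "chr1", 0, 10), rep(2, 10))
})

test_that("malformed BedGraph lines are rejected with their line number", {
  expect_error(read_bedgraph(write_tmp(c("chr1\t0\t10\t1", "chr1\t10\t5\t1"))), "line 2")
  expect_error(read_bedgraph(write_tmp("chr1\t0\t10\tNOPE")), "non-numeric")
  expect_error(read_bedgraph(write_tmp("chr1\tx\t10\t1")), "non-integer")
})

test_that("fixedStep and variableStep Wiggle blocks convert 1-based starts", {
  f <- write_tmp(c(
    "fixedStep chrom=chr1 start=1 step=5 span=5",
    "1.0", "2.0",
    "variableStep chrom=chr1 span=2",
    "11 3.0",
    "variableStep chrom=chr2",
    "5 4.0"
  ), ".wig")
  tr <- read_wiggle(f)
  expect_equal(per_base(tr, "chr1", 0, 12), c(rep(1, 5), rep(2, 5), 3, 3))
  # span omitted in variableStep defaults to 1; 1-based 5 -> [4, 5)
  c2 <- tr[tr$chrom == "chr2", ]
  expect_equal(c(c2$start, c2$end), c(4L, 5L))
})

test_that("fixedStep span defaults to step unless strict_span", {
  lines <- c("fixedStep chrom=chr1 start=1 step=10", "1.0", "2.0")
  tr <- read_wiggle(write_tmp(lines))
  expect_equal(tr$end - tr$start, c(10L, 10L))
  strict <- read_wiggle(write_tmp(lines), strict_span = TRUE)
  expect_equal(strict$end - strict$start, c(1L, 1L))
  expect_equal(strict$start, c(0L, 10L))
})

test_that("a data line before any declaration is rejected", {
  expect_error(read_wiggle(write_tmp(c("1.0", "fixedStep chrom=chr1 start=1 step=1"))),
               "before any")
})

test_that("bigWig round-trips the text-parser contract", {
  tr <- read_bedgraph(write_tmp(c("chr1\t0\t10\t2.0", "chr1\t100\t200\t7.5")))
  bw <- tempfile(fileext = ".bw")
  write_bigwig(tr, bw, chrom_sizes = c(chr1 = 1000))
  tr2 <- read_bigwig(bw)
  expect_equal(per_base(tr2, "chr1", 0, 250), per_base(tr, "chr1", 0, 250))
  expect_error(read_bigwig(write_tmp("not a bigwig", ".bw")), "cannot read")
})

test_that("read_track dispatches on extension, gzip and content", {
  bg_lines <- "chr1\t0\t10\t2.0"
  f_gz <- tempfile(fileext = ".bedgraph.gz")
  con <- gzfile(f_gz, "w"); writeLines(bg_lines, con); close(con)
  expect_equal(read_track(f_gz)$value, 2.0)
  # wiggle content in a .txt file is sniffed
  f_txt <- write_tmp(c("fixedStep chrom=chr1 start=1 step=5", "1.0"), ".txt")
  expect_equal(read_track(f_txt)$end, 5L)
  # bare 4-column numeric content sniffs as bedgraph
  f_txt2 <- write_tmp(bg_lines, ".txt")
  expect_equal(read_track(f_txt2)$value, 2.0)
  expect_error(read_track(write_tmp("who knows", ".xyz")), "supported formats")
})

test_that("overlapping intervals resolve last-writer-wins with a warning", {
  f <- write_tmp(c(
    "chr1\t0\t100\t1.0",
    "chr1\t50\t60\t9.0"
  ))
  expect_warning(tr <- read_bedgraph(f), "last-writer-wins")
  expect_equal(per_base(tr, "chr1", 0, 100),
               c(rep(1, 50), rep(9, 10), rep(1, 40)))
  # in reverse file order the early writer is clobbered
  f2 <- write_tmp(c(
    "chr1\t50\t60\t9.0",
    "chr1\t0\t100\t1.0"
  ))
  expect_warning(tr2 <- read_bedgraph(f2), "last-writer-wins")
  expect_equal(per_base(tr2, "chr1", 0, 100), rep(1, 100))
})

test_that("negative values pass through with a summary warning", {
  expect_warning(tr <- read_bedgraph(write_tmp("chr1\t0\t10\t-2.5")), "negative")
  expect_equal(tr$value, -2.5)
})

test_that("the same coverage in BedGraph, fixedStep and variableStep is per-base identical", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- 20
      w <- sample(c(5L, 10L), n, replace = TRUE)
      start <- cumsum(c(0L, w[-n] + sample(c(0L, 7L), n - 1, replace = TRUE)))
      tr0 <- track_tbl("chr1", start, start + w, round(runif(n), 3))
      bg <- read_bedgraph(write_bedgraph(tr0, tempfile(fileext = ".bedgraph")))
      fx <- read_wiggle(write_wiggle(tr0, tempfile(fileext = ".wig"), style = "fixedStep"))
      vs <- read_wiggle(write_wiggle(tr0, tempfile(fileext = ".wig"), style = "variableStep"))
      to <- max(tr0$end)
      expect_equal(per_base(bg, "chr1", 0, to), per_base(tr0, "chr1", 0, to))
      expect_equal(per_base(fx, "chr1", 0, to), per_base(tr0, "chr1", 0, to))
      expect_equal(per_base(vs, "chr1", 0, to), per_base(tr0, "chr1", 0, to))
    }
  })
})

test_that("extract_signal orients 5'->3', zero-fills gaps and clips below 0", {
  # flat value c over the whole window, plus strand
  tr <- track_tbl("chr1", 0, 10000, 3)
  g <- gene_tbl("t", "chr1", "+", 5000, 6000)
  w <- promoter_windows(g, 100)
  expect_equal(extract_signal(tr, w), rep(3, 201))

  # spike at TSS+3 on a minus-strand gene appears at index L-3 (1-based: L-2)
  gm <- gene_tbl("t", "chr1", "-", 4000, 5000) # TSS = 4999
  spike <- track_tbl("chr1", 5002, 5003, 8) # genomic TSS+3
  L <- 50
  v <- extract_signal(spike, promoter_windows(gm, L))
  expect_equal(which(v != 0), L - 3 + 1)
  expect_equal(v[L - 3 + 1], 8)

  # window overhanging position 0 gets leading zeros
  g0 <- gene_tbl("t", "chr1", "+", 10, 500)
  v0 <- extract_signal(track_tbl("chr1", 0, 1000, 1), promoter_windows(g0, 50))
  expect_equal(v0, c(rep(0, 40), rep(1, 61)))

  # chromosome absent from track: all zero with a warning, not an error
  expect_warning(
    v_missing <- extract_signal(track_tbl("chrX", 0, 10, 1), promoter_windows(g, 10)),
    "absent"
  )
  expect_equal(v_missing, rep(0, 21))
})

test_that("minus-strand extraction is the mirror of plus-strand extraction", {
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- 15
      start <- sort(sample(0:2000, n))
      tr <- track_tbl("chr1", start, start + sample(1:40, n, replace = TRUE), runif(n))
      suppressWarnings(tr <- tipscore:::finalize_track(tr))
      g_plus <- gene_tbl("t", "chr1", "+", 1000, 1500)
      g_minus <- gene_tbl("t", "chr1", "-", 500, 1001) # same TSS = 1000
      vp <- extract_signal(tr, promoter_windows(g_plus, 200))
      vm <- extract_signal(tr, promoter_windows(g_minus, 200))
      expect_equal(vm, rev(vp))
    }
  })
})

test_that("a track written to BedGraph and re-parsed is value-identical", {
  withr::with_seed(3, {
    start <- sort(sample(0:5000, 30))
    tr <- track_tbl("chr7", start, start + sample(1:50, 30, replace = TRUE), round(runif(30), 4))
    suppressWarnings(tr <- tipscore:::finalize_track(tr))
    tr2 <- read_bedgraph(write_bedgraph(tr, tempfile(fileext = ".bedgraph")))
    expect_equal(per_base(tr2, "chr7", 0, 5100), per_base(tr, "chr7", 0, 5100))
  })
})
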