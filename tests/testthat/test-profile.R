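# Scoring core: characteristic profile, regulatory scores, z-scores.

test_that("a flat track gives a constant profile with uniform weights", {
  g <- gene_tbl(sprintf("t%d", 1:10), "chr1", "+", seq(1000, 10000, by = 1000),
                seq(1500, 10500, by = 1000))
  tr <- track_tbl("chr1", 0, 20000, 2)
  p <- binding_profile(tr, g, half_width = 50)
  expect_equal(p$mean_signal, rep(2, 101))
  expect_equal(p$weight, rep(1 / 101, 101))
  expect_equal(sum(p$weight), 1, tolerance = 1e-12)
})

test_that("a shared spike exactly at every TSS gives a point-mass weight at offset 0", {
  tss <- seq(1000, 5000, by = 1000)
  g <- gene_tbl(sprintf("t%d", 1:5), "chr1", "+", tss, tss + 500)
  tr <- track_tbl("chr1", tss, tss + 1, 4)
  p <- binding_profile(tr, g, half_width = 20)
  expect_equal(p$weight[p$offset == 0], 1)
  expect_equal(sum(p$weight), 1)
})

test_that("profile and scores match a hand-computed 3-gene oracle", {
  # three + strand genes, 5 bp windows (L = 2), hand-written per-base signal
  g <- gene_tbl(c("a", "b", "c"), "chr1", "+", c(10, 30, 50), c(20, 40, 60))
  tr <- track_tbl(
    "chr1",
    c(8, 9, 10, 11, 12, 28, 29, 30, 31, 32, 48, 49, 50, 51, 52),
    c(9, 10, 11, 12, 13, 29, 30, 31, 32, 33, 49, 50, 51, 52, 53),
    c(1, 2, 5, 2, 1, 0, 1, 3, 1, 0, 2, 2, 2, 2, 2)
  )
  f_a <- c(1, 2, 5, 2, 1)
  f_b <- c(0, 1, 3, 1, 0)
  f_c <- c(2, 2, 2, 2, 2)
  raw <- (f_a + f_b + f_c) / 3
  wts <- raw / sum(raw)
  p <- binding_profile(tr, g, half_width = 2)
  expect_equal(p$mean_signal, raw)
  expect_equal(p$weight, wts)
  sc <- regulatory_scores(tr, p, genes = g, half_width = 2)
  expect_equal(sc$score, c(sum(wts * f_a), sum(wts * f_b), sum(wts * f_c)))
})

test_that("an all-zero aggregate aborts with a chromosome-mismatch hint", {
  g <- gene_tbl(c("a", "b"), "chr1", "+", c(100, 300), c(200, 400))
  tr <- track_tbl("1", 0, 1000, 5) # Ensembl-style name, no 'chr' prefix
  expect_error(suppressWarnings(binding_profile(tr, g, half_width = 10)),
               "share no signal")
})

test_that("a flat per-gene signal scores exactly that constant; zero signal scores 0", {
  g <- gene_tbl(c("a", "b"), "chr1", "+", c(1000, 5000), c(2000, 6000))
  tr <- track_tbl("chr1", c(900, 950), c(950, 1200), c(7, 7)) # flat 7 around gene a only
  p <- binding_profile(tr, g, half_width = 50)
  sc <- regulatory_scores(tr, p, genes = g, half_width = 50)
  expect_equal(sc$score[sc$transcript_id == "a"], 7)
  expect_equal(sc$score[sc$transcript_id == "b"], 0)
})

test_that("z-scores standardize with sample sd and are location/scale invariant", {
  expect_equal(zscore(c(0, 2)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  x <- c(1.2, 3.4, 2.2, 8.0, 0.5)
  expect_equal(zscore(x + 100), zscore(x))
  expect_equal(zscore(x * 7), zscore(x))
  expect_equal(mean(zscore(x)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(x)), 1, tolerance = 1e-12)
  expect_error(zscore(rep(1, 5)), "degenerate")
})

test_that("doubling the track doubles scores and leaves z-scores unchanged", {
  g <- simulate_genome(n_genes = 30, spacing = 5000, half_width = 2000, seed = 2)
  sim <- simulate_track(g, seed = 2)
  s1 <- tip_score(sim$track, g, half_width = 2000)
  tr2 <- sim$track
  tr2$value <- tr2$value * 2
  s2 <- tip_score(tr2, g, half_width = 2000)
  expect_equal(s2$score, 2 * s1$score, tolerance = 1e-12)
  expect_equal(s2$zscore, s1$zscore, tolerance = 1e-9)
})

test_that("negative profile entries are floored for weights, with a warning", {
  g <- gene_tbl(c("a", "b"), "chr1", "+", c(1000, 2000), c(1500, 2500))
  tr <- track_tbl("chr1", c(995, 1000), c(1000, 1010), c(-3, 2)) # log-ratio style
  suppressWarnings(
    expect_warning(p <- binding_profile(tr, g, half_width = 10), "floored")
  )
  expect_true(all(p$weight >= 0))
  expect_equal(sum(p$weight), 1, tolerance = 1e-12)
  expect_true(any(p$mean_signal < 0))
})

test_that("implanted targets out-score background genes on average", {
  g <- simulate_genome(n_genes = 80, spacing = 5000, half_width = 2000, seed = 4)
  sim <- simulate_track(g, amplitude = 5, noise = 1, seed = 4)
  sc <- tip_score(sim$track, g, half_width = 2000)
  z_t <- sc$zscore[sim$truth$is_target]
  z_b <- sc$zscore[!sim$truth$is_target]
  expect_gt(mean(z_t), mean(z_b))
})

test_that("mirroring the genome and track reproduces identical scores", {
  g <- simulate_genome(n_genes = 40, spacing = 5000, half_width = 2000, seed = 6)
  sim <- simulate_track(g, seed = 6)
  G <- max(sim$track$end) + 10000L
  g_m <- g
  g_m$tx_start <- G - g$tx_end
  g_m$tx_end <- G - g$tx_start
  g_m$strand <- ifelse(g$strand == "+", "-", "+")
  g_m$tss <- ifelse(g_m$strand == "+", g_m$tx_start, g_m$tx_end - 1L)
  tr_m <- sim$track
  tr_m$start <- G - sim$track$end
  tr_m$end <- G - sim$track$start
  s1 <- tip_score(sim$track, g, half_width = 2000)
  s2 <- tip_score(tr_m, g_m, half_width = 2000)
  expect_equal(s2$score, s1$score, tolerance = 1e-12)
  expect_equal(s2$zscore, s1$zscore, tolerance = 1e-9)
})
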