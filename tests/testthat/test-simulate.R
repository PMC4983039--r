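# Synthetic fixture generators: determinism, ground-truth wiring, and the
# end-to-end behavior they were built to expose.

test_that("generators are deterministic under a fixed seed", {
  g1 <- simulate_genome(n_genes = 40, spacing = 5000, half_width = 2000, seed = 1)
  g2 <- simulate_genome(n_genes = 40, spacing = 5000, half_width = 2000, seed = 1)
  expect_identical(g1, g2)
  s1 <- simulate_track(g1, seed = 2)
  s2 <- simulate_track(g1, seed = 2)
  expect_identical(s1$track, s2$track)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_gmt(g1, s1, seed = 3), simulate_gmt(g1, s1, seed = 3))
  expect_false(identical(simulate_track(g1, seed = 3)$track, s1$track))
})

test_that("a toy genome has both strands, unique ids and respects spacing", {
  g <- simulate_genome(n_genes = 30, spacing = 5000, half_width = 2000, seed = 4)
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_equal(anyDuplicated(g$transcript_id), 0L)
  gaps <- g %>%
    dplyr::group_by(chrom) %>%
    dplyr::summarise(min_gap = min(diff(sort(tss))), .groups = "drop")
  expect_true(all(gaps$min_gap >= 2 * 2000 + 1))
  expect_error(simulate_genome(n_genes = 10, spacing = 3000, half_width = 2000),
               "too small")
  expect_error(simulate_genome(n_genes = 1), "at least 2")
  # the 2-gene minimal case survives a full scoring pass
  g2 <- simulate_genome(n_genes = 2, spacing = 5000, half_width = 2000, seed = 5)
  sim2 <- simulate_track(g2, target_fraction = 0.5, seed = 5)
  expect_equal(nrow(tip_score(sim2$track, g2, half_width = 2000)), 2L)
})

test_that("amplitude 0 yields a null track where targets do not stand out", {
  g <- simulate_genome(n_genes = 100, spacing = 5000, half_width = 2000, seed = 6)
  sim <- simulate_track(g, amplitude = 0, seed = 6)
  sc <- score_significance(tip_score(sim$track, g, half_width = 2000), seed = 1)
  # true targets are indistinguishable: roughly as often above the median as below
  frac_above <- mean(sc$zscore[sim$truth$is_target] > stats::median(sc$zscore))
  expect_gt(frac_above, 0.1)
  expect_lt(frac_above, 0.9)
})

test_that("with strong jitter-free bumps all targets out-rank all background genes", {
  g <- simulate_genome(n_genes = 100, spacing = 5000, half_width = 2000, seed = 7)
  sim <- simulate_track(g, amplitude = 10, noise = 1, jitter = 0, seed = 7)
  sc <- tip_score(sim$track, g, half_width = 2000)
  expect_gt(min(sc$score[sim$truth$is_target]), max(sc$score[!sim$truth$is_target]))
})

test_that("recovery sensitivity is nondecreasing in bump amplitude", {
  g <- simulate_genome(n_genes = 100, spacing = 5000, half_width = 2000, seed = 8)
  sens <- vapply(c(0.5, 3, 10), function(a) {
    sim <- simulate_track(g, amplitude = a, seed = 8)
    sc <- score_significance(tip_score(sim$track, g, half_width = 2000), seed = 1)
    called <- call_targets(sc, 0.05, "mixture")$transcript_id
    truth <- sim$truth$transcript_id[sim$truth$is_target]
    length(intersect(called, truth)) / length(truth)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})

test_that("the same simulation written as BedGraph or Wiggle scores identically", {
  g <- simulate_genome(n_genes = 40, spacing = 5000, half_width = 2000, seed = 9)
  sim <- simulate_track(g, quantize = 1 / 64, seed = 9)
  f_bg <- write_bedgraph(sim$track, tempfile(fileext = ".bedgraph"))
  f_wig <- write_wiggle(sim$track, tempfile(fileext = ".wig"))
  s_bg <- tip_score(read_track(f_bg), g, half_width = 2000)
  s_wig <- tip_score(read_track(f_wig), g, half_width = 2000)
  expect_identical(s_bg$score, s_wig$score)
})

test_that("simulated peaks annotate every implanted target at the exact summit", {
  g <- simulate_genome(n_genes = 60, spacing = 5000, half_width = 2000, seed = 10)
  sim <- simulate_track(g, jitter = 0, seed = 10)
  pk <- simulate_peaks(sim, g)
  targets <- g[sim$truth$is_target, ]
  hits <- annotate_peaks(pk, targets, g, half_width = 2000, track = sim$track)
  expect_setequal(unique(hits$transcript_id), targets$transcript_id)
  # with jitter 0 and offset 0 the summit is the TSS itself
  primary <- hits[hits$is_primary, ]
  expect_true(all(primary$summit_from_tss == 0))
  # non-targets yield no hits
  bg <- g[!sim$truth$is_target, ][1:5, ]
  expect_equal(nrow(annotate_peaks(pk, bg, g, half_width = 2000, track = sim$track)), 0L)
})

test_that("an enriched GMT term ranks first after a strong-signal run", {
  g <- simulate_genome(n_genes = 100, spacing = 5000, half_width = 2000, seed = 11)
  sim <- simulate_track(g, amplitude = 10, seed = 11)
  ann <- simulate_gmt(g, sim, n_terms = 15, n_enriched = 1, oversize_term = TRUE, seed = 11)
  expect_gte(sum(ann$term_id == "GO:BIG"), 1000)
  sc <- score_significance(tip_score(sim$track, g, half_width = 2000), seed = 1)
  targets <- call_targets(sc, 0.05, "mixture")
  res <- go_enrichment(targets$gene_symbol, sc$gene_symbol, ann, p_threshold = Inf)
  expect_equal(res$term_id[1], "GO:ENR001")
  expect_false("GO:BIG" %in% res$term_id)
})
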