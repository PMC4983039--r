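# Small in-code fixture builders shared across the test files.

# gene table row(s) with the strand-oriented TSS filled in
gene_tbl <- function(transcript_id, chrom, strand, tx_start, tx_end,
                     gene_symbol = transcript_id) {
  tibble::tibble(
    transcript_id = transcript_id,
    gene_symbol = gene_symbol,
    chrom = chrom,
    strand = strand,
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    tss = as.integer(ifelse(strand == "+", tx_start, tx_end - 1L))
  )
}

track_tbl <- function(chrom, start, end, value) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), value = as.numeric(value))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# per-base expansion of a track over [from, to) on one chromosome --
# independent brute-force rendering used as an oracle for the parsers
# and for extract_signal
per_base <- function(track, chrom, from, to) {
  out <- numeric(to - from)
  tr <- track[track$chrom == chrom, ]
  for (i in seq_len(nrow(tr))) {
    lo <- max(tr$start[i], from)
    hi <- min(tr$end[i], to)
    if (hi > lo) out[(lo - from + 1):(hi - from)] <- tr$value[i]
  }
  out
}

# direct evaluation of one EM iteration: posterior responsibilities and the
# weighted-moment parameter updates, written independently of the package's
# EM loop
em_step_oracle <- function(z, w, mu, sigma) {
  d1 <- w[1] * dnorm(z, mu[1], sigma[1])
  d2 <- w[2] * dnorm(z, mu[2], sigma[2])
  tot <- d1 + d2
  post <- cbind(d1 / tot, d2 / tot)
  nk <- colSums(post)
  mu_new <- c(sum(post[, 1] * z) / nk[1], sum(post[, 2] * z) / nk[2])
  var_new <- c(
    sum(post[, 1] * (z - mu_new[1])^2) / nk[1],
    sum(post[, 2] * (z - mu_new[2])^2) / nk[2]
  )
  list(post = post, w = nk / length(z), mu = mu_new, var = var_new)
}

# mixture log-likelihood evaluated directly
loglik_oracle <- function(z, w, mu, sigma) {
  sum(log(w[1] * dnorm(z, mu[1], sigma[1]) + w[2] * dnorm(z, mu[2], sigma[2])))
}

# reference BH step-up, written from the definition: q_(i) = min_{j >= i}
# m * p_(j) / j, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# exhaustive hypergeometric upper tail from binomial coefficients
hyper_oracle <- function(k, N, K, n) {
  support <- max(0, n - (N - K)):min(K, n)
  mass <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(mass[support >= k])
}
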