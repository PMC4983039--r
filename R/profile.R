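# The TIP scoring core: characteristic TSS-centered binding profile and
# profile-weighted regulatory scores.
#
# For N transcripts with strand-oriented per-base promoter signal f_g(x),
# x = -L..L, the characteristic profile is h(x) = (1/N) sum_g f_g(x); the
# weight vector is w(x) = h(x) / sum_x h(x); and each gene's regulatory
# score is s_g = sum_x w(x) f_g(x). Scores are standardized to z-scores
# (sample sd) before significance estimation.

#' Characteristic TSS-centered binding profile
#'
#' Averages the strand-oriented promoter signal of all transcripts at each
#' TSS offset (the aggregation plot) and normalizes the mean profile into a
#' weight vector summing to 1. With log-ratio input the raw profile can dip
#' below zero; weights are then computed on the profile floored at zero,
#' with a warning reporting the floored mass, so that they remain a
#' probability-like vector.
#'
#' @param signal A genes-by-position matrix from [signal_matrix()], or a
#'   signal-track tibble (in which case `genes` and `half_width` are used to
#'   build the matrix).
#' @param genes Gene table; required when `signal` is a track.
#' @param half_width Half window length `L` in bp; default 10000.
#' @return A tibble of class `"binding_profile"` with columns `offset`
#'   (`-L..L` bp relative to the TSS, 5'→3'), `mean_signal` and `weight`,
#'   and attributes `n_genes` and `floored_mass`.
#' @examples
#' genes <- simulate_genome(n_genes = 20, seed = 1)
#' sim <- simulate_track(genes, seed = 1)
#' binding_profile(sim$track, genes, half_width = 2000)
#' @export
binding_profile <- function(signal, genes = NULL, half_width = 10000) {
  mat <- as_signal_mat(signal, genes, half_width)
  if (nrow(mat) < 2L) abort("need at least 2 transcripts to build a binding profile")
  raw <- colMeans(mat)
  if (sum(raw) == 0) {
    abort(paste(
      "track and annotation share no signal: the aggregate binding profile is all zero.",
      "Check for a chromosome-name mismatch between the track and the annotation."
    ))
  }
  floored <- pmax(raw, 0)
  floored_mass <- sum(raw[raw < 0])
  if (floored_mass < 0) {
    warn(sprintf("profile has negative entries; weights computed on the profile floored at 0 (floored mass %.4g)",
                 floored_mass))
  }
  L <- (length(raw) - 1L) %/% 2L
  out <- tibble(
    offset = seq.int(-L, L),
    mean_signal = raw,
    weight = floored / sum(floored)
  )
  class(out) <- c("binding_profile", class(out))
  attr(out, "n_genes") <- nrow(mat)
  attr(out, "floored_mass") <- floored_mass
  out
}

#' Profile-weighted regulatory scores and z-scores
#'
#' Scores each transcript as the weight-vector dot product with its
#' strand-oriented promoter signal, then standardizes the scores to
#' z-scores (sample standard deviation). A flat signal of value c scores
#' exactly c, since the weights sum to 1.
#'
#' @inheritParams binding_profile
#' @param profile A `binding_profile` (or anything with a `weight` column of
#'   matching length).
#' @return A tibble with one row per transcript: the gene columns plus
#'   `score` and `zscore`.
#' @export
regulatory_scores <- function(signal, profile, genes = NULL, half_width = 10000) {
  mat <- as_signal_mat(signal, genes, half_width)
  if (!is.data.frame(profile) || !"weight" %in% names(profile)) {
    abort("`profile` must be a binding_profile (see binding_profile())")
  }
  if (nrow(profile) != ncol(mat)) {
    abort(sprintf("profile length (%d) does not match window width (%d)", nrow(profile), ncol(mat)))
  }
  scores <- as.numeric(mat %*% profile$weight)
  base <- if (is.data.frame(signal)) {
    # caller passed a track: rebuild gene columns from `genes`
    as_tibble(genes)
  } else if (!is.null(genes)) {
    as_tibble(genes)
  } else {
    tibble(transcript_id = rownames(mat))
  }
  keep <- intersect(c("transcript_id", "gene_symbol", "chrom", "strand", "tss"), names(base))
  out <- base[, keep]
  out$score <- scores
  out$zscore <- zscore(scores)
  out
}

#' Standardize scores to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation. Location and
#' scale shifts of the input leave the result unchanged.
#'
#' @param x Numeric vector of at least 2 finite values.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) abort("need at least 2 scores to standardize")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("degenerate score distribution: standard deviation is 0")
  (x - mean(x)) / s
}

#' Score all transcripts against a signal track
#'
#' One-call front end to the scoring core: builds promoter windows, extracts
#' the signal matrix, computes the characteristic binding profile, and
#' returns per-transcript regulatory scores and z-scores with the profile
#' attached as an attribute.
#'
#' @param track A signal-track tibble or a path readable by [read_track()].
#' @param genes A gene table or a path readable by [read_refgene()].
#' @param half_width Half window length `L` in bp; default 10000.
#' @return The [regulatory_scores()] tibble with the `binding_profile`
#'   available as `attr(, "profile")`.
#' @examples
#' genes <- simulate_genome(n_genes = 30, seed = 7)
#' sim <- simulate_track(genes, seed = 7)
#' scores <- tip_score(sim$track, genes, half_width = 2000)
#' head(dplyr::arrange(scores, dplyr::desc(score)))
#' @export
tip_score <- function(track, genes, half_width = 10000) {
  if (is.character(track)) track <- read_track(track)
  if (is.character(genes)) genes <- read_refgene(genes)
  assert_track(track)
  assert_genes(genes)
  win <- promoter_windows(genes, half_width)
  mat <- signal_matrix(track, win)
  profile <- binding_profile(mat)
  out <- regulatory_scores(mat, profile, genes = genes)
  attr(out, "profile") <- profile
  out
}

as_signal_mat <- function(signal, genes, half_width) {
  if (is.matrix(signal)) {
    return(signal)
  }
  if (is.data.frame(signal)) {
    if (is.null(genes)) abort("`genes` is required when `signal` is a track tibble")
    win <- promoter_windows(genes, half_width)
    return(signal_matrix(signal, win))
  }
  abort("`signal` must be a matrix from signal_matrix() or a signal-track tibble")
}
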