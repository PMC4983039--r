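# End-to-end orchestration: annotation -> signal -> profile -> scores ->
# mixture -> FDR -> optional peak annotation and GO enrichment, written out
# as five panel files plus a cache that lets thresholds be changed without
# recomputing scores or refitting the mixture.

PANEL_FILES <- c(
  summary = "run_summary.tsv",
  profile = "binding_profile.tsv",
  density = "zscore_density.tsv",
  targets = "target_genes.tsv",
  go = "go_enrichment.tsv"
)

#' Run the full target-identification pipeline
#'
#' Reads the inputs, scores every transcript, fits the two-component
#' mixture, calls targets at the FDR threshold, optionally annotates peak
#' summits in target promoters and tests GO enrichment, and writes five
#' panel files to `out_dir`: a run-summary table, the characteristic
#' binding profile, the z-score density (histogram plus fitted component
#' curves), the target-gene table (both p-value routes side by side) and
#' the GO enrichment table. A cache under `out_dir/cache/` supports
#' [tip_rethreshold()].
#'
#' @param track Signal track: a tibble or a path readable by [read_track()].
#' @param annotation Gene annotation: a tibble, a refGene-style path, or a
#'   `.bed` path (BED6).
#' @param out_dir Output directory (created if needed).
#' @param peaks Optional peak tibble or BED/narrowPeak path.
#' @param gmt Optional annotation tibble ([read_gmt()] shape) or GMT path.
#' @param half_width Half promoter-window length `L` in bp; default 10000.
#' @param fdr_threshold FDR threshold for target calling; default 0.05.
#' @param go_p_threshold Raw p-value threshold for reported GO terms;
#'   default 0.05.
#' @param method Which p-value route calls targets: `"mixture"` (default)
#'   or `"single"`. Both are always computed and reported.
#' @param seed Seed for the randomized EM restarts.
#' @param organism Free-text organism/assembly label for the run summary;
#'   metadata only.
#' @return A list of class `"tip_run"`: `paths` (the five panel files),
#'   `scores` (full score table), `targets`, `peak_hits`, `go`, `fit`,
#'   `config`.
#' @examples
#' genes <- simulate_genome(n_genes = 60, seed = 3)
#' sim <- simulate_track(genes, seed = 3)
#' res <- tip_run(sim$track, genes, out_dir = tempfile(), half_width = 2000)
#' nrow(res$targets)
#' @export
tip_run <- function(track, annotation, out_dir, peaks = NULL, gmt = NULL,
                    half_width = 10000, fdr_threshold = 0.05,
                    go_p_threshold = 0.05, method = c("mixture", "single"),
                    seed = 1, organism = NA_character_) {
  method <- match.arg(method)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, go_p_threshold > 0, go_p_threshold < 1)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  genes <- with_stage("annotation", {
    if (is.character(annotation)) {
      if (grepl("\\.bed(\\.gz)?$", annotation)) read_bed_genes(annotation) else read_refgene(annotation)
    } else {
      assert_genes(annotation)
    }
  })
  track <- with_stage("signal", {
    if (is.character(track)) read_track(track) else assert_track(track)
  })
  shared <- intersect(unique(genes$chrom), unique(track$chrom))
  if (length(shared) == 0L) {
    abort(sprintf(
      "no chromosome shared between track (%s) and annotation (%s): likely a naming mismatch",
      paste(head(sort(unique(track$chrom)), 5), collapse = ","),
      paste(head(sort(unique(genes$chrom)), 5), collapse = ",")
    ))
  }
  peaks <- if (is.character(peaks)) with_stage("peaks", read_narrowpeak(peaks)) else peaks
  gmt <- if (is.character(gmt)) with_stage("go", read_gmt(gmt)) else gmt

  scores <- with_stage("scoring", tip_score(track, genes, half_width))
  profile <- attr(scores, "profile")
  scored <- with_stage("significance",
                       score_significance(scores, fdr_threshold, seed = seed))
  fit <- attr(scored, "fit")
  targets <- call_targets(scored, fdr_threshold, method)
  peak_hits <- if (!is.null(peaks)) {
    with_stage("peak annotation",
               annotate_peaks(peaks, targets, genes, half_width, track))
  }
  go <- if (!is.null(gmt)) {
    with_stage("go", go_enrichment(targets$gene_symbol, scored$gene_symbol,
                                   gmt, p_threshold = go_p_threshold))
  }

  config <- list(
    half_width = half_width, fdr_threshold = fdr_threshold,
    go_p_threshold = go_p_threshold, method = method, seed = seed,
    organism = organism,
    has_peaks = !is.null(peaks), has_gmt = !is.null(gmt)
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_panels(out_dir, config, genes, profile, scored, fit,
                        targets, peak_hits, go)
  write_run_cache(out_dir, config, genes, track, scored, profile, fit, peaks, gmt)

  structure(
    list(paths = paths, scores = scored, targets = targets,
         peak_hits = peak_hits, go = go, fit = fit, profile = profile,
         config = config),
    class = "tip_run"
  )
}

#' Re-threshold a cached run without recomputation
#'
#' Reloads the score table and mixture fit cached by [tip_run()] and
#' recomputes only what the new thresholds touch: target flags, the target
#' table, peak-summit annotation for the new target set, and GO
#' enrichment. Scores, z-scores and the mixture fit are reused untouched.
#' Calling it with the original thresholds reproduces the original panels.
#'
#' @param out_dir The output directory of a prior [tip_run()].
#' @param fdr_threshold New FDR threshold (default: the cached one).
#' @param go_p_threshold New GO p-value threshold (default: the cached one).
#' @param method New target-calling route (default: the cached one).
#' @return A `"tip_run"` list, as from [tip_run()].
#' @export
tip_rethreshold <- function(out_dir, fdr_threshold = NULL, go_p_threshold = NULL,
                            method = NULL) {
  cache <- file.path(out_dir, "cache")
  if (!file.exists(file.path(cache, "config.json"))) {
    abort(sprintf("no cached run under '%s'; run tip_run() first", out_dir))
  }
  config <- jsonlite::read_json(file.path(cache, "config.json"), simplifyVector = TRUE)
  config$organism <- scalar_chr(config$organism) # NA round-trips as JSON null
  config$fdr_threshold <- fdr_threshold %||% config$fdr_threshold
  config$go_p_threshold <- go_p_threshold %||% config$go_p_threshold
  config$method <- method %||% config$method

  scored <- readr::read_tsv(file.path(cache, "scores.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  genes <- readr::read_tsv(file.path(cache, "genes.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  profile <- readr::read_tsv(file.path(cache, "profile.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  class(profile) <- c("binding_profile", class(profile))
  fit <- jsonlite::read_json(file.path(cache, "fit.json"), simplifyVector = TRUE)
  fit$z <- scored$zscore
  class(fit) <- "gmm2"
  track <- if (file.exists(file.path(cache, "track.bedgraph.gz"))) {
    suppressWarnings(read_bedgraph(file.path(cache, "track.bedgraph.gz")))
  }
  peaks <- if (file.exists(file.path(cache, "peaks.tsv"))) {
    readr::read_tsv(file.path(cache, "peaks.tsv"), show_col_types = FALSE, progress = FALSE)
  }
  gmt <- if (file.exists(file.path(cache, "gmt.tsv"))) {
    readr::read_tsv(file.path(cache, "gmt.tsv"), show_col_types = FALSE, progress = FALSE)
  }

  # only flags and downstream annotations move with the thresholds
  scored$is_target_single <- scored$fdr_single < config$fdr_threshold
  scored$is_target_mixture <- scored$fdr_mixture < config$fdr_threshold
  attr(scored, "fit") <- fit
  targets <- call_targets(scored, config$fdr_threshold, config$method)
  peak_hits <- if (!is.null(peaks)) {
    annotate_peaks(peaks, targets, genes, config$half_width, track)
  }
  go <- if (!is.null(gmt)) {
    go_enrichment(targets$gene_symbol, scored$gene_symbol, gmt,
                  p_threshold = config$go_p_threshold)
  }
  paths <- write_panels(out_dir, config, genes, profile, scored, fit,
                        targets, peak_hits, go)
  jsonlite::write_json(config, file.path(cache, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(
    list(paths = paths, scores = scored, targets = targets,
         peak_hits = peak_hits, go = go, fit = fit, profile = profile,
         config = config),
    class = "tip_run"
  )
}

#' @export
print.tip_run <- function(x, ...) {
  cat("TIP target-identification run\n")
  cat(sprintf("  transcripts scored: %d\n", nrow(x$scores)))
  cat(sprintf("  targets (%s, FDR < %g): %d\n", x$config$method,
              x$config$fdr_threshold, nrow(x$targets)))
  if (!is.null(x$go)) cat(sprintf("  enriched GO terms (p < %g): %d\n",
                                  x$config$go_p_threshold, nrow(x$go)))
  cat("  panel files:\n")
  for (p in x$paths) cat("   ", p, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scalar_chr <- function(x) {
  x <- unlist(x, use.names = FALSE)
  if (length(x) == 0L) NA_character_ else as.character(x)[1]
}

# fixed-precision panel formatting keeps re-runs byte-identical
fmt_num_cols <- function(df, digits = 6) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf(paste0("%.", digits, "g"), df[[nm]])
  }
  df
}

write_panel <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

write_panels <- function(out_dir, config, genes, profile, scored, fit,
                         targets, peak_hits, go) {
  paths <- setNames(file.path(out_dir, PANEL_FILES), names(PANEL_FILES))

  summary_tbl <- tibble(
    parameter = c("organism", "n_transcripts", "n_chromosomes", "half_width_bp",
                  "fdr_threshold", "go_p_threshold", "method", "seed",
                  "n_targets", "mixture_background_mean", "mixture_background_sd",
                  "mixture_background_weight", "mixture_converged"),
    value = c(
      scalar_chr(config$organism), as.character(nrow(scored)),
      as.character(length(unique(genes$chrom))), as.character(config$half_width),
      as.character(config$fdr_threshold), as.character(config$go_p_threshold),
      config$method, as.character(config$seed), as.character(nrow(targets)),
      sprintf("%.6g", fit$mu[1]), sprintf("%.6g", fit$sigma[1]),
      sprintf("%.6g", fit$w[1]), as.character(fit$converged)
    )
  )
  write_panel(summary_tbl, paths["summary"])
  write_panel(fmt_num_cols(as_tibble(profile)), paths["profile"])

  h <- graphics::hist(scored$zscore, breaks = 50, plot = FALSE)
  density_tbl <- tibble(
    z = h$mids,
    hist_density = h$density,
    density_background = fit$w[1] * dnorm(h$mids, fit$mu[1], fit$sigma[1]),
    density_target = fit$w[2] * dnorm(h$mids, fit$mu[2], fit$sigma[2]),
    density_mixture = gmm2_density(fit, h$mids)
  )
  write_panel(fmt_num_cols(density_tbl), paths["density"])

  target_tbl <- targets %>%
    select(any_of(c("transcript_id", "gene_symbol", "chrom", "strand", "tss",
                    "score", "zscore", "p_mixture", "fdr_mixture",
                    "p_single", "fdr_single")))
  if (!is.null(peak_hits) && nrow(peak_hits) > 0) {
    primary <- peak_hits %>%
      filter(.data$is_primary) %>%
      select("transcript_id", "summit_from_tss", "peak_height")
    target_tbl <- left_join(target_tbl, primary, by = "transcript_id")
  }
  write_panel(fmt_num_cols(target_tbl), paths["targets"])

  if (!is.null(go)) {
    write_panel(fmt_num_cols(go), paths["go"])
  } else {
    writeLines(c("# GO enrichment not computed: no GMT annotation was provided",
                 "term_id\tterm_name\tterm_size\tn_term\tn_overlap\tp_value\tp_adjusted\toverlapping_genes"),
               paths["go"])
  }
  paths
}

write_run_cache <- function(out_dir, config, genes, track, scored, profile, fit, peaks, gmt) {
  cache <- file.path(out_dir, "cache")
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  full <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
    df
  }
  readr::write_tsv(full(as_tibble(scored)), file.path(cache, "scores.tsv"), progress = FALSE)
  readr::write_tsv(genes, file.path(cache, "genes.tsv"), progress = FALSE)
  readr::write_tsv(full(as_tibble(profile)), file.path(cache, "profile.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(w = fit$w, mu = fit$mu, sigma = fit$sigma, loglik = fit$loglik,
         loglik_trace = fit$loglik_trace, n_iter = fit$n_iter,
         converged = fit$converged, degenerate = isTRUE(fit$degenerate), n = fit$n),
    file.path(cache, "fit.json"), digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(config, file.path(cache, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_bedgraph(track, file.path(cache, "track.bedgraph.gz"))
  if (!is.null(peaks)) readr::write_tsv(peaks, file.path(cache, "peaks.tsv"), progress = FALSE)
  if (!is.null(gmt)) readr::write_tsv(gmt, file.path(cache, "gmt.tsv"), progress = FALSE)
  invisible(cache)
}
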