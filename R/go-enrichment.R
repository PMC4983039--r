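# GO enrichment of called targets against the scored gene universe:
# one-sided hypergeometric (Fisher exact) test per term, with general terms
# (>= 1000 annotated genes) excluded up front.

#' Read a GMT gene-set file
#'
#' One term per line: `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate genes within a line are counted once; lines with fewer than 3
#' columns are skipped with a warning.
#'
#' @param path Path to a GMT file (plain or gzipped).
#' @return A long tibble with columns `term_id`, `term_name`,
#'   `gene_symbol` (one row per term-gene pair, symbols uppercased).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    warn(sprintf("%d GMT line(s) with fewer than 3 columns skipped", sum(short)))
    fields <- fields[!short]
  }
  if (length(fields) == 0L) {
    return(tibble(term_id = character(), term_name = character(), gene_symbol = character()))
  }
  purrr::map_dfr(fields, function(f) {
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[genes != ""]
    tibble(term_id = f[1], term_name = f[2], gene_symbol = genes)
  })
}

#' Hypergeometric upper-tail p-value for a gene-set overlap
#'
#' `P(X >= k)` where X is the overlap between a random draw of `n_term`
#' genes from a universe of `n_universe` containing `n_targets` targets —
#' the one-sided Fisher exact test for enrichment.
#'
#' @param k Observed overlap between the term and the target set.
#' @param n_universe Size of the gene universe.
#' @param n_targets Number of target genes in the universe.
#' @param n_term Number of term genes in the universe.
#' @return Upper-tail probability; 1 when `k = 0`.
#' @export
hypergeom_test <- function(k, n_universe, n_targets, n_term) {
  phyper(k - 1, n_targets, n_universe - n_targets, n_term, lower.tail = FALSE)
}

#' GO enrichment of target genes
#'
#' Tests each annotation term for over-representation of the target genes
#' within the scored universe, using the one-sided hypergeometric test.
#' Following the principle that very general terms are uninformative, terms
#' with `max_term_size` (default 1000) or more genes in the annotation —
#' counted annotation-wide, before intersecting with the universe — are
#' excluded. Raw p-values drive the significance threshold; BH-adjusted
#' values are reported alongside for reference.
#'
#' @param targets Character vector of target gene symbols (or a score-table
#'   tibble with a `gene_symbol` column).
#' @param universe Character vector of all scored gene symbols (or a tibble
#'   with `gene_symbol`). Targets outside the universe are dropped.
#' @param annotation Long annotation tibble from [read_gmt()].
#' @param max_term_size Terms with at least this many annotated genes are
#'   excluded (strict `< max_term_size` filter); default 1000.
#' @param p_threshold Only terms with raw `p_value <` this are returned;
#'   default 0.05. Use `Inf` to keep every tested term.
#' @return A tibble sorted by ascending p-value: `term_id`, `term_name`,
#'   `term_size` (annotation-wide), `n_term` (in-universe), `n_overlap`,
#'   `p_value`, `p_adjusted` (BH across all tested terms),
#'   `overlapping_genes` (comma-joined).
#' @export
go_enrichment <- function(targets, universe, annotation, max_term_size = 1000,
                          p_threshold = 0.05) {
  if (is.data.frame(targets)) targets <- targets$gene_symbol
  if (is.data.frame(universe)) universe <- universe$gene_symbol
  universe <- unique(toupper(universe))
  targets <- intersect(unique(toupper(targets)), universe)
  empty <- tibble(
    term_id = character(), term_name = character(), term_size = integer(),
    n_term = integer(), n_overlap = integer(), p_value = numeric(),
    p_adjusted = numeric(), overlapping_genes = character()
  )
  if (length(targets) == 0L || nrow(annotation) == 0L) {
    return(empty)
  }
  terms <- annotation %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(
      term_size = dplyr::n_distinct(.data$gene_symbol),
      members = list(unique(.data$gene_symbol)),
      .groups = "drop"
    ) %>%
    filter(.data$term_size < max_term_size)
  if (nrow(terms) == 0L) {
    return(empty)
  }
  res <- terms %>%
    mutate(
      in_universe = purrr::map(.data$members, ~ intersect(.x, universe)),
      n_term = lengths(.data$in_universe),
      overlap = purrr::map(.data$in_universe, ~ intersect(.x, targets)),
      n_overlap = lengths(.data$overlap)
    ) %>%
    filter(.data$n_term > 0L) %>%
    mutate(
      p_value = hypergeom_test(.data$n_overlap, length(universe), length(targets), .data$n_term),
      p_adjusted = bh_fdr(.data$p_value),
      overlapping_genes = purrr::map_chr(.data$overlap, ~ paste(sort(.x), collapse = ","))
    ) %>%
    filter(.data$p_value < p_threshold) %>%
    arrange(.data$p_value, .data$term_id) %>%
    select("term_id", "term_name", "term_size", "n_term", "n_overlap",
           "p_value", "p_adjusted", "overlapping_genes")
  res
}

#' Write a GMT annotation file
#'
#' @param annotation Long tibble (`term_id`, `term_name`, `gene_symbol`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  lines <- annotation %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(genes = paste(unique(.data$gene_symbol), collapse = "\t"), .groups = "drop") %>%
    mutate(line = paste(.data$term_id, .data$term_name, .data$genes, sep = "\t")) %>%
    pull("line")
  writeLines(lines, path)
  invisible(path)
}
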