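# Hypergeometric / EASE term over-representation with Bonferroni control,
# the statistic behind DAVID-style functional enrichment chart reports.

#' One-tailed hypergeometric term test
#'
#' Upper-tail probability of observing at least `k` query members annotated
#' to the term, where `k = |query & term|`, drawing `n = |query|` proteins
#' from a universe of `N` containing `K = |term|` annotated proteins. The
#' `"ease"` variant recomputes the tail after removing one overlap member
#' (k -> k-1, floored at 0) — the conservative EASE score.
#'
#' @param query character vector (must be a subset of `universe`)
#' @param term_members character vector (subset of `universe`)
#' @param universe background accession set
#' @param variant `"fisher"` (exact upper tail) or `"ease"`
#' @return the raw one-tailed p-value
#' @export
term_test <- function(query, term_members, universe,
                      variant = c("fisher", "ease")) {
  variant <- match.arg(variant)
  universe <- unique(universe)
  if (length(universe) == 0) abort("The background universe is empty.")
  query <- unique(query)
  term_members <- unique(term_members)
  if (length(setdiff(query, universe)) > 0) {
    abort("Query contains accessions outside the universe.")
  }
  if (length(setdiff(term_members, universe)) > 0) {
    abort("Term members outside the universe.")
  }
  N <- length(universe)
  K <- length(term_members)
  n <- length(query)
  k <- length(intersect(query, term_members))
  if (variant == "ease") k <- max(k - 1L, 0L)
  # P(X >= k) for X ~ Hypergeometric(N, K, n); exact log-gamma arithmetic
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis
#'
#' Tests every term against the query, applies Bonferroni correction with
#' `m` = number of terms having at least one query member (the chart-report
#' convention; set `correct_over = "all"` to use every annotated term), and
#' reports terms with corrected p below `alpha` carrying at least
#' `min_count` query proteins, sorted by corrected p.
#'
#' @param query character vector of accessions (subset of the universe)
#' @param annotation a `term_map` (see [read_term_map()])
#' @param alpha corrected-p cutoff (default 0.05)
#' @param min_count minimum query proteins per reported term (default 2)
#' @param variant `"ease"` (default, the DAVID-style conservative score) or
#'   `"fisher"`
#' @param correct_over `"overlapping"` (default) or `"all"`
#' @param all_terms return every tested term, not only significant ones
#' @return an `enriched_terms` tibble: `term_id`, `name`, `count`,
#'   `universe_count`, `enrichment_ratio`, `p_raw`, `p_corrected`,
#'   `neg_log10_p_corrected`, `significant`
#' @export
enrich_terms <- function(query, annotation, alpha = 0.05, min_count = 2L,
                         variant = c("ease", "fisher"),
                         correct_over = c("overlapping", "all"),
                         all_terms = FALSE) {
  variant <- match.arg(variant)
  correct_over <- match.arg(correct_over)
  stopifnot(inherits(annotation, "term_map"))
  query <- unique(query)
  universe <- annotation$universe
  members <- split(annotation$annotation$accession, annotation$annotation$term_id)

  res <- purrr::imap_dfr(members, function(acc, id) {
    k <- length(intersect(query, acc))
    tibble(
      term_id = id,
      count = k,
      universe_count = length(unique(acc)),
      p_raw = term_test(query, acc, universe, variant)
    )
  })
  n_q <- length(query)
  N <- length(universe)
  res <- res |>
    dplyr::mutate(enrichment_ratio = (.data$count / n_q) /
                    (.data$universe_count / N))
  m <- if (correct_over == "overlapping") sum(res$count >= 1) else nrow(res)
  m <- max(m, 1L)
  res <- res |>
    dplyr::mutate(
      p_corrected = pmin(1, .data$p_raw * m),
      neg_log10_p_corrected = -log10(.data$p_corrected),
      significant = .data$p_corrected < alpha & .data$count >= min_count
    ) |>
    dplyr::left_join(annotation$term_names, by = "term_id") |>
    dplyr::arrange(.data$p_corrected, .data$term_id) |>
    dplyr::relocate("term_id", "name")
  if (!all_terms) res <- res[res$significant, , drop = FALSE]
  structure(res, class = c("enriched_terms", class(tibble())),
            m_tests = m, alpha = alpha, variant = variant)
}

#' @export
glance.enriched_terms <- function(x, ...) {
  tibble(
    n_terms_reported = nrow(tibble::as_tibble(x)),
    m_tests = attr(x, "m_tests"),
    alpha = attr(x, "alpha"),
    variant = attr(x, "variant")
  )
}

#' Write enriched terms as TSV (count, enrichment, -log10 corrected P)
#' @param x an `enriched_terms` tibble
#' @param path output path
#' @export
write_enriched_terms <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
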