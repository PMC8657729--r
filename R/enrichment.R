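#' Hypergeometric over-representation of a gene list against gene sets
#'
#' For each set the overlap k between the query (size n) and the set's
#' members restricted to the universe (size K, universe size N) is tested
#' with the hypergeometric upper tail P(X >= k). Adjusted p-values
#' (Benjamini-Hochberg) are computed within each namespace, and the
#' enrichment score is -log10 of the adjusted p-value. By default only
#' terms with adjusted p <= `alpha` are returned.
#'
#' @param query Character vector of query gene ids; must be contained in
#'   `universe`.
#' @param sets Gene-set tibble as from [read_gmt()] (`term_id`,
#'   `term_name`, `namespace`, list-column `genes`).
#' @param universe Character vector of background gene ids (e.g. all
#'   orthologs present in every species after mapping).
#' @param alpha Adjusted-p cut-off for the returned table.
#' @param keep_all If `TRUE`, return all tested sets regardless of `alpha`.
#' @return Tibble of class `enrichment_tbl` with columns `term_id`,
#'   `term_name`, `namespace`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `es`,
#'   and list-column `overlap_genes`, sorted by `p_adj` then `p`.
#' @export
hypergeom_enrich <- function(query, sets, universe, alpha = 0.05,
                             keep_all = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  assert_that(length(universe) > 0, "empty universe")
  missing <- setdiff(query, universe)
  assert_that(length(missing) == 0,
              paste0("query gene(s) absent from the universe: ",
                     paste(utils::head(missing, 10), collapse = ", ")))
  assert_that(all(c("term_id", "term_name", "namespace", "genes") %in% names(sets)),
              "sets need term_id, term_name, namespace, genes")
  n_universe <- length(universe)
  n_query <- length(query)
  res <- sets |>
    mutate(
      members = map(.data$genes, ~ intersect(unique(.x), universe)),
      overlap_genes = map(.data$members, ~ sort(intersect(.x, query))),
      K = lengths(.data$members),
      k = lengths(.data$overlap_genes),
      n = n_query, N = n_universe,
      p = hyper_tail_p(.data$k, .data$K, n_query, n_universe)
    ) |>
    group_by(.data$namespace) |>
    mutate(p_adj = benjamini_hochberg(.data$p)) |>
    ungroup() |>
    mutate(es = enrichment_score(.data$p_adj)) |>
    select("term_id", "term_name", "namespace", "k", "K", "n", "N",
           "p", "p_adj", "es", "overlap_genes") |>
    arrange(.data$p_adj, .data$p, desc(.data$k), .data$term_id)
  if (!keep_all) res <- res |> filter(.data$p_adj <= alpha)
  class(res) <- c("enrichment_tbl", class(res))
  res
}

# Upper-tail hypergeometric probability P(X >= k) for an overlap of k
# between a query of size n and a set of size K inside a universe of N.
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment score: -log10 of an adjusted p-value
#'
#' Summaries conventionally print the score rounded to 2 decimals; full
#' precision is retained here. Zero inputs are clamped to the smallest
#' positive representable double (logged) so the score stays finite.
#'
#' @param p_adj Numeric vector of adjusted p-values in (0, 1] (zeros
#'   clamped).
#' @return Nonnegative scores, same length.
#' @export
enrichment_score <- function(p_adj) {
  assert_that(is.numeric(p_adj) && !anyNA(p_adj) &&
                all(p_adj >= 0 & p_adj <= 1),
              "adjusted p-values must lie in [0, 1]")
  zero <- p_adj == 0
  if (any(zero)) {
    xsci_log(sprintf("enrichment_score: clamped %d zero p-value(s) to %.3g",
                     sum(zero), .Machine$double.xmin))
    p_adj[zero] <- .Machine$double.xmin
  }
  -log10(p_adj)
}

#' Top-k most enriched terms per namespace
#'
#' Selects the `k` smallest adjusted p-values within each namespace, ties
#' broken by larger overlap then lexicographic term id. Each row also
#' reports how many (and what share of) query genes fall anywhere in its
#' namespace (`ns_query_genes`, `ns_query_pct`).
#'
#' @param results An `enrichment_tbl` (run with `keep_all = TRUE` if
#'   unfiltered rankings are wanted).
#' @param k Number of terms to keep per namespace.
#' @return Summary tibble.
#' @export
top_k_by_namespace <- function(results, k = 5) {
  assert_that(k >= 1, "k must be >= 1")
  ns_cov <- results |>
    group_by(.data$namespace) |>
    summarise(ns_query_genes = length(unique(unlist(.data$overlap_genes))),
              n_query = dplyr::first(.data$n), .groups = "drop") |>
    mutate(ns_query_pct = 100 * .data$ns_query_genes / .data$n_query) |>
    select("namespace", "ns_query_genes", "ns_query_pct")
  results |>
    group_by(.data$namespace) |>
    arrange(.data$p_adj, desc(.data$k), .data$term_id, .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup() |>
    left_join(ns_cov, by = "namespace")
}
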