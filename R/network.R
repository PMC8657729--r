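#' Filter a protein-interaction edge list and order nodes by degree
#'
#' Keeps edges whose confidence is at least `cutoff` (the conventional
#' "medium confidence" threshold is 0.4, applied inclusively) and, when a
#' query list is given, whose endpoints are both query nodes. Nodes left
#' without any edge (singletons) are removed; the survivors are ordered by
#' descending degree, ties broken lexicographically -- the ordering used by
#' degree-sorted circular layouts.
#'
#' @param edges Edge tibble (`node_a`, `node_b`, `confidence`); self-loops
#'   and duplicate undirected edges are normalized away first.
#' @param cutoff Confidence cut-off in [0, 1]; edges with
#'   `confidence >= cutoff` are kept.
#' @param query_nodes Optional character vector restricting the network to
#'   these nodes.
#' @return Object of class `ppi_network`: a list with `edges` (filtered
#'   tibble) and `nodes` (tibble `node`, `degree`, in layout order).
#' @export
filter_network <- function(edges, cutoff = 0.4, query_nodes = NULL) {
  assert_that(cutoff >= 0 && cutoff <= 1, "cutoff must lie in [0, 1]")
  edges <- normalize_edges(edges)
  kept <- edges |> filter(.data$confidence >= cutoff)
  if (!is.null(query_nodes)) {
    kept <- kept |>
      filter(.data$node_a %in% query_nodes & .data$node_b %in% query_nodes)
  }
  if (nrow(kept) == 0) {
    xsci_log("filter_network: no edges survive the filter")
    return(structure(list(edges = kept,
                          nodes = tibble(node = character(), degree = integer())),
                     class = "ppi_network"))
  }
  nodes <- tibble(node = c(kept$node_a, kept$node_b)) |>
    count(.data$node, name = "degree") |>
    arrange(desc(.data$degree), .data$node)
  structure(list(edges = kept, nodes = nodes), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) x$nodes

#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else 0L)
}
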