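#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   facet_wrap coord_flip labs theme_minimal
NULL

#' Volcano plot of a moderated-t fit
#'
#' @param object A `moderated_t_fit`.
#' @param alpha Adjusted-p level drawn as a horizontal guide.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot moderated_t_fit
#' @export
autoplot.moderated_t_fit <- function(object, alpha = 0.05, ...) {
  tab <- object$table |>
    mutate(significant = .data$p_adj <= alpha)
  ggplot(tab, aes(x = .data$log2fc, y = -log10(.data$p),
                  colour = .data$significant)) +
    geom_point(size = 0.8, alpha = 0.7) +
    labs(title = paste0(object$study_id, " (", object$species, ")"),
         x = "log2 fold-change (injured - control)",
         y = "-log10 p", colour = paste0("p_adj ≤ ", alpha)) +
    theme_minimal()
}

#' Bar chart of enrichment scores by namespace
#'
#' @param object An `enrichment_tbl`.
#' @param k Terms shown per namespace (by smallest adjusted p).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, k = 5, ...) {
  top <- top_k_by_namespace(object, k = k)
  ggplot(top, aes(x = stats::reorder(.data$term_id, .data$es), y = .data$es)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~namespace, scales = "free_y") +
    labs(x = NULL, y = "enrichment score (-log10 adjusted p)") +
    theme_minimal()
}

#' Bar chart of the concordance partition
#'
#' @param object A `concordance_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concordance_tbl
#' @export
autoplot.concordance_tbl <- function(object, ...) {
  cnt <- partition_summary(object)
  df <- tibble(pattern = c("consistent", "opposite_outgroup", "other"),
               n = c(cnt$n_consistent, cnt$n_opposite, cnt$n_other))
  ggplot(df, aes(x = .data$pattern, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "significant orthologs",
         title = sprintf("%d significant orthologs", cnt$n_significant)) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
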