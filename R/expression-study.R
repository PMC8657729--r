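#' Construct an expression study
#'
#' Bundles one study's log2-scale expression matrix (probesets x samples)
#' with its sample group labels, species tag, and an optional
#' probeset-to-gene annotation. Values are assumed already normalized
#' (RMA/gcRMA-style log2 intensities); no normalization is performed here.
#'
#' @param matrix Numeric matrix of log2 intensities, probesets in rows
#'   (unique rownames required), samples in columns (colnames required).
#' @param sample_groups Character vector of `"injured"`/`"control"` labels,
#'   one per column of `matrix` (optionally named by sample).
#' @param study_id Study identifier.
#' @param species One of `"rat"`, `"mouse"`, `"salamander"`, `"other"`.
#' @param probeset_to_gene Optional tibble with columns `probeset_id`,
#'   `gene_symbol` annotating (a subset of) the probesets.
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, sample_groups, study_id, species,
                             probeset_to_gene = NULL) {
  assert_that(is.matrix(matrix) && is.numeric(matrix),
              "`matrix` must be a numeric matrix")
  assert_that(all(is.finite(matrix)), "expression values must all be finite")
  assert_that(!is.null(rownames(matrix)) && !is.null(colnames(matrix)),
              "`matrix` needs probeset rownames and sample colnames")
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  assert_that(length(dup) == 0,
              paste0("duplicated probeset id(s): ",
                     paste(unique(dup), collapse = ", ")))
  sample_groups <- unname(as.character(sample_groups))
  assert_that(length(sample_groups) == ncol(matrix),
              "one group label per sample is required")
  assert_that(all(sample_groups %in% c("injured", "control")) &&
                !anyNA(sample_groups),
              "group labels must be 'injured' or 'control', no missing")
  tab <- table(sample_groups)
  assert_that(length(tab) == 2 && all(tab >= 2),
              "at least 2 samples per arm are required (variance undefined otherwise)")
  species <- match.arg(species, c("rat", "mouse", "salamander", "other"))
  if (!is.null(probeset_to_gene)) {
    probeset_to_gene <- as_tibble(probeset_to_gene)
    assert_that(all(c("probeset_id", "gene_symbol") %in% names(probeset_to_gene)),
                "`probeset_to_gene` needs columns probeset_id, gene_symbol")
  }
  structure(
    list(matrix = matrix,
         sample_groups = sample_groups,
         study_id = as.character(study_id),
         species = species,
         probeset_to_gene = probeset_to_gene),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s (%s): %d probesets x %d samples (%d injured / %d control)\n",
              x$study_id, x$species, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_groups == "injured"),
              sum(x$sample_groups == "control")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$matrix)
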