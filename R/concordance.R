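#' Map per-study gene tables onto reference-organism orthologs
#'
#' Resolves every source gene to its rank-1 reference-organism ortholog.
#' Species listed in `chain` are resolved hop-by-hop (e.g. salamander
#' annotations keyed to human orthologs are first mapped to human, then
#' human to the reference), each hop taking the rank-1 candidate. Genes of
#' the reference species itself map to themselves unless the table says
#' otherwise. When two source genes resolve to the same reference gene
#' within one study, the one with the smaller adjusted p-value represents
#' it (ties by source gene id); every collision is logged.
#'
#' @param de_genes Long tibble of per-study gene results with columns
#'   `study_id`, `species`, `gene`, `log2fc`, `p_adj`.
#' @param ortho Ortholog table: `source_species`, `source_gene`,
#'   `reference_gene`, `rank` (see [read_ortholog_map()]).
#' @param reference Reference species (genes already on its symbols pass
#'   through when the table has no entry for them).
#' @param chain Named character vector giving the intermediate species for
#'   chained mappings, e.g. `c(salamander = "human")`.
#' @return Tibble with columns `study_id`, `species`, `ref_gene`,
#'   `source_gene`, `log2fc`, `p_adj`.
#' @export
map_to_reference <- function(de_genes, ortho, reference = "mouse",
                             chain = c(salamander = "human")) {
  assert_that(all(c("study_id", "species", "gene", "log2fc", "p_adj") %in%
                    names(de_genes)),
              "de_genes needs study_id, species, gene, log2fc, p_adj")
  ortho <- validate_ortholog_map(ortho)
  top <- ortho |>
    filter(.data$rank == 1L) |>
    select("source_species", "source_gene", "reference_gene")

  hop <- function(genes, species) {
    m <- top |> filter(.data$source_species == species)
    out <- m$reference_gene[match(genes, m$source_gene)]
    if (species == reference) out[is.na(out)] <- genes[is.na(out)]
    out
  }

  species_in <- unique(de_genes$species)
  for (sp in setdiff(species_in, reference)) {
    mapped <- sp %in% top$source_species
    assert_that(mapped, paste0("species not present in the ortholog map: ", sp))
    if (sp %in% names(chain)) {
      assert_that(chain[[sp]] %in% top$source_species,
                  paste0("missing chain hop '", chain[[sp]], "' for species ", sp))
    }
  }

  mapped <- de_genes |>
    group_by(.data$species) |>
    mutate(ref_gene = {
      sp <- .data$species[1]
      g <- hop(.data$gene, sp)
      if (sp %in% names(chain)) g <- hop(g, chain[[sp]])
      g
    }) |>
    ungroup() |>
    rename(source_gene = "gene")

  n_unmapped <- sum(is.na(mapped$ref_gene))
  if (n_unmapped > 0) {
    xsci_log(sprintf("map_to_reference: dropped %d gene record(s) with no ortholog",
                     n_unmapped))
    mapped <- mapped |> filter(!is.na(.data$ref_gene))
  }

  collided <- mapped |>
    count(.data$study_id, .data$ref_gene) |>
    filter(.data$n > 1)
  if (nrow(collided) > 0) {
    xsci_log(sprintf(
      "map_to_reference: %d reference gene(s) hit by multiple source genes; keeping smallest p_adj (%s)",
      nrow(collided),
      paste(utils::head(paste0(collided$study_id, ":", collided$ref_gene), 5),
            collapse = ", ")))
  }
  mapped |>
    arrange(.data$study_id, .data$ref_gene, .data$p_adj, .data$source_gene) |>
    distinct(.data$study_id, .data$ref_gene, .keep_all = TRUE) |>
    select("study_id", "species", "ref_gene", "source_gene", "log2fc", "p_adj")
}

#' Intersect reference-keyed tables across species and classify directions
#'
#' Applies the two gates in order: an ortholog is retained only if present
#' in every species (species level), and is flagged `significant_all` only
#' if its adjusted p-value is at or below `alpha` in every study (study
#' level; absence from any study fails the flag). Among significant
#' orthologs the direction pattern is
#' \describe{
#'   \item{consistent}{every study shares one nonzero sign of log2fc;}
#'   \item{opposite_outgroup}{all non-outgroup studies share one nonzero
#'     sign and every outgroup study has the opposite nonzero sign;}
#'   \item{other}{anything else, including any zero fold-change (no
#'     direction) or within-species disagreement.}
#' }
#'
#' @param mapped Output of [map_to_reference()].
#' @param outgroup Outgroup species (e.g. `"salamander"`).
#' @param alpha Per-study adjusted-p significance level.
#' @return A tibble of class `concordance_tbl`: one row per retained
#'   ortholog with wide `log2fc_*` / `p_adj_*` columns, `significant_all`,
#'   and `pattern` (`NA` for non-significant records). Partition counts are
#'   logged and available via [partition_summary()].
#' @export
intersect_and_classify <- function(mapped, outgroup, alpha = 0.05) {
  assert_that(all(c("study_id", "species", "ref_gene", "log2fc", "p_adj") %in%
                    names(mapped)),
              "mapped table must carry study_id, species, ref_gene, log2fc, p_adj")
  assert_that(outgroup %in% mapped$species,
              paste0("outgroup species absent from the data: ", outgroup))
  studies <- mapped |> distinct(.data$study_id, .data$species)
  n_species <- dplyr::n_distinct(studies$species)
  n_studies <- nrow(studies)

  kept <- mapped |>
    group_by(.data$ref_gene) |>
    filter(dplyr::n_distinct(.data$species) == n_species) |>
    ungroup()

  records <- kept |>
    group_by(.data$ref_gene) |>
    summarise(
      n_studies_present = dplyr::n(),
      significant_all = dplyr::n() == n_studies && all(.data$p_adj <= alpha),
      pattern = if (dplyr::n() == n_studies && all(.data$p_adj <= alpha)) {
        classify_signs(.data$log2fc, .data$species == .env$outgroup)
      } else NA_character_,
      .groups = "drop"
    )

  wide <- kept |>
    select("ref_gene", "study_id", "log2fc", "p_adj") |>
    pivot_wider(names_from = "study_id", values_from = c("log2fc", "p_adj"))

  out <- records |>
    left_join(wide, by = "ref_gene") |>
    arrange(.data$ref_gene)
  class(out) <- c("concordance_tbl", class(out))
  cnt <- partition_summary(out)
  xsci_log(sprintf(
    "concordance: %d orthologs in all species; %d significant in all studies (%d consistent, %d opposite_outgroup, %d other)",
    nrow(out), cnt$n_significant, cnt$n_consistent, cnt$n_opposite, cnt$n_other))
  out
}

# Direction classification of one significant ortholog given per-study
# fold-changes and an outgroup indicator. Zero fold-change anywhere means
# no direction -> other.
classify_signs <- function(log2fc, is_outgroup) {
  s <- sign(log2fc)
  if (any(s == 0)) return("other")
  if (length(unique(s)) == 1) return("consistent")
  s_in <- unique(s[!is_outgroup])
  s_out <- unique(s[is_outgroup])
  if (length(s_in) == 1 && length(s_out) == 1 && s_in == -s_out) {
    return("opposite_outgroup")
  }
  "other"
}

#' Partition counts of classified concordance records
#'
#' @param records A `concordance_tbl` from [intersect_and_classify()].
#' @return One-row tibble `n_significant`, `n_consistent`, `n_opposite`,
#'   `n_other`; the first always equals the sum of the other three.
#' @export
partition_summary <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(n_significant = 0L, n_consistent = 0L,
                  n_opposite = 0L, n_other = 0L))
  }
  pat <- records$pattern[records$significant_all]
  tibble(
    n_significant = length(pat),
    n_consistent = sum(pat == "consistent"),
    n_opposite = sum(pat == "opposite_outgroup"),
    n_other = sum(pat == "other")
  )
}
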