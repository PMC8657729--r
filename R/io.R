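#' Read an expression study from a TSV file with a YAML sidecar
#'
#' The on-disk dialect is a plain UTF-8 tab-separated table whose first
#' column (`probeset_id`) holds unique probeset identifiers and whose
#' remaining columns are samples, together with a sidecar YAML file (same
#' path with extension `.yaml`) carrying `study_id`, `species`, and the
#' per-sample `groups` map. Study metadata can instead be supplied in
#' `meta`, which overrides the sidecar.
#'
#' @param path Path to the expression TSV.
#' @param meta Optional list with `study_id`, `species`, `groups` (named
#'   character vector sample -> "injured"/"control").
#' @param annotation Optional path to a probeset annotation TSV
#'   (columns `probeset_id`, `gene_symbol`).
#' @return An [expression_study()].
#' @export
read_expression_study <- function(path, meta = NULL, annotation = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  assert_that(length(header) >= 2 && header[1] == "probeset_id",
              "first column must be named 'probeset_id'")
  df <- tryCatch(
    utils::read.delim(path, colClasses = c("character",
                                           rep("numeric", length(header) - 1)),
                      check.names = FALSE, fill = FALSE),
    error = function(e) rlang::abort(paste0(
      "malformed expression table (ragged rows or non-numeric cells) in ",
      path, ": ", conditionMessage(e))),
    warning = function(w) rlang::abort(paste0(
      "malformed expression table (ragged rows or non-numeric cells) in ",
      path, ": ", conditionMessage(w))))
  assert_that(!anyNA(as.matrix(df[-1])),
              paste0("malformed expression table (missing or non-numeric cells) in ", path))
  dup <- df$probeset_id[duplicated(df$probeset_id)]
  assert_that(length(dup) == 0,
              paste0("duplicated probeset id(s) in ", path, ": ",
                     paste(unique(dup), collapse = ", ")))
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$probeset_id
  if (is.null(meta)) {
    side <- sidecar_path(path)
    assert_that(file.exists(side),
                paste0("missing sidecar metadata file: ", side))
    meta <- yaml::read_yaml(side)
  }
  groups <- unlist(meta$groups)
  assert_that(all(colnames(mat) %in% names(groups)),
              "sidecar groups must label every sample column")
  p2g <- if (!is.null(annotation)) read_annotation(annotation) else NULL
  expression_study(mat, groups[colnames(mat)], meta$study_id, meta$species,
                   probeset_to_gene = p2g)
}

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".yaml")

#' Write an expression study (TSV + YAML sidecar)
#'
#' @param study An [expression_study()].
#' @param path Output TSV path; the sidecar goes next to it as `.yaml`.
#' @return `path`, invisibly.
#' @export
write_expression_study <- function(study, path) {
  df <- tibble(probeset_id = rownames(study$matrix)) |>
    dplyr::bind_cols(as_tibble(study$matrix))
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(study_id = study$study_id,
               species = study$species,
               groups = as.list(stats::setNames(study$sample_groups,
                                                colnames(study$matrix))))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read / write a probeset annotation table
#'
#' Two-column TSV: `probeset_id`, `gene_symbol`. Symbols are treated
#' case-sensitively; harmonization to the reference organism's casing is
#' the concordance stage's job.
#' @param path File path.
#' @return Tibble with columns `probeset_id`, `gene_symbol`.
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  assert_that(all(c("probeset_id", "gene_symbol") %in% names(df)),
              "annotation needs columns probeset_id, gene_symbol")
  df
}

#' @rdname read_annotation
#' @param annotation Tibble to write.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[c("probeset_id", "gene_symbol")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write an ortholog mapping table
#'
#' TSV with columns `source_species`, `source_gene`, `reference_gene`,
#' `rank`. Ranks must start at 1 and be unique within each
#' (species, source gene); chained species (e.g. salamander -> human ->
#' mouse) appear as two hops in the same table.
#' @param path File path.
#' @return Tibble.
#' @export
read_ortholog_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccci", progress = FALSE)
  validate_ortholog_map(df)
}

#' @rdname read_ortholog_map
#' @param ortho Tibble to write.
#' @export
write_ortholog_map <- function(ortho, path) {
  readr::write_tsv(ortho, path, progress = FALSE)
  invisible(path)
}

validate_ortholog_map <- function(df) {
  assert_that(all(c("source_species", "source_gene", "reference_gene", "rank")
                  %in% names(df)),
              "ortholog map needs source_species, source_gene, reference_gene, rank")
  bad <- df |>
    group_by(.data$source_species, .data$source_gene) |>
    summarise(ok = min(.data$rank) == 1L && !anyDuplicated(.data$rank),
              .groups = "drop") |>
    filter(!.data$ok)
  assert_that(nrow(bad) == 0,
              "ortholog ranks must start at 1 and be unique per source gene")
  as_tibble(df)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `term_id`, description,
#' then member gene ids. Blank lines are skipped (with a logged count).
#'
#' @param path GMT file path.
#' @param namespace Collection namespace, one of `"GO:MF"`, `"GO:BP"`,
#'   `"GO:CC"`, `"KEGG"`.
#' @return Tibble with columns `term_id`, `term_name`, `namespace`, and a
#'   list-column `genes` (unique member ids per set).
#' @export
read_gmt <- function(path, namespace = c("GO:BP", "GO:MF", "GO:CC", "KEGG")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) xsci_log(sprintf("read_gmt: skipped %d blank line(s)", sum(blank)))
  lines <- lines[!blank]
  assert_that(length(lines) > 0, "GMT file has no sets")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  assert_that(length(bad) == 0,
              paste0("GMT set(s) with zero members at line(s): ",
                     paste(bad, collapse = ", ")))
  tibble(
    term_id = map_chr(parts, 1),
    term_name = map_chr(parts, 2),
    namespace = namespace,
    genes = map(parts, ~ unique(.x[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param sets Tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets[c("term_id", "term_name", "genes")],
                           function(term_id, term_name, genes) {
                             paste(c(term_id, term_name, genes), collapse = "\t")
                           })
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an aligned amino-acid FASTA
#'
#' Records must be pre-aligned (equal lengths, >= 2 taxa) over the 20
#' amino-acid letters plus gap `-` and ambiguity `X`; case is normalized
#' to upper. Alignment construction itself is out of scope: aligned input
#' is accepted as produced by any MSA tool.
#'
#' @param path FASTA path.
#' @return A named character vector of class `aa_alignment`.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  aa_alignment(stats::setNames(as.character(set), names(set)))
}

#' @rdname read_aligned_fasta
#' @param aln An `aa_alignment`.
#' @export
write_aligned_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(aln)), path)
  invisible(path)
}

#' Construct an aligned amino-acid sequence set
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return A named character vector of class `aa_alignment`.
#' @export
aa_alignment <- function(seqs) {
  assert_that(length(seqs) >= 2, "an alignment needs at least 2 taxa")
  assert_that(!is.null(names(seqs)) && all(nzchar(names(seqs))),
              "all sequences must be named")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  assert_that(length(unique(lens)) == 1,
              paste0("aligned sequences must have equal lengths; got: ",
                     paste(unique(lens), collapse = ", ")))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX-]*$", seqs)
  assert_that(all(ok),
              paste0("illegal residue characters in: ",
                     paste(names(seqs)[!ok], collapse = ", ")))
  structure(seqs, class = "aa_alignment")
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d taxa x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

#' Read / write a confidence-scored protein-interaction edge list
#'
#' TSV with columns `node_a`, `node_b`, `confidence` (in [0, 1]).
#' Self-loops are dropped and duplicate undirected edges collapsed to
#' their maximum confidence at read time, each with a logged count.
#'
#' @param path File path.
#' @return Tibble with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edges <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  normalize_edges(df)
}

#' @rdname read_edges
#' @param edges Edge tibble to write.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

normalize_edges <- function(edges) {
  edges <- as_tibble(edges)
  assert_that(all(c("node_a", "node_b", "confidence") %in% names(edges)),
              "edge list needs columns node_a, node_b, confidence")
  assert_that(all(edges$confidence >= 0 & edges$confidence <= 1),
              "confidence scores must lie in [0, 1]")
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    xsci_log(sprintf("edges: dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, ]
  }
  # canonical undirected orientation, then collapse duplicates to max
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges$node_a <- a
  edges$node_b <- b
  n_before <- nrow(edges)
  edges <- edges |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(confidence = max(.data$confidence), .groups = "drop")
  if (nrow(edges) < n_before) {
    xsci_log(sprintf("edges: collapsed %d duplicate undirected edge(s) to max confidence",
                     n_before - nrow(edges)))
  }
  edges
}

#' Read / write an 8-bit grayscale image (PNG or TIFF)
#'
#' Images are handled as numeric matrices with intensities in [0, 1].
#' Multi-channel input is rejected.
#'
#' @param path Image path; format chosen by extension (.png/.tif/.tiff).
#' @return Numeric matrix in [0, 1].
#' @export
read_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    rlang::abort(paste0("unsupported image extension: ", ext))
  )
  assert_that(length(dim(img)) == 2, "a single-channel grayscale image is required")
  img
}

#' @rdname read_grayscale
#' @param img Numeric matrix in [0, 1].
#' @export
write_grayscale <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(unclass(img), 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    rlang::abort(paste0("unsupported image extension: ", ext))
  )
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are written with 6 significant digits.
#' @param tree An ape `phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
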