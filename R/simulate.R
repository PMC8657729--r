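#' Simulation configuration for multi-species injury studies
#'
#' Describes a planted-truth simulation emulating a set of cross-compatible
#' microarray studies: two rat studies, one mouse study, and one salamander
#' study at the early subacute time point, each with a small number of
#' replicates per arm. Defaults mirror that design (rat 4/4, rat 3/3,
#' mouse 3/3, salamander 3/3).
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param n_genes Number of reference-organism genes to simulate.
#' @param species_plan Tibble with columns `study_id`, `species`,
#'   `n_injured`, `n_control` (one row per study).
#' @param frac_consistent Proportion of genes planted with the same
#'   direction of injury response in every species.
#' @param frac_opposite Proportion planted with the rodent direction
#'   flipped in the salamander (outgroup) study.
#' @param effect_log2fc Planted injury effect magnitude, log2 units.
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param probeset_choices Possible probesets-per-gene counts (sampled
#'   uniformly per gene per study).
#' @param ortholog_dropout Per-species (and, for the chained salamander
#'   mapping, per-hop) probability that a gene is missing from the
#'   ortholog table. Default 0 keeps planted truth fully recoverable.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 500,
                              species_plan = default_species_plan(),
                              frac_consistent = 0.1,
                              frac_opposite = 0.1,
                              effect_log2fc = 2,
                              noise_sd = 0.5,
                              probeset_choices = 1:3,
                              ortholog_dropout = 0) {
  species_plan <- as_tibble(species_plan)
  assert_that(all(c("study_id", "species", "n_injured", "n_control") %in%
                    names(species_plan)),
              "species_plan needs study_id, species, n_injured, n_control")
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(frac_consistent >= 0 && frac_opposite >= 0 &&
                frac_consistent + frac_opposite <= 1,
              "frac_consistent + frac_opposite must be <= 1")
  assert_that(all(species_plan$n_injured >= 2) && all(species_plan$n_control >= 2),
              "fewer than 2 samples per arm: variance undefined")
  assert_that(all(probeset_choices >= 1), "probeset counts must be >= 1")
  assert_that(ortholog_dropout >= 0 && ortholog_dropout < 1,
              "ortholog_dropout must be in [0, 1)")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 species_plan = species_plan,
                 frac_consistent = frac_consistent,
                 frac_opposite = frac_opposite,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 probeset_choices = as.integer(probeset_choices),
                 ortholog_dropout = ortholog_dropout),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_species_plan <- function() {
  tibble(
    study_id = c("rat_a", "rat_b", "mouse_a", "sal_a"),
    species = c("rat", "rat", "mouse", "salamander"),
    n_injured = c(4L, 3L, 3L, 3L),
    n_control = c(4L, 3L, 3L, 3L)
  )
}

#' Simulate multi-species injury studies with planted structure
#'
#' Generates one [expression_study()] per row of the species plan. A
#' planted-consistent gene receives `+effect_log2fc` in the injured arm of
#' every study; a planted-opposite gene receives the effect in rodent
#' studies and its negative in salamander studies; null genes receive
#' nothing. Each gene gets 1-3 probesets per study sharing the gene signal
#' plus independent Gaussian noise; one probeset per gene carries an
#' elevated baseline so the highest-average-expression collapsing rule has
#' a deterministic winner. A chained ortholog table (salamander -> human ->
#' mouse; rat -> mouse; mouse identity) is emitted alongside, with
#' optional per-hop dropout and rank-2 decoy candidates exercising the
#' rank-1 rule. A planted gene-set collection for enrichment testing is
#' also returned.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `studies` (list of `expression_study`),
#'   `truth` (planted gene classes, winners, enriched sets),
#'   `ortholog_map` (tibble), and `gene_sets` (GMT-style tibble).
#' @export
simulate_studies <- function(config) {
  assert_that(inherits(config, "simulation_config"),
              "`config` must be a simulation_config")
  withr::with_seed(config$seed, simulate_studies_impl(config))
}

simulate_studies_impl <- function(config) {
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  n_cons <- round(config$frac_consistent * n)
  n_opp <- round(config$frac_opposite * n)
  cls <- rep("null", n)
  idx <- sample.int(n)
  cls[idx[seq_len(n_cons)]] <- "consistent"
  if (n_opp > 0) cls[idx[n_cons + seq_len(n_opp)]] <- "opposite"
  names(cls) <- genes

  plan <- config$species_plan
  src_gene <- function(species, g) {
    switch(species,
           mouse = g,
           rat = paste0("r", g),
           salamander = paste0("s", g),
           paste0("o", g))
  }

  # ortholog table: rat -> mouse direct; salamander chained via human.
  keep <- function() stats::runif(n) >= config$ortholog_dropout
  ortho <- list()
  for (sp in setdiff(unique(plan$species), "mouse")) {
    if (sp == "salamander") {
      k1 <- keep(); k2 <- keep()
      ortho[[length(ortho) + 1]] <- tibble(
        source_species = "salamander",
        source_gene = vapply(genes, src_gene, "", species = "salamander")[k1],
        reference_gene = paste0("h", genes)[k1], rank = 1L)
      ortho[[length(ortho) + 1]] <- tibble(
        source_species = "human",
        source_gene = paste0("h", genes)[k2],
        reference_gene = genes[k2], rank = 1L)
    } else {
      k <- keep()
      ortho[[length(ortho) + 1]] <- tibble(
        source_species = sp,
        source_gene = vapply(genes, src_gene, "", species = sp)[k],
        reference_gene = genes[k], rank = 1L)
    }
  }
  ortho <- dplyr::bind_rows(ortho)
  # rank-2 decoys for ~20% of direct entries: the rank-1 rule must win.
  decoy_pool <- ortho |> filter(.data$rank == 1L)
  n_decoy <- floor(nrow(decoy_pool) * 0.2)
  if (n_decoy > 0) {
    di <- sample.int(nrow(decoy_pool), n_decoy)
    decoys <- decoy_pool[di, ]
    decoys$reference_gene <- paste0("DECOY_", decoys$reference_gene)
    decoys$rank <- 2L
    ortho <- dplyr::bind_rows(ortho, decoys) |>
      arrange(.data$source_species, .data$source_gene, .data$rank)
  }

  studies <- vector("list", nrow(plan))
  winners <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    sg <- vapply(genes, src_gene, "", species = row$species)
    n_ps <- sample(config$probeset_choices, n, replace = TRUE)
    gene_of_ps <- rep(seq_len(n), n_ps)
    ps_rank <- sequence(n_ps)
    ps_id <- sprintf("%s_ps%d", sg[gene_of_ps], ps_rank)
    # the planted collapse winner is each gene's first probeset (+2 baseline)
    baseline <- stats::runif(n, 5, 10)[gene_of_ps] + ifelse(ps_rank == 1L, 2, 0)
    ns <- row$n_injured + row$n_control
    grp <- c(rep("injured", row$n_injured), rep("control", row$n_control))
    eff <- switch(row$species,
                  salamander = ifelse(cls == "consistent", config$effect_log2fc,
                               ifelse(cls == "opposite", -config$effect_log2fc, 0)),
                  ifelse(cls %in% c("consistent", "opposite"),
                         config$effect_log2fc, 0))
    mu <- outer(baseline, rep(1, ns)) +
      outer(eff[gene_of_ps], as.numeric(grp == "injured"))
    mat <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow(mu))
    dimnames(mat) <- list(ps_id, sprintf("%s_s%02d", row$study_id, seq_len(ns)))
    annot <- tibble(probeset_id = ps_id, gene_symbol = sg[gene_of_ps])
    studies[[i]] <- expression_study(mat, grp, row$study_id, row$species,
                                     probeset_to_gene = annot)
    winners[[row$study_id]] <- tibble(gene_symbol = sg,
                                      probeset_id = sprintf("%s_ps1", sg))
  }
  names(studies) <- plan$study_id

  truth <- list(
    consistent_genes = genes[cls == "consistent"],
    opposite_genes = genes[cls == "opposite"],
    null_genes = genes[cls == "null"],
    collapse_winners = winners
  )
  gs <- simulate_gene_sets_impl(genes, truth)
  truth$enriched_sets <- gs$planted
  list(studies = studies, truth = truth, ortholog_map = ortho,
       gene_sets = gs$sets)
}

# Planted GMT-style collection: one set covering 80% of each planted class
# plus random null sets over all genes.
simulate_gene_sets_impl <- function(genes, truth, n_null_sets = 30,
                                    null_size = 25) {
  planted <- list()
  rows <- list()
  for (class in c("consistent", "opposite")) {
    members <- truth[[paste0(class, "_genes")]]
    if (length(members) >= 2) {
      sel <- sort(sample(members, max(2, round(0.8 * length(members)))))
      id <- paste0("PLANTED_", toupper(class))
      planted[[id]] <- sel
      rows[[id]] <- tibble(term_id = id,
                           term_name = paste("planted", class, "set"),
                           namespace = "GO:BP", genes = list(sel))
    }
  }
  for (j in seq_len(n_null_sets)) {
    id <- sprintf("NULL_%03d", j)
    rows[[id]] <- tibble(term_id = id,
                         term_name = sprintf("random set %d", j),
                         namespace = "GO:BP",
                         genes = list(sort(sample(genes, min(null_size, length(genes))))))
  }
  list(sets = dplyr::bind_rows(rows), planted = planted)
}

#' Write every artifact of a simulation to a directory
#'
#' Emits per-study expression TSV + YAML sidecars and annotation TSVs,
#' the ortholog TSV, the gene-set GMT, and a JSON truth file recording the
#' planted classes and the seed.
#'
#' @param sim Result of [simulate_studies()].
#' @param dir Output directory (created if missing).
#' @param seed Seed to record in the truth file.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in sim$studies) {
    write_expression_study(st, file.path(dir, paste0(st$study_id, ".tsv")))
    write_annotation(st$probeset_to_gene,
                     file.path(dir, paste0(st$study_id, "_annot.tsv")))
  }
  write_ortholog_map(sim$ortholog_map, file.path(dir, "orthologs.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- sim$truth
  truth$collapse_winners <- NULL
  jsonlite::write_json(c(list(seed = seed), truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate an amino-acid alignment along a tree
#'
#' Evolves i.i.d. Poisson substitution processes over the sites of a root
#' sequence along each branch of a Newick tree: per site the number of
#' substitution events on a branch of length b (times `subst_rate`) is
#' Poisson(b * rate), each event replacing the residue with a uniformly
#' chosen different residue. No indels, so the result is trivially
#' column-complete.
#'
#' @param tree_newick Newick string with branch lengths (zero allowed,
#'   negative rejected).
#' @param n_sites Number of alignment columns (>= 1).
#' @param subst_rate Expected substitutions per site per branch-length unit.
#' @param seed Integer seed.
#' @return An `aa_alignment` over the tree's tips.
#' @export
simulate_alignment <- function(tree_newick, n_sites, subst_rate = 1, seed) {
  assert_that(n_sites >= 1, "n_sites must be >= 1")
  tree <- tryCatch(ape::read.tree(text = tree_newick),
                   error = function(e) NULL, warning = function(w) NULL)
  assert_that(!is.null(tree) && inherits(tree, "phylo"),
              "malformed Newick input")
  assert_that(!is.null(tree$edge.length), "branch lengths are required")
  assert_that(all(tree$edge.length >= 0), "negative branch length")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(aas, n_sites, replace = TRUE)
    # preorder: parents before children
    ord <- order(tree$edge[, 1])
    for (e in ord) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      s <- seqs[[parent]]
      b <- tree$edge.length[e] * subst_rate
      k <- stats::rpois(n_sites, b)
      while (any(k > 0)) {
        hit <- which(k > 0)
        repl <- sample(aas, length(hit), replace = TRUE)
        # an event must change the residue: redraw collisions
        same <- repl == s[hit]
        while (any(same)) {
          repl[same] <- sample(aas, sum(same), replace = TRUE)
          same <- repl == s[hit]
        }
        s[hit] <- repl
        k[hit] <- k[hit] - 1L
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
    aa_alignment(stats::setNames(out, tree$tip.label))
  })
}

#' Simulate a bimodal grayscale image with a planted foreground fraction
#'
#' Exactly `round(true_fraction * prod(shape))` pixels are drawn at high
#' intensity (uniform on 0.65-0.95) at random positions; the rest are
#' background (uniform on 0.05-0.35). Any threshold between the two bands
#' recovers the planted area fraction exactly.
#'
#' @param shape Integer vector `c(height, width)`.
#' @param true_fraction Planted foreground proportion in [0, 1].
#' @param seed Integer seed.
#' @return Numeric matrix in [0, 1] with attributes `true_fraction` and
#'   `n_foreground`.
#' @export
simulate_image <- function(shape, true_fraction, seed) {
  assert_that(true_fraction >= 0 && true_fraction <= 1,
              "true_fraction must lie in [0, 1]")
  assert_that(length(shape) == 2 && all(shape >= 1),
              "shape must be c(height, width)")
  total <- prod(shape)
  n_fg <- round(true_fraction * total)
  withr::with_seed(seed, {
    img <- matrix(stats::runif(total, 0.05, 0.35), shape[1], shape[2])
    if (n_fg > 0) {
      pos <- sample.int(total, n_fg)
      img[pos] <- stats::runif(n_fg, 0.65, 0.95)
    }
  })
  attr(img, "true_fraction") <- true_fraction
  attr(img, "n_foreground") <- n_fg
  img
}

#' Simulate a confidence-scored interaction edge list
#'
#' Erdos-Renyi-style random edges over the given nodes with uniform
#' confidences, plus an optional hub node connected to every other node at
#' high confidence (emulating a highly connected interactor).
#'
#' @param nodes Character vector of node ids.
#' @param seed Integer seed.
#' @param p_edge Edge probability between non-hub pairs.
#' @param hub Optional node id to wire to all others (confidence 0.7-0.99).
#' @return Edge tibble (`node_a`, `node_b`, `confidence`).
#' @export
simulate_edges <- function(nodes, seed, p_edge = 0.15, hub = NULL) {
  assert_that(length(nodes) >= 2, "need at least 2 nodes")
  withr::with_seed(seed, {
    pairs <- utils::combn(sort(nodes), 2)
    keep <- stats::runif(ncol(pairs)) < p_edge
    edges <- tibble(node_a = pairs[1, keep], node_b = pairs[2, keep],
                    confidence = round(stats::runif(sum(keep)), 3))
    if (!is.null(hub)) {
      others <- setdiff(nodes, hub)
      edges <- dplyr::bind_rows(edges, tibble(
        node_a = pmin(hub, others), node_b = pmax(hub, others),
        confidence = round(stats::runif(length(others), 0.7, 0.99), 3)))
    }
    normalize_edges(edges)
  })
}
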