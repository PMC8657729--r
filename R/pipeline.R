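#' Configuration for an end-to-end pipeline run
#'
#' Either a [simulation_config()] (synthetic run with planted truth) or a
#' `paths` list pointing at on-disk inputs: `studies` (character vector of
#' expression TSVs with YAML sidecars), `annotations` (named by study id,
#' optional when sidecar studies carry annotations), `ortholog_map`, and
#' `gene_sets` (GMT). Validation happens here, before any stage runs.
#'
#' @param sim Optional [simulation_config()].
#' @param paths Optional list of input paths (see above).
#' @param outgroup Outgroup species for the concordance classification.
#' @param reference Reference organism for ortholog harmonization.
#' @param chain Named chain of intermediate species for chained mappings.
#' @param alpha Per-study adjusted-p significance level.
#' @param n_gene_clusters k for the heatmap gene clustering.
#' @param seed Top-level seed; every stage derives a named substream from it.
#' @param output_dir Optional directory for stage outputs and the report.
#' @return A validated `run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL, outgroup = "salamander",
                       reference = "mouse", chain = c(salamander = "human"),
                       alpha = 0.05, n_gene_clusters = 4, seed = 1,
                       output_dir = NULL) {
  assert_that(xor(is.null(sim), is.null(paths)),
              "exactly one of `sim` or `paths` must be given")
  if (!is.null(sim)) {
    assert_that(inherits(sim, "simulation_config"),
                "`sim` must be a simulation_config")
    assert_that(outgroup %in% sim$species_plan$species,
                paste0("outgroup species missing from the study plan: ", outgroup))
  } else {
    assert_that(!is.null(paths$studies) && !is.null(paths$ortholog_map),
                "`paths` needs at least $studies and $ortholog_map")
  }
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(sim = sim, paths = paths, outgroup = outgroup,
                 reference = reference, chain = chain, alpha = alpha,
                 n_gene_clusters = n_gene_clusters, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full cross-species concordance pipeline
#'
#' Stages, in dependency order: (1) simulate or load the studies;
#' (2) per-study moderated-t differential expression and probeset
#' collapsing; (3) ortholog harmonization, species intersection, and
#' direction-pattern classification; (4) hypergeometric enrichment run
#' separately on the consistent and the opposite classes against the
#' universe of orthologs present in every species; (5) sequence
#' conservation (percent identity, Poisson distances, NJ tree) on a
#' supplied or simulated alignment; (6) confidence-filtered interaction
#' network over the significant orthologs; (7) synthetic immunostain
#' quantification with two-way ANOVA (simulated runs only). Every stage's
#' counts and decisions are logged; the run report is written as JSON plus
#' a human-readable text file when `output_dir` is set.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_run` with all stage outputs and the
#'   `report` list.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), class = "xsci_stage_error")
    })
  }

  # -- stage 1: inputs ------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_studies(config$sim))
    studies <- sim$studies
    ortho <- sim$ortholog_map
    gene_sets <- sim$gene_sets
    truth <- sim$truth
    if (!is.null(out_dir)) {
      write_simulation(sim, file.path(out_dir, "inputs"), seed = config$sim$seed)
    }
  } else {
    annots <- config$paths$annotations %||%
      sub("\\.tsv$", "_annot.tsv", config$paths$studies)
    studies <- stage("load", purrr::map2(
      config$paths$studies, annots,
      function(p, a) read_expression_study(p, annotation = a)))
    names(studies) <- vapply(studies, function(s) s$study_id, "")
    ortho <- stage("load", read_ortholog_map(config$paths$ortholog_map))
    gene_sets <- if (!is.null(config$paths$gene_sets)) {
      stage("load", read_gmt(config$paths$gene_sets))
    } else NULL
  }

  # -- stage 2: differential expression ------------------------------------
  de <- stage("diffexpr", {
    lapply(studies, function(st) {
      fit <- fit_moderated_t(st)
      genes <- collapse_probesets(tidy(fit), st$probeset_to_gene)
      list(fit = fit, genes = genes)
    })
  })
  de_long <- purrr::imap(de, function(x, id) {
    sp <- studies[[id]]$species
    x$genes |> mutate(study_id = id, species = sp)
  }) |> dplyr::bind_rows()

  # -- stage 3: concordance -------------------------------------------------
  mapped <- stage("concordance",
    map_to_reference(de_long, ortho, reference = config$reference,
                     chain = config$chain))
  records <- stage("concordance",
    intersect_and_classify(mapped, outgroup = config$outgroup,
                           alpha = config$alpha))
  partition <- partition_summary(records)

  # -- stage 4: enrichment (consistent and opposite classes separately) ----
  universe <- records$ref_gene
  classes <- list(
    consistent = records$ref_gene[which(records$pattern == "consistent")],
    opposite = records$ref_gene[which(records$pattern == "opposite_outgroup")]
  )
  enrich <- NULL
  if (!is.null(gene_sets)) {
    enrich <- stage("enrichment", lapply(classes, function(q) {
      if (length(q) == 0) return(NULL)
      hypergeom_enrich(q, gene_sets, universe)
    }))
  }

  # -- stage 5: conservation ------------------------------------------------
  conservation <- stage("conservation", {
    aln <- if (!is.null(config$paths$alignment)) {
      read_aligned_fasta(config$paths$alignment)
    } else {
      simulate_alignment(sci_model_tree(), n_sites = 1000,
                         seed = derive_seed(config$seed, "alignment"))
    }
    ref_taxon <- if ("human" %in% names(aln)) "human" else names(aln)[1]
    dm <- poisson_distance(aln)
    list(identity = percent_identity(aln, ref_taxon),
         distances = dm, tree = neighbor_joining(dm))
  })

  # -- stage 6: interactome -------------------------------------------------
  network <- stage("interactome", {
    sig <- records$ref_gene[records$significant_all]
    if (length(sig) >= 2) {
      edges <- if (!is.null(config$paths$edges)) read_edges(config$paths$edges)
        else simulate_edges(sig, seed = derive_seed(config$seed, "edges"))
      filter_network(edges, cutoff = 0.4, query_nodes = sig)
    } else NULL
  })

  # -- stage 7: immunostain quantification (synthetic validation arm) ------
  imaging <- NULL
  if (!is.null(config$sim)) {
    imaging <- stage("imaging", simulate_ihc_experiment(
      seed = derive_seed(config$seed, "imaging")))
  }

  report <- build_report(config, studies, de, partition, truth, enrich,
                         conservation, network, imaging)
  run <- structure(list(config = config, studies = studies, de = de,
                        mapped = mapped, records = records,
                        partition = partition, truth = truth,
                        enrichment = enrich, conservation = conservation,
                        network = network, imaging = imaging,
                        report = report),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# Reference topology used for simulated conservation analyses: the species
# commonly compared in spinal-cord-injury work, rooted mammals-vs-amphibia,
# branch lengths in expected substitutions per site.
sci_model_tree <- function() {
  paste0("(((human:0.06,(mouse:0.04,rat:0.04):0.04):0.04,pig:0.10):0.08,",
         "(xenopus:0.16,axolotl:0.16):0.08);")
}

# Synthetic immunostain arm: SCI vs sham animals imaged at four cord
# regions; injury raises the stained fraction in the grey-matter regions.
simulate_ihc_experiment <- function(seed, n_sci = 5, n_sham = 3,
                                    shape = c(64, 64)) {
  regions <- c("DG", "VG", "DW", "VW")
  base <- c(DG = 0.10, VG = 0.10, DW = 0.08, VW = 0.08)
  lift <- c(DG = 0.15, VG = 0.10, DW = 0.03, VW = 0.02)
  plan <- tidyr::expand_grid(
    tibble(group = c(rep("SCI", n_sci), rep("sham", n_sham)),
           animal_id = c(sprintf("sci%02d", seq_len(n_sci)),
                         sprintf("sham%02d", seq_len(n_sham)))),
    region = regions)
  meas <- withr::with_seed(seed, {
    purrr::pmap_dfr(plan, function(group, animal_id, region) {
      f <- base[[region]] + if (group == "SCI") lift[[region]] else 0
      f <- min(max(f + stats::rnorm(1, 0, 0.015), 0.01), 0.99)
      img <- simulate_image(shape, f, seed = sample.int(2^30, 1))
      tibble(animal_id = animal_id, group = group, region = region,
             planted_fraction = f,
             area_fraction = area_fraction(img, threshold = "otsu"))
    })
  })
  list(measurements = meas, anova = two_way_anova_holm_sidak(meas))
}

build_report <- function(config, studies, de, partition, truth, enrich,
                         conservation, network, imaging) {
  truth_cmp <- NULL
  if (!is.null(truth)) {
    truth_cmp <- list(planted_consistent = length(truth$consistent_genes),
                      planted_opposite = length(truth$opposite_genes),
                      recovered_consistent = partition$n_consistent,
                      recovered_opposite = partition$n_opposite)
  }
  list(
    config = list(seed = config$seed, alpha = config$alpha,
                  outgroup = config$outgroup, reference = config$reference,
                  simulated = !is.null(config$sim)),
    studies = lapply(studies, function(s) list(
      study_id = s$study_id, species = s$species,
      n_probesets = nrow(s$matrix),
      n_injured = sum(s$sample_groups == "injured"),
      n_control = sum(s$sample_groups == "control"))),
    diffexpr = lapply(de, function(x) list(
      n_probesets = nrow(x$fit$table), n_genes = nrow(x$genes),
      d0 = x$fit$prior$d0, s0_sq = x$fit$prior$s0_sq)),
    partition = as.list(partition),
    truth_comparison = truth_cmp,
    enrichment = if (!is.null(enrich)) lapply(enrich, function(e) {
      if (is.null(e)) NULL else list(
        n_significant_terms = nrow(e),
        top_term = if (nrow(e)) e$term_id[1] else NA,
        top_es = if (nrow(e)) round(e$es[1], 2) else NA)
    }),
    conservation = list(
      n_taxa = nrow(conservation$identity),
      mean_pct_identity = mean(conservation$identity$pct_identity),
      tree = ape::write.tree(conservation$tree)),
    network = if (!is.null(network)) list(
      n_nodes = nrow(network$nodes), n_edges = nrow(network$edges)),
    imaging = if (!is.null(imaging)) list(
      n_measurements = nrow(imaging$measurements),
      group_p = imaging$anova$anova$p.value[imaging$anova$anova$term == "group"])
  )
}

write_run_outputs <- function(run, out_dir) {
  for (id in names(run$de)) {
    readr::write_csv(run$de[[id]]$genes,
                     file.path(out_dir, paste0("de_", id, ".csv")))
  }
  readr::write_csv(as_tibble(run$records) |>
                     select(-dplyr::any_of("n_studies_present")),
                   file.path(out_dir, "concordance.csv"))
  if (!is.null(run$enrichment)) {
    for (cl in names(run$enrichment)) {
      e <- run$enrichment[[cl]]
      if (!is.null(e)) {
        readr::write_csv(e |> mutate(overlap_genes =
                                       map_chr(.data$overlap_genes, paste, collapse = ";")),
                         file.path(out_dir, paste0("enrichment_", cl, ".csv")))
      }
    }
  }
  readr::write_csv(run$conservation$identity, file.path(out_dir, "pid.csv"))
  write_newick(run$conservation$tree, file.path(out_dir, "tree.nwk"))
  if (!is.null(run$network)) {
    write_edges(run$network$edges, file.path(out_dir, "network_edges.tsv"))
    readr::write_csv(run$network$nodes, file.path(out_dir, "network_nodes.csv"))
  }
  if (!is.null(run$imaging)) {
    readr::write_csv(run$imaging$measurements, file.path(out_dir, "ihc.csv"))
  }
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(run$report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

format_report <- function(rep) {
  c(sprintf("xsci pipeline run (seed %d, alpha %.3g, outgroup %s)",
            rep$config$seed, rep$config$alpha, rep$config$outgroup),
    sprintf("studies: %s", paste(names(rep$studies), collapse = ", ")),
    sprintf("significant orthologs: %d (consistent %d, opposite %d, other %d)",
            rep$partition$n_significant, rep$partition$n_consistent,
            rep$partition$n_opposite, rep$partition$n_other),
    if (!is.null(rep$truth_comparison))
      sprintf("planted: consistent %d, opposite %d",
              rep$truth_comparison$planted_consistent,
              rep$truth_comparison$planted_opposite),
    sprintf("conservation: %d taxa, mean identity %.1f%%",
            rep$conservation$n_taxa, rep$conservation$mean_pct_identity),
    if (!is.null(rep$network))
      sprintf("network: %d nodes, %d edges",
              rep$network$n_nodes, rep$network$n_edges))
}

#' @export
print.pipeline_run <- function(x, ...) {
  writeLines(format_report(x$report))
  invisible(x)
}
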