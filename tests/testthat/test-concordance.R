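test_that("rank-1 orthologs are chosen, directly and through a chain", {
  ortho <- tibble::tibble(
    source_species = c("rat", "rat", "rat", "salamander", "human"),
    source_gene = c("rA", "rB", "rB", "sC", "hC"),
    reference_gene = c("A", "B", "WRONG_B", "hC", "C"),
    rank = c(1L, 1L, 2L, 1L, 1L))
  de <- tibble::tibble(
    study_id = c("r1", "r1", "s1"),
    species = c("rat", "rat", "salamander"),
    gene = c("rA", "rB", "sC"),
    log2fc = c(1, -1, 2), p_adj = c(0.01, 0.02, 0.03))
  out <- map_to_reference(de, ortho)
  expect_equal(out$ref_gene[out$source_gene == "rA"], "A")
  expect_equal(out$ref_gene[out$source_gene == "rB"], "B")   # rank 1 wins
  expect_equal(out$ref_gene[out$source_gene == "sC"], "C")   # via human hop
})

test_that("chained mapping recovers the planted reference for non-dropout genes", {
  cfg <- simulation_config(seed = 31, n_genes = 150, ortholog_dropout = 0.15)
  sim <- suppressMessages(simulate_studies(cfg))
  sal_genes <- paste0("s", sprintf("G%04d", 1:150))
  de <- tibble::tibble(study_id = "sal_a", species = "salamander",
                       gene = sal_genes, log2fc = 1, p_adj = 0.01)
  out <- suppressMessages(map_to_reference(de, sim$ortholog_map))
  # every mapped gene resolves to its own planted reference symbol
  expect_true(all(out$ref_gene == sub("^s", "", out$source_gene)))
  # dropout removes some genes from the chain
  expect_lt(nrow(out), 150)
  # the survivors are exactly those present at both hops of the map
  hop1 <- sim$ortholog_map$source_gene[
    sim$ortholog_map$source_species == "salamander"]
  hop2 <- sim$ortholog_map$source_gene[
    sim$ortholog_map$source_species == "human"]
  expected <- sal_genes[sal_genes %in% hop1 &
                          paste0("h", sub("^s", "", sal_genes)) %in% hop2]
  expect_setequal(out$source_gene, expected)
})

test_that("reference-gene collisions keep the smaller adjusted p", {
  ortho <- tibble::tibble(
    source_species = "rat", source_gene = c("r1", "r2"),
    reference_gene = "A", rank = 1L)
  de <- tibble::tibble(study_id = "r1", species = "rat",
                       gene = c("r1", "r2"),
                       log2fc = c(1, 2), p_adj = c(0.2, 0.01))
  expect_message(out <- map_to_reference(de, ortho), "multiple source genes",
                 class = "xsci_log")
  expect_equal(nrow(out), 1)
  expect_equal(out$source_gene, "r2")
})

test_that("a missing chain hop is an error", {
  ortho <- tibble::tibble(source_species = "salamander", source_gene = "sA",
                          reference_gene = "hA", rank = 1L)
  de <- tibble::tibble(study_id = "s1", species = "salamander",
                       gene = "sA", log2fc = 1, p_adj = 0.01)
  expect_error(map_to_reference(de, ortho), "missing chain hop")
})

test_that("the worked sign patterns classify as defined", {
  # all up across rat1, rat2, mouse, salamander
  rec <- intersect_and_classify(make_mapped_signs(rbind(c(1, 1, 1, 1))),
                                outgroup = "salamander") |>
    suppressMessages()
  expect_equal(rec$pattern, "consistent")
  # rodents up, salamander down
  rec <- intersect_and_classify(make_mapped_signs(rbind(c(1, 1, 1, -1))),
                                outgroup = "salamander") |>
    suppressMessages()
  expect_equal(rec$pattern, "opposite_outgroup")
  # rat studies disagree
  rec <- intersect_and_classify(make_mapped_signs(rbind(c(1, -1, 1, -1))),
                                outgroup = "salamander") |>
    suppressMessages()
  expect_equal(rec$pattern, "other")
})

test_that("all 16 sign patterns partition into 2 consistent, 2 opposite, 12 other", {
  rec <- suppressMessages(
    intersect_and_classify(make_mapped_signs(all_sign_patterns()),
                           outgroup = "salamander"))
  cnt <- partition_summary(rec)
  expect_equal(cnt$n_significant, 16L)
  expect_equal(cnt$n_consistent, 2L)
  expect_equal(cnt$n_opposite, 2L)
  expect_equal(cnt$n_other, 12L)
})

test_that("zero fold-change in any study forces pattern 'other'", {
  m <- make_mapped_signs(rbind(c(1, 1, 1, 1)))
  m$log2fc[m$study_id == "mouse_a"] <- 0
  rec <- suppressMessages(intersect_and_classify(m, outgroup = "salamander"))
  expect_equal(rec$pattern, "other")
})

test_that("significance in every study gates the classification", {
  m <- make_mapped_signs(rbind(c(1, 1, 1, 1)))
  m$p_adj[m$study_id == "rat_b"] <- 0.2
  rec <- suppressMessages(intersect_and_classify(m, outgroup = "salamander"))
  expect_false(rec$significant_all)
  expect_true(is.na(rec$pattern))
  # and absence from one study fails the gate too (species gate still passes
  # because the other rat study covers the species)
  m2 <- make_mapped_signs(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)))
  m2 <- m2[!(m2$study_id == "rat_b" & m2$ref_gene == "G002"), ]
  rec2 <- suppressMessages(intersect_and_classify(m2, outgroup = "salamander"))
  expect_true(rec2$significant_all[rec2$ref_gene == "G001"])
  expect_false(rec2$significant_all[rec2$ref_gene == "G002"])
  expect_true(is.na(rec2$pattern[rec2$ref_gene == "G002"]))
})

test_that("only orthologs present in every species are retained", {
  m <- make_mapped_signs(all_sign_patterns()[1:3, , drop = FALSE])
  m <- m[!(m$ref_gene == "G002" & m$species == "salamander"), ]
  rec <- suppressMessages(intersect_and_classify(m, outgroup = "salamander"))
  expect_false("G002" %in% rec$ref_gene)
  expect_setequal(rec$ref_gene, c("G001", "G003"))
})

test_that("classification is invariant to study order and positive scaling", {
  set.seed(5)
  signs <- all_sign_patterns()[sample.int(16, 10, replace = TRUE), ]
  m <- make_mapped_signs(signs, p_adj = 0.02)
  base <- suppressMessages(intersect_and_classify(m, outgroup = "salamander"))
  perm <- m[sample.int(nrow(m)), ]
  perm$log2fc[perm$study_id == "mouse_a"] <-
    perm$log2fc[perm$study_id == "mouse_a"] * 3.7
  alt <- suppressMessages(intersect_and_classify(perm, outgroup = "salamander"))
  expect_equal(base$pattern, alt$pattern)
  expect_equal(base$ref_gene, alt$ref_gene)
})

test_that("the three patterns always partition the significant set", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    m <- make_mapped_signs(all_sign_patterns()[sample.int(16, n, replace = TRUE), ],
                           p_adj = 0.01)
    m$p_adj <- runif(nrow(m), 0, 0.1)
    m$log2fc <- m$log2fc * runif(nrow(m), 0, 2)  # may create zeros
    rec <- suppressMessages(intersect_and_classify(m, outgroup = "salamander"))
    cnt <- partition_summary(rec)
    expect_equal(cnt$n_consistent + cnt$n_opposite + cnt$n_other,
                 cnt$n_significant)
  }
})

test_that("an empty record set summarises to zeros", {
  rec <- suppressMessages(
    intersect_and_classify(make_mapped_signs(rbind(c(1, 1, 1, 1))),
                           outgroup = "salamander"))
  expect_equal(unlist(partition_summary(rec[0, ])),
               c(n_significant = 0L, n_consistent = 0L,
                 n_opposite = 0L, n_other = 0L))
})
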