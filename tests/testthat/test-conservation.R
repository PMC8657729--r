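test_that("percent identity counts identical non-gap columns", {
  aln <- aa_alignment(c(human = "ACDEFGHIKL", mouse = "ACDEFGHIKL",
                        frog = "ACDEFGHIAA"))
  pid <- percent_identity(aln, "human")
  expect_equal(pid$pct_identity[pid$taxon == "human"], 100)
  expect_equal(pid$pct_identity[pid$taxon == "mouse"], 100)
  expect_equal(pid$pct_identity[pid$taxon == "frog"], 80)  # 2 of 10 differ

  # gap columns leave the denominator (terminal and internal alike)
  aln2 <- aa_alignment(c(human = "AC-EFGHIK-", frog = "ACAEFGHIAA"))
  pid2 <- percent_identity(aln2, "human")
  expect_equal(pid2$n_comparable[pid2$taxon == "frog"], 8)
  expect_equal(pid2$pct_identity[pid2$taxon == "frog"], 100 * 7 / 8)

  # symmetric in the pair and invariant under column permutation
  expect_equal(percent_identity(aln2, "frog")$pct_identity[1], 100 * 7 / 8)
  perm <- withr::with_seed(3, sample.int(10))
  shuf <- aa_alignment(vapply(unclass(aln), function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), ""))
  expect_equal(percent_identity(shuf, "human")$pct_identity,
               pid$pct_identity)

  expect_error(percent_identity(aln, "yeti"), "not in alignment")
  expect_error(percent_identity(
    aa_alignment(c(a = "----A", b = "AAAA-")), "a"), "no comparable")
})

test_that("Poisson correction follows -ln(1 - p) with pairwise deletion", {
  same <- aa_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  expect_equal(poisson_distance(same)["a", "b"], 0)

  # exactly 1 of 10 sites differs: p = 0.1
  one <- aa_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKV"))
  expect_equal(poisson_distance(one)["a", "b"], -log(0.9), tolerance = 1e-5)
  expect_equal(round(poisson_distance(one)["a", "b"], 5), 0.10536)

  # a gap or X in taxon c must not change d(a, b)
  trio <- aa_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKV",
                         c = "-CDEFGHXKL"))
  expect_equal(poisson_distance(trio)["a", "b"], -log(0.9))
  # but does shrink c's comparable set
  expect_equal(poisson_distance(trio)["a", "c"], 0)

  # corrected distance is at least the raw p-distance
  aln <- simulate_alignment("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);",
                            800, seed = 6)
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  dm <- poisson_distance(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    p <- mean(m[i, ] != m[j, ])
    expect_gte(dm[i, j] + 1e-12, p)
  }

  diverged <- aa_alignment(c(a = "AAAA", b = "CCCC"))
  expect_error(poisson_distance(diverged), "undefined")
})

test_that("neighbor joining is exact on the additive 4-taxon instance", {
  d <- matrix(4, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  tree <- neighbor_joining(d)
  # topology ((A,B),(C,D))
  ref <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(ref)), 0)
  # external branches 1,1,1,1 and internal branch 2
  expect_equal(sort(tree$edge.length), c(1, 1, 1, 1, 2))
  # path lengths reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("three taxa are resolved by the closed three-point formulas", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.5
  d["a", "c"] <- d["c", "a"] <- 0.7
  d["b", "c"] <- d["c", "b"] <- 0.8
  tree <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("NJ matches the ape reference on random additive matrices", {
  for (seed in 1:4) {
    ref <- withr::with_seed(seed, ape::rtree(7))
    d <- ape::cophenetic.phylo(ref)
    tree <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(ref)), 0)
    expect_equal(phangorn::RF.dist(ape::unroot(tree),
                                   ape::unroot(ape::nj(d))), 0)
    expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("negative NJ branch lengths are clamped with a log", {
  d <- matrix(c(0, 0.531, 0.744, 1.146,
                0.531, 0, 1.816, 0.403,
                0.744, 1.816, 0, 1.797,
                1.146, 0.403, 1.797, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  msgs <- character()
  tree <- withCallingHandlers(neighbor_joining(d), xsci_log = function(c) {
    msgs <<- c(msgs, conditionMessage(c)); invokeRestart("muffleMessage")
  })
  expect_true(all(tree$edge.length >= 0))
  expect_true(any(grepl("clamped", msgs)))
})

test_that("non-symmetric input is rejected", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "symmetric")
})

test_that("heatmap ordering clusters species and genes by cosine structure", {
  set.seed(4)
  # four well-separated direction blocks over 5 species
  block <- rbind(c(2, 2, 2, 2, 2), c(-2, -2, -2, -2, -2),
                 c(2, 2, 2, -2, -2), c(-2, -2, 2, 2, 2))
  vals <- block[rep(1:4, each = 10), ] + matrix(rnorm(200, 0, 0.1), 40)
  rownames(vals) <- sprintf("g%02d", 1:40)
  colnames(vals) <- c("rat1", "rat2", "mouse", "sal1", "sal2")
  ord <- order_for_heatmap(vals, n_gene_clusters = 4, seed = 1)
  truth <- rep(1:4, each = 10)
  # clusters match the planted blocks up to label permutation
  tab <- table(truth, ord$gene_clusters)
  expect_equal(sum(apply(tab, 1, max)), 40)
  # identical-direction species pair merges first
  h <- ord$species_hclust
  first_pair <- sort(colnames(vals)[-h$merge[1, ]])
  expect_true(all(first_pair %in% c("rat1", "rat2", "sal1", "sal2")))

  # permuting gene order leaves the partition unchanged up to labels
  perm <- sample.int(40)
  ord2 <- order_for_heatmap(vals[perm, ], n_gene_clusters = 4, seed = 1)
  tab2 <- table(ord$gene_clusters, ord2$gene_clusters[rownames(vals)])
  expect_equal(sum(apply(tab2, 1, max)), 40)
  expect_equal(ord$species_order, ord2$species_order)
})

test_that("degenerate heatmap inputs are handled", {
  vals <- matrix(rnorm(30), 10, 3,
                 dimnames = list(sprintf("g%d", 1:10), c("a", "b", "c")))
  vals[3, ] <- 0
  expect_message(ord <- order_for_heatmap(vals, n_gene_clusters = 2, seed = 1),
                 "sentinel", class = "xsci_log")
  expect_equal(unname(ord$gene_clusters["g3"]), 0L)
  expect_error(order_for_heatmap(vals, n_gene_clusters = 50, seed = 1),
               "more clusters")
})

test_that("the longest isoform per gene is kept deterministically", {
  seqs <- c(iso1 = "ACDEF", iso2 = "ACDEFGH", iso3 = "AC---", iso4 = "ACDEA")
  genes <- c("g1", "g1", "g2", "g2")
  out <- longest_isoforms(seqs, genes)
  expect_equal(names(out), c("iso2", "iso4"))  # gaps don't count as length
  # tie -> lexicographically smallest id
  out2 <- longest_isoforms(c(b = "AAA", a = "CCC"), c("g", "g"))
  expect_equal(names(out2), "a")
})
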