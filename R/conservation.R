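#' Percent amino-acid identity against a reference taxon
#'
#' For each taxon, identity is the number of columns identical to the
#' reference divided by the number of comparable columns (columns where
#' neither sequence has a gap, terminal or internal), times 100. The
#' ambiguity code `X` counts as a comparable mismatch.
#'
#' @param aln An `aa_alignment`.
#' @param reference Reference taxon name (e.g. `"human"`).
#' @return Tibble with columns `taxon`, `pct_identity`, `n_comparable`.
#' @export
percent_identity <- function(aln, reference) {
  m <- aln_matrix(aln)
  assert_that(reference %in% rownames(m),
              paste0("reference taxon not in alignment: ", reference))
  ref <- m[reference, ]
  out <- purrr::map_dfr(rownames(m), function(tx) {
    s <- m[tx, ]
    comparable <- ref != "-" & s != "-"
    assert_that(any(comparable),
                paste0("no comparable (gap-free) columns between ",
                       reference, " and ", tx))
    tibble(taxon = tx,
           pct_identity = 100 * sum(s[comparable] == ref[comparable]) /
             sum(comparable),
           n_comparable = sum(comparable))
  })
  out
}

#' Poisson-corrected evolutionary distances with pairwise deletion
#'
#' For each sequence pair, p is the proportion of differing sites among
#' comparable columns -- columns with a gap or ambiguity (`X`) in either
#' member of the pair are removed for that pair only (pairwise deletion) --
#' and the Poisson-corrected distance is d = -ln(1 - p), in expected
#' amino-acid substitutions per site.
#'
#' @param aln An `aa_alignment` with >= 2 taxa.
#' @return Symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
poisson_distance <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  usable <- m != "-" & m != "X"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- usable[i, ] & usable[j, ]
      assert_that(any(comp),
                  paste0("no comparable columns for pair ",
                         rownames(m)[i], " / ", rownames(m)[j]))
      p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
      assert_that(p < 1,
                  paste0("all comparable sites differ for pair ",
                         rownames(m)[i], " / ", rownames(m)[j],
                         ": Poisson distance undefined"))
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k) is joined,
#' with the standard branch-length and distance-update formulas; the final
#' three nodes are resolved exactly by the three-point formulas. Ties in Q
#' are broken by the lexicographically smallest taxon pair (each internal
#' node is labelled by the smallest leaf beneath it), so the construction
#' is deterministic. Negative branch lengths are clamped to zero and the
#' clamped deficit logged. Exact on additive matrices.
#'
#' @param dm Symmetric nonnegative matrix with zero diagonal and taxa
#'   dimnames (>= 3 taxa), e.g. from [poisson_distance()].
#' @return An unrooted `phylo` tree (ape) with branch lengths in the input
#'   units.
#' @export
neighbor_joining <- function(dm) {
  assert_that(is.matrix(dm) && nrow(dm) == ncol(dm) && nrow(dm) >= 3,
              "need a square distance matrix over >= 3 taxa")
  assert_that(all(is.finite(dm)), "distances must all be finite")
  assert_that(max(abs(dm - t(dm))) < 1e-12 && all(diag(dm) == 0),
              "distance matrix must be symmetric with zero diagonal")
  assert_that(!is.null(rownames(dm)), "taxa dimnames are required")

  labels <- rownames(dm)   # lexicographic tie-break key per active node
  newick <- rownames(dm)   # growing subtree strings
  D <- dm
  clamped <- 0

  fmt <- function(sub, b) {
    if (b < 0) { clamped <<- clamped + 1; b <- 0 }
    sprintf("%s:%.10g", sub, b)
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(z) {
      pr <- sort(c(labels[cand[z, 1]], labels[cand[z, 2]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    sub <- sprintf("(%s,%s)", fmt(newick[i], bi), fmt(newick[j], bj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    newlab <- min(labels[c(i, j)])
    labels <- c(labels[keep], newlab)
    newick <- c(newick[keep], sub)
    dimnames(D2) <- list(labels, labels)
    D <- D2
  }

  # exact three-point resolution of the last three nodes
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s,%s,%s);", fmt(newick[1], b1), fmt(newick[2], b2),
                 fmt(newick[3], b3))
  if (clamped > 0) {
    xsci_log(sprintf("neighbor_joining: clamped %d negative branch length(s) to 0",
                     clamped))
  }
  ape::read.tree(text = txt)
}

#' Heatmap ordering: cosine clustering of species and genes
#'
#' Species (columns) are ordered by average-linkage hierarchical clustering
#' under the 1 - cosine-similarity dissimilarity. Genes (rows) are grouped
#' by spherical k-means -- k-means on L2-normalized rows, the standard
#' realization of "one minus cosine" k-means, with the centroid taken as
#' the normalized mean -- with `n_restarts` seeded restarts keeping the
#' best total inertia (sum of 1 - cosine to the assigned centroid).
#' All-zero rows have no direction under cosine and are assigned the
#' sentinel cluster 0 (logged).
#'
#' @param values Numeric matrix (genes x species) with dimnames, or a
#'   data frame with a first id column and numeric species columns.
#' @param n_gene_clusters Number of gene clusters (default 4).
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts Number of k-means restarts.
#' @return List with `species_order` (character), `gene_clusters` (named
#'   integer vector; 0 = sentinel), `inertia`, and `species_hclust`.
#' @export
order_for_heatmap <- function(values, n_gene_clusters = 4, seed = 1,
                              n_restarts = 10) {
  if (is.data.frame(values)) {
    ids <- values[[1]]
    values <- as.matrix(values[-1])
    rownames(values) <- ids
  }
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix (genes x species)")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values needs gene rownames and species colnames")
  zero_col <- colSums(values^2) == 0
  assert_that(!any(zero_col),
              paste0("all-zero species column(s): ",
                     paste(colnames(values)[zero_col], collapse = ", ")))

  cd <- cosine_dissimilarity(t(values))
  hc <- stats::hclust(stats::as.dist(cd), method = "average")
  species_order <- colnames(values)[hc$order]

  zero_row <- rowSums(values^2) == 0
  if (any(zero_row)) {
    xsci_log(sprintf("order_for_heatmap: %d all-zero row(s) assigned sentinel cluster 0",
                     sum(zero_row)))
  }
  live <- values[!zero_row, , drop = FALSE]
  assert_that(n_gene_clusters <= nrow(live),
              "more clusters requested than (non-degenerate) genes")
  km <- withr::with_seed(seed,
    spherical_kmeans(live, n_gene_clusters, n_restarts))
  clusters <- stats::setNames(integer(nrow(values)), rownames(values))
  clusters[rownames(live)] <- km$cluster
  list(species_order = species_order, gene_clusters = clusters,
       inertia = km$inertia, species_hclust = hc)
}

cosine_dissimilarity <- function(rows) {
  nrm <- sqrt(rowSums(rows^2))
  u <- rows / nrm
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Spherical k-means: rows L2-normalized, assignment by max cosine,
# centroid = normalized mean of assigned rows. Empty clusters are reseeded
# from the worst-fit row.
spherical_kmeans <- function(x, k, n_restarts = 10, max_iter = 100) {
  u <- x / sqrt(rowSums(x^2))
  n <- nrow(u)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- u[sample.int(n, k), , drop = FALSE]
    cl <- integer(n)
    for (it in seq_len(max_iter)) {
      sim <- tcrossprod(u, centers)
      cl_new <- max.col(sim, ties.method = "first")
      for (c in seq_len(k)) {
        if (!any(cl_new == c)) cl_new[which.min(sim[cbind(seq_len(n), cl_new)])] <- c
      }
      if (identical(cl_new, cl)) break
      cl <- cl_new
      for (c in seq_len(k)) {
        m <- colMeans(u[cl == c, , drop = FALSE])
        centers[c, ] <- m / sqrt(sum(m^2))
      }
    }
    inertia <- sum(1 - tcrossprod(u, centers)[cbind(seq_len(n), cl)])
    if (is.null(best) || inertia < best$inertia - 1e-12) {
      best <- list(cluster = stats::setNames(cl, rownames(x)), inertia = inertia)
    }
  }
  best
}

#' Keep the longest record per gene id
#'
#' Helper for picking one isoform per gene before alignment-based
#' analyses: keeps the longest sequence per gene, ties broken by
#' lexicographically smallest record id. Gap characters do not count
#' toward length.
#'
#' @param seqs Named character vector of sequences (record ids as names).
#' @param genes Character vector of gene ids, one per record.
#' @return Named character vector, one record per gene.
#' @export
longest_isoforms <- function(seqs, genes) {
  assert_that(length(seqs) == length(genes), "one gene id per record")
  tibble(id = names(seqs), gene = genes, seq = unname(seqs),
         len = nchar(gsub("-", "", unname(seqs), fixed = TRUE))) |>
    arrange(.data$gene, desc(.data$len), .data$id) |>
    distinct(.data$gene, .keep_all = TRUE) |>
    (\(d) stats::setNames(d$seq, d$id))()
}
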