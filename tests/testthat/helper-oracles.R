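# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Step-up FDR adjustment straight from the definition: adj for rank i is
# min over j >= i of p_(j) * m / j, capped at 1, back in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  adj[order(o)]
}

# Exhaustive hypergeometric upper tail P(X >= k) from binomial coefficients.
hyper_tail_enum <- function(k, K, n, N) {
  js <- max(k, 0, n + K - N):min(K, n)
  js <- js[js >= k]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Degree counting straight from an edge table.
degree_bruteforce <- function(edges) {
  tab <- table(c(edges$node_a, edges$node_b))
  sort_order <- order(-as.integer(tab), names(tab))
  data.frame(node = names(tab)[sort_order],
             degree = as.integer(tab)[sort_order])
}

# A long mapped table for four studies (two rat, one mouse, one salamander
# outgroup) with one ortholog per row of `signs`; used to exercise the
# direction classifier over explicit sign patterns.
make_mapped_signs <- function(signs, p_adj = 0.01) {
  studies <- data.frame(
    study_id = c("rat_a", "rat_b", "mouse_a", "sal_a"),
    species = c("rat", "rat", "mouse", "salamander"))
  stopifnot(ncol(signs) == 4)
  out <- list()
  for (g in seq_len(nrow(signs))) {
    out[[g]] <- data.frame(
      study_id = studies$study_id, species = studies$species,
      ref_gene = sprintf("G%03d", g),
      source_gene = sprintf("G%03d", g),
      log2fc = signs[g, ] * 1.5,
      p_adj = p_adj)
  }
  dplyr::bind_rows(out)
}

# All 16 sign patterns over four studies.
all_sign_patterns <- function() {
  as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1), c(1, -1)))
}

# Small deterministic expression study built by hand.
toy_study <- function(n_probesets = 6, n1 = 3, n2 = 3, seed = 1,
                      effect = 0) {
  set.seed(seed)
  mat <- matrix(rnorm(n_probesets * (n1 + n2), mean = 8, sd = 0.4),
                nrow = n_probesets)
  mat[, seq_len(n1)] <- mat[, seq_len(n1)] + effect
  rownames(mat) <- sprintf("ps%02d", seq_len(n_probesets))
  colnames(mat) <- sprintf("s%02d", seq_len(n1 + n2))
  expression_study(mat, c(rep("injured", n1), rep("control", n2)),
                   study_id = "toy", species = "rat")
}
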