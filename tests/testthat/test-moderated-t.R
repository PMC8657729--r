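test_that("a probeset with identical arms gets zero fold-change and t", {
  st <- toy_study(n_probesets = 5, seed = 2)
  st$matrix[3, ] <- c(7, 8, 9, 7, 8, 9)  # injured == control pattern
  fit <- suppressMessages(fit_moderated_t(st))
  tab <- tidy(fit)
  expect_equal(tab$log2fc[3], 0)
  expect_equal(tab$t_mod[3], 0)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  expect_true(all(tab$ci_low <= tab$log2fc & tab$log2fc <= tab$ci_high))
  expect_true(all(sign(tab$t_mod) == sign(tab$log2fc) |
                    tab$log2fc == 0))
})

test_that("a pinned prior reproduces the posterior-variance formula exactly", {
  st <- toy_study(n_probesets = 5, n1 = 4, n2 = 4, seed = 3, effect = 1)
  fit <- fit_moderated_t(st, prior = list(d0 = 4, s0_sq = 0.04))
  tab <- tidy(fit)
  inj <- st$matrix[, 1:4]; ctl <- st$matrix[, 5:8]
  for (i in 1:5) {
    fc <- mean(inj[i, ]) - mean(ctl[i, ])
    s2 <- (3 * var(inj[i, ]) + 3 * var(ctl[i, ])) / 6
    s2_post <- (4 * 0.04 + 6 * s2) / (4 + 6)
    t_hand <- fc / sqrt(s2_post * (1 / 4 + 1 / 4))
    expect_equal(tab$t_mod[i], t_hand, tolerance = 1e-10)
    expect_equal(tab$p[i], 2 * pt(-abs(t_hand), df = 10), tolerance = 1e-10)
  }
})

test_that("estimated prior and statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  # heteroscedastic truth so d0 is finite and shrinkage is real
  set.seed(42)
  n <- 300; n1 <- 4; n2 <- 4
  sds <- sqrt(0.04 * rchisq(n, df = 5) / 5)
  mat <- matrix(rnorm(n * (n1 + n2), sd = rep(sds, n1 + n2)), nrow = n)
  mat <- mat + 8
  rownames(mat) <- sprintf("p%03d", seq_len(n))
  colnames(mat) <- sprintf("s%d", seq_len(n1 + n2))
  st <- expression_study(mat, c(rep("injured", n1), rep("control", n2)),
                         "x", "rat")
  fit <- suppressMessages(fit_moderated_t(st))

  design <- cbind(1, c(rep(1, n1), rep(0, n2)))
  lfit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(fit$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(tidy(fit)$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(tidy(fit)$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("trigamma inversion matches the limma reference", {
  skip_if_not_installed("limma")
  for (y in c(1e-5, 0.01, 0.3, 2, 50, 1e6)) {
    expect_equal(xsci:::trigamma_inverse(y), c(limma::trigammaInverse(y)),
                 tolerance = 1e-8)
  }
})

test_that("moderated t interpolates between ordinary t and pooled z", {
  st <- toy_study(n_probesets = 40, n1 = 4, n2 = 4, seed = 5)
  inj <- st$matrix[, 1:4]; ctl <- st$matrix[, 5:8]
  s2 <- (3 * apply(inj, 1, var) + 3 * apply(ctl, 1, var)) / 6
  fc <- rowMeans(inj) - rowMeans(ctl)

  lo <- fit_moderated_t(st, prior = list(d0 = 1e-9, s0_sq = 0.04))
  t_classic <- fc / sqrt(s2 * (1 / 4 + 1 / 4))
  expect_equal(tidy(lo)$t_mod, unname(t_classic), tolerance = 1e-4)

  hi <- fit_moderated_t(st, prior = list(d0 = 1e12, s0_sq = 0.04))
  t_pooled <- fc / sqrt(0.04 * (1 / 4 + 1 / 4))
  expect_equal(tidy(hi)$t_mod, unname(t_pooled), tolerance = 1e-4)
})

test_that("degenerate all-constant input is rejected", {
  mat <- matrix(5, nrow = 3, ncol = 6,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:6)))
  st <- expression_study(mat, rep(c("injured", "control"), each = 3),
                         "flat", "rat")
  expect_error(suppressMessages(fit_moderated_t(st)), "degenerate")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  p_eq <- rep(0.07, 6)
  expect_equal(benjamini_hochberg(p_eq), p_eq)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  expect_equal(benjamini_hochberg(c(0.9, 0.001)),
               bh_bruteforce(c(0.9, 0.001)))
})

test_that("probeset collapsing keeps the highest-expression representative", {
  tab <- tibble::tibble(
    probeset_id = c("a1", "b1", "b2", "c2", "c1"),
    log2fc = 1:5 / 10, t_mod = 1:5, p = rep(0.01, 5), p_adj = rep(0.02, 5),
    ci_low = 0, ci_high = 1,
    mean_expr = c(5, 7.1, 9.3, 6, 6))
  map <- tibble::tibble(probeset_id = c("a1", "b1", "b2", "c1", "c2"),
                        gene_symbol = c("A", "B", "B", "C", "C"))
  out <- collapse_probesets(tab, map)
  expect_equal(nrow(out), 3)
  expect_equal(out$probeset_id[out$gene == "A"], "a1")   # single probeset
  expect_equal(out$probeset_id[out$gene == "B"], "b2")   # 9.3 beats 7.1
  expect_equal(out$probeset_id[out$gene == "C"], "c1")   # tie -> smaller id

  # unmapped probesets are dropped with a log
  expect_message(
    out2 <- collapse_probesets(tab, map[-1, ]),
    "dropped 1 unmapped", class = "xsci_log")
  expect_false("A" %in% out2$gene)
})

test_that("collapsing recovers the planted high-baseline winner everywhere", {
  cfg <- simulation_config(seed = 13, n_genes = 120)
  sim <- suppressMessages(simulate_studies(cfg))
  st <- sim$studies[["rat_a"]]
  genes <- suppressMessages(
    collapse_probesets(tidy(suppressMessages(fit_moderated_t(st))),
                       st$probeset_to_gene))
  winners <- sim$truth$collapse_winners[["rat_a"]]
  merged <- dplyr::inner_join(genes, winners,
                              by = c(gene = "gene_symbol"),
                              suffix = c("", "_true"))
  expect_equal(nrow(merged), 120)
  expect_equal(merged$probeset_id, merged$probeset_id_true)
})

test_that("planted effects are recovered with high sensitivity and low FDP", {
  plan <- default_species_plan()
  plan$n_injured <- 4L; plan$n_control <- 4L
  cfg <- simulation_config(seed = 21, n_genes = 400, species_plan = plan,
                           frac_consistent = 0.1, frac_opposite = 0.1,
                           effect_log2fc = 2, noise_sd = 0.5)
  sim <- suppressMessages(simulate_studies(cfg))
  st <- sim$studies[["rat_a"]]
  genes <- suppressMessages(
    collapse_probesets(tidy(suppressMessages(fit_moderated_t(st))),
                       st$probeset_to_gene))
  ref <- sub("^r", "", genes$gene)
  truth_de <- ref %in% c(sim$truth$consistent_genes, sim$truth$opposite_genes)
  called <- genes$p_adj <= 0.05
  sensitivity <- sum(called & truth_de) / sum(truth_de)
  fdp <- if (any(called)) sum(called & !truth_de) / sum(called) else 0
  expect_gte(sensitivity, 0.8)
  expect_lte(fdp, 0.1)
})
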