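#' Empirical-Bayes moderated two-sample t-test per probeset
#'
#' For each probeset the injured-minus-control log2 fold-change is tested
#' with a moderated t-statistic: the per-probeset residual variance s^2
#' (pooled over the two arms, d = n1 + n2 - 2 df) is shrunk toward a prior
#' variance s0^2 carrying d0 prior degrees of freedom, giving the posterior
#' variance
#'   s~^2 = (d0 * s0^2 + d * s^2) / (d0 + d),
#' and t_mod = log2fc / (s~ * sqrt(1/n1 + 1/n2)) is referred to a Student t
#' with d0 + d degrees of freedom. The hyperparameters (d0, s0^2) are
#' estimated from the ensemble of s^2 by moment-matching on log s^2: since
#' log s^2 = log s_true^2 + log X/d for X ~ chi^2_d, the excess variance of
#' log s^2 over trigamma(d/2) identifies d0 through a Newton inversion of
#' the trigamma function, and the mean identifies s0^2. An infinite d0
#' estimate (no excess dispersion) collapses every posterior variance to
#' the pooled s0^2 -- a pooled-variance (z-like) test -- and is logged.
#' Two-sided p-values, 95% confidence intervals on the same posterior
#' scale, and Benjamini-Hochberg adjusted p-values are returned.
#'
#' @param study An [expression_study()].
#' @param prior Optional list `list(d0 =, s0_sq =)` pinning the prior
#'   instead of estimating it (useful for validation).
#' @param ci_level Confidence level for the fold-change interval.
#' @return An object of class `moderated_t_fit`; see [tidy.moderated_t_fit()]
#'   for the per-probeset table and [glance.moderated_t_fit()] for the
#'   estimated prior.
#' @export
fit_moderated_t <- function(study, prior = NULL, ci_level = 0.95) {
  assert_that(inherits(study, "expression_study"),
              "`study` must be an expression_study")
  inj <- study$matrix[, study$sample_groups == "injured", drop = FALSE]
  ctl <- study$matrix[, study$sample_groups == "control", drop = FALSE]
  n1 <- ncol(inj); n2 <- ncol(ctl)
  d <- n1 + n2 - 2
  log2fc <- rowMeans(inj) - rowMeans(ctl)
  s2 <- ((n1 - 1) * apply(inj, 1, stats::var) +
           (n2 - 1) * apply(ctl, 1, stats::var)) / d
  assert_that(any(s2 > 0),
              "degenerate input: zero residual variance in every probeset")

  if (is.null(prior)) {
    prior <- estimate_variance_prior(s2, d)
    if (is.infinite(prior$d0)) {
      xsci_log("moderated t: estimated d0 is infinite; using the pooled prior variance for every probeset")
    }
  } else {
    assert_that(prior$d0 > 0 && prior$s0_sq > 0,
                "prior needs d0 > 0 and s0_sq > 0")
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + d
  t_mod <- ifelse(log2fc == 0, 0, log2fc / se)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  q <- stats::qt(1 - (1 - ci_level) / 2, df = df_total)
  table <- tibble(
    probeset_id = rownames(study$matrix),
    log2fc = unname(log2fc),
    t_mod = unname(t_mod),
    p = unname(p),
    p_adj = benjamini_hochberg(unname(p)),
    ci_low = unname(log2fc - q * se),
    ci_high = unname(log2fc + q * se),
    mean_expr = unname(rowMeans(study$matrix))
  )
  structure(list(table = table,
                 prior = list(d0 = d0, s0_sq = s0_sq),
                 study_id = study$study_id, species = study$species,
                 n_injured = n1, n_control = n2, df_residual = d,
                 df_total = df_total, ci_level = ci_level),
            class = "moderated_t_fit")
}

# Moment-matching of a scaled inverse-chi-square prior to the observed
# log s^2 ensemble. Zero sample variances cannot enter the log-scale fit
# and are offset to a small multiple of the median (logged).
estimate_variance_prior <- function(s2, d) {
  zero <- s2 <= 0
  if (any(zero)) {
    xsci_log(sprintf("moderated t: %d zero sample variance(s) offset away from zero for prior estimation",
                     sum(zero)))
  }
  x <- pmax(s2, 1e-5 * stats::median(s2))
  z <- log(x)
  e <- z - digamma(d / 2) + log(d / 2)
  n <- length(e)
  assert_that(n >= 2, "too few probesets to estimate a prior")
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = mean(x)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing, so the
# iteration in 1/x space (as for other polygamma inversions) is stable.
trigamma_inverse <- function(y) {
  assert_that(length(y) == 1 && is.finite(y) && y > 0,
              "trigamma_inverse needs a single positive finite value")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validated wrapper over the standard step-up procedure: adjusted values
#' are monotone nondecreasing in rank, capped at 1, and returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  assert_that(is.numeric(pvalues) && !anyNA(pvalues) &&
                all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1] with no missing values")
  if (length(pvalues) == 0) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Collapse probesets to one representative row per gene
#'
#' Probesets mapping to no gene are dropped (with a logged count); among a
#' gene's probesets the one with the highest average expression is kept as
#' the representative, ties broken by lexicographically smallest probeset
#' id so the choice is deterministic.
#'
#' @param results Per-probeset tibble as from `tidy(fit_moderated_t(...))`
#'   (must contain `probeset_id` and `mean_expr`).
#' @param mapping Tibble with columns `probeset_id`, `gene_symbol`.
#' @return Per-gene tibble: `gene` first, then the representative
#'   probeset's row.
#' @export
collapse_probesets <- function(results, mapping) {
  assert_that(all(c("probeset_id", "mean_expr") %in% names(results)),
              "results need probeset_id and mean_expr columns")
  joined <- results |>
    inner_join(mapping[c("probeset_id", "gene_symbol")], by = "probeset_id")
  n_drop <- nrow(results) - nrow(joined)
  if (n_drop > 0) {
    xsci_log(sprintf("collapse_probesets: dropped %d unmapped probeset(s)", n_drop))
  }
  joined |>
    arrange(desc(.data$mean_expr), .data$probeset_id) |>
    distinct(.data$gene_symbol, .keep_all = TRUE) |>
    rename(gene = "gene_symbol") |>
    relocate("gene") |>
    arrange(.data$gene)
}

#' @export
print.moderated_t_fit <- function(x, ...) {
  cat(sprintf("<moderated_t_fit> %s (%s): %d probesets, %d vs %d samples\n",
              x$study_id, x$species, nrow(x$table), x$n_injured, x$n_control))
  cat(sprintf("  prior: d0 = %s, s0^2 = %.4g; total df = %s\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq,
              format(x$df_total, digits = 4)))
  invisible(x)
}

#' Tidy a moderated-t fit into its per-probeset table
#'
#' @param x A `moderated_t_fit`.
#' @param ... Unused.
#' @return Tibble with columns `probeset_id`, `log2fc`, `t_mod`, `p`,
#'   `p_adj`, `ci_low`, `ci_high`, `mean_expr`.
#' @method tidy moderated_t_fit
#' @export
tidy.moderated_t_fit <- function(x, ...) x$table

#' One-row summary of a moderated-t fit
#'
#' @param x A `moderated_t_fit`.
#' @param ... Unused.
#' @return One-row tibble with the estimated prior and design sizes.
#' @method glance moderated_t_fit
#' @export
glance.moderated_t_fit <- function(x, ...) {
  tibble(study_id = x$study_id, species = x$species,
         n_probesets = nrow(x$table),
         n_injured = x$n_injured, n_control = x$n_control,
         d0 = x$prior$d0, s0_sq = x$prior$s0_sq, df_total = x$df_total)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
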