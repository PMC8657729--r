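#' Stain area fraction of a grayscale image
#'
#' Thresholds the image, binarizes it, and returns the foreground share:
#' pixels with intensity at or above the threshold count as stained.
#' `threshold = "otsu"` picks the threshold by Otsu's method (deterministic
#' and parameter-free); a numeric threshold overrides it.
#'
#' @param image Numeric matrix with intensities in [0, 1] (see
#'   [read_grayscale()]).
#' @param threshold `"otsu"` or a numeric intensity in [0, 1].
#' @return Foreground pixel fraction in [0, 1].
#' @export
area_fraction <- function(image, threshold = "otsu") {
  image <- unclass(image)
  assert_that(is.matrix(image) && is.numeric(image) && length(image) > 0,
              "image must be a non-empty numeric matrix")
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(image, range = c(0, 1))
  }
  assert_that(is.numeric(threshold) && length(threshold) == 1,
              "threshold must be 'otsu' or a single number")
  mean(image >= threshold)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorted ascending, the i-th smallest of m p-values is adjusted to
#' 1 - (1 - p_(i))^(m - i + 1); a running maximum enforces monotonicity
#' and values are capped at 1. Returned in the input order.
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
holm_sidak <- function(pvalues) {
  assert_that(is.numeric(pvalues) && !anyNA(pvalues) &&
                all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  adj <- 1 - (1 - pvalues[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  adj[order(o)]
}

#' Two-way ANOVA of area fractions with Holm-Sidak comparisons
#'
#' Fits the fixed-effects model `area_fraction ~ group * region` and tests
#' the group, region, and interaction terms (Type II sums of squares, which
#' coincide with the balanced-design decomposition when cell sizes are
#' equal). Per-region group contrasts use the pooled residual error
#' (estimated marginal means) and are adjusted across regions by the
#' Holm-Sidak step-down.
#'
#' @param data Tibble with columns `group` (2+ levels), `region` (2+
#'   levels), `area_fraction`, and optionally `animal_id`.
#' @return Object of class `anova_hs` with elements `anova` (term table),
#'   `comparisons` (per-region contrasts with `p_adj`), and `fit` (the lm).
#' @export
two_way_anova_holm_sidak <- function(data) {
  data <- as_tibble(data)
  assert_that(all(c("group", "region", "area_fraction") %in% names(data)),
              "data needs group, region, area_fraction")
  assert_that(all(data$area_fraction >= 0 & data$area_fraction <= 1),
              "area fractions must lie in [0, 1]")
  data$group <- factor(data$group)
  data$region <- factor(data$region)
  assert_that(nlevels(data$group) >= 2 && nlevels(data$region) >= 2,
              "need at least 2 groups and 2 regions")
  cells <- data |> count(.data$group, .data$region, .drop = FALSE)
  bad <- cells |> filter(.data$n < 2)
  assert_that(nrow(bad) == 0,
              paste0("cell(s) with fewer than 2 observations: ",
                     paste(paste0(bad$group, ":", bad$region), collapse = ", ")))

  fit <- stats::lm(area_fraction ~ group * region, data = data)
  a2 <- car::Anova(fit, type = 2)
  anova_tbl <- tibble(
    term = trimws(rownames(a2)),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`
  )

  emm <- emmeans::emmeans(fit, ~ group | region)
  cmp <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "none",
                 infer = c(FALSE, TRUE))
  comparisons <- as_tibble(cmp) |>
    select(region = "region", contrast = "contrast", estimate = "estimate",
           se = "SE", df = "df", statistic = "t.ratio", p = "p.value") |>
    mutate(p_adj = holm_sidak(.data$p))

  structure(list(anova = anova_tbl, comparisons = comparisons, fit = fit,
                 nobs = nrow(data)),
            class = "anova_hs")
}

#' @export
print.anova_hs <- function(x, ...) {
  cat("<anova_hs> two-way ANOVA with Holm-Sidak comparisons\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("\nPer-region comparisons:\n")
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}

#' Tidy the per-region comparisons of an `anova_hs` fit
#'
#' @param x An `anova_hs` object.
#' @param which `"comparisons"` (default) or `"anova"` for the term table.
#' @param ... Unused.
#' @return Tibble.
#' @method tidy anova_hs
#' @export
tidy.anova_hs <- function(x, which = c("comparisons", "anova"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @method glance anova_hs
#' @export
glance.anova_hs <- function(x, ...) {
  s <- summary(x$fit)
  tibble(nobs = x$nobs, r.squared = s$r.squared,
         sigma = s$sigma, df.residual = x$fit$df.residual)
}
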