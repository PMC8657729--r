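#' @importFrom rlang abort inform warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest
#' @importFrom purrr map map_chr map_dbl map_int map2 imap
NULL

# Single notification channel so every logged event (skips, collisions,
# clamps) is classed and can be muffled or collected by callers.
xsci_log <- function(msg, class = "xsci_log") {
  rlang::inform(msg, class = c(class, "xsci_log"))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg, class = "xsci_error")
  invisible(TRUE)
}

# Deterministic per-stage substream seeds derived from one top-level seed.
# Kept strictly below 2^31 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}
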