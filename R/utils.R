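#' @import rlang
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number across all_of desc
#' @importFrom purrr map map_dbl map2 pmap imap walk
#' @importFrom stats median mad rnorm rexp rgeom runif rlnorm rpois prcomp
#'   kmeans pf pt ptukey pchisq quantile sd density var
NULL

# Internal parameter check helper: all conditions must hold, otherwise a
# classed error that tests can assert on.
check_that <- function(..., class = "gravimea_invalid_parameter") {
  conds <- list(...)
  msgs <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(conds[[i]])) {
      rlang::abort(msgs[i], class = class)
    }
  }
  invisible(TRUE)
}

# Derive a deterministic child seed from a root seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7907 * stream) %% 2147483647L)
}

`%||%` <- rlang::`%||%`
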