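#' Tidy a rank correlation result
#'
#' @param x A `rank_cor` object from [spearman()] or [partial_spearman()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `p.value`, `n`, `method`,
#'   `controlled`, `statistic`, `df`, `p.method`.
#' @export
tidy.rank_cor <- function(x, ...) {
  tibble(
    estimate = x$r,
    p.value = x$p,
    n = x$n,
    method = x$method,
    controlled = if (length(x$controlled) > 0L) {
      paste(x$controlled, collapse = ",")
    } else {
      NA_character_
    },
    statistic = x$statistic,
    df = x$df,
    p.method = x$p_method
  )
}

#' @rdname tidy.rank_cor
#' @export
glance.rank_cor <- function(x, ...) {
  tidy.rank_cor(x)
}
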