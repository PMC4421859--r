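# Spearman and body-mass-controlled partial Spearman rank correlation,
# implemented from first principles, plus the category screen and subgroup
# analyses built on them.

#' Rank-transform a numeric vector
#'
#' Ranks 1..n with average ranks assigned to ties (the convention used
#' throughout the rank statistics in this package; tie handling affects the
#' third decimal place of correlation coefficients, so it is fixed here).
#'
#' @param values Finite numeric vector of length >= 1.
#' @return Numeric vector of (possibly fractional) ranks.
#' @export
rank_transform <- function(values) {
  if (!is.numeric(values) || length(values) < 1L) {
    abort("`values` must be a numeric vector of length >= 1.")
  }
  assert_numeric_finite(values, "values")
  rank(values, ties.method = "average")
}

# All n! permutations of 1..n as an (n!) x n integer matrix. Used for the
# exact permutation null at small n (n <= 8 => at most 40320 rows).
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact two-sided permutation p-value for the Spearman coefficient: the
# proportion of permutations of y whose |r| is at least |r_obs|.
exact_spearman_p <- function(rx, ry, r_obs) {
  P <- all_perms(length(rx))
  rx_c <- rx - mean(rx)
  ry_c <- ry - mean(ry)
  num <- matrix(ry_c[P], nrow(P)) %*% rx_c
  r_all <- as.numeric(num) / sqrt(sum(rx_c^2) * sum(ry_c^2))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Exact permutation p-value for the first-order partial coefficient,
# permuting y while holding x and z fixed.
exact_partial_p <- function(rx, ry, rz, r_obs) {
  P <- all_perms(length(rx))
  cx <- rx - mean(rx); cy <- ry - mean(ry); cz <- rz - mean(rz)
  sx <- sqrt(sum(cx^2)); sy <- sqrt(sum(cy^2)); sz <- sqrt(sum(cz^2))
  M <- matrix(cy[P], nrow(P))
  rxy <- as.numeric(M %*% cx) / (sx * sy)
  ryz <- as.numeric(M %*% cz) / (sy * sz)
  rxz <- sum(cx * cz) / (sx * sz)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  ok <- den2 > 0
  r_all <- (rxy[ok] - rxz * ryz[ok]) / sqrt(den2[ok])
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

new_rank_cor <- function(r, p, n, method, controlled, statistic, df, p_method) {
  structure(
    list(r = r, p = p, n = n, method = method, controlled = controlled,
         statistic = statistic, df = df, p_method = p_method),
    class = "rank_cor"
  )
}

#' @export
print.rank_cor <- function(x, ...) {
  lab <- if (length(x$controlled) > 0L) {
    sprintf("partial Spearman rank correlation (controlling %s)",
            paste(x$controlled, collapse = ", "))
  } else {
    "Spearman rank correlation"
  }
  p_txt <- if (x$p < 2.2e-16) "< 2.2e-16" else format(x$p, digits = 3)
  cat(sprintf("%s\n  r = %.4f, p %s%s, n = %d (%s p-value)\n",
              lab, x$r, if (x$p < 2.2e-16) "" else "= ", p_txt, x$n,
              x$p_method))
  invisible(x)
}

t_approx_p <- function(r, df) {
  if (1 - r^2 <= .Machine$double.eps) {
    return(0)
  }
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Spearman rank correlation with p-value
#'
#' The coefficient is the Pearson correlation of the tie-averaged ranks of
#' `x` and `y`. The two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2` degrees of freedom; for
#' `n <= 8` (and `p_method = "auto"`, the default) the exact permutation
#' distribution over all `n!` reorderings is used instead. With `|r| = 1`
#' the t-based p-value collapses to the distribution floor (0 as a double;
#' printed as `< 2.2e-16`).
#'
#' @param x,y Finite numeric vectors of equal length `n >= 3`, each
#'   non-constant.
#' @param p_method `"auto"` (exact for n <= 8, t otherwise), `"t"`, or
#'   `"exact"`.
#' @return A `rank_cor` object with elements `r`, `p`, `n`, `method`,
#'   `controlled`, `statistic`, `df`, `p_method`. [tidy()] it for a
#'   one-row tibble.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4), c(2, 4, 6, 8))$r # 1
spearman <- function(x, y, p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.")
  }
  if (n < 3L) {
    abort("Need n >= 3 for a Spearman correlation.")
  }
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Constant vector: Spearman correlation is undefined.")
  }
  r <- stats::cor(rx, ry)
  use_exact <- p_method == "exact" || (p_method == "auto" && n <= 8L)
  if (use_exact && n > 9L) {
    abort("Exact permutation p-values are only available for n <= 9.")
  }
  if (use_exact) {
    p <- exact_spearman_p(rx, ry, r)
    stat <- NA_real_; df <- NA_real_; used <- "exact"
  } else {
    df <- n - 2
    p <- t_approx_p(r, df)
    stat <- if (1 - r^2 <= .Machine$double.eps) sign(r) * Inf else
      r * sqrt(df / (1 - r^2))
    used <- "t"
  }
  new_rank_cor(r, p, n, "spearman", character(0), stat, df, used)
}

#' First-order partial Spearman rank correlation
#'
#' Correlation between `x` and `y` with the rank-linear influence of the
#' controlling variable `z` removed, computed from the first-order formula
#' on the pairwise Spearman coefficients:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#' The two-sided p-value uses `t = r * sqrt((n - 3)/(1 - r^2))` on `n - 3`
#' degrees of freedom (one controller), with an exact permutation fallback
#' for `n <= 8` under `p_method = "auto"`.
#'
#' @param x,y Finite numeric vectors of equal length `n >= 4`.
#' @param z Controlling variable; its rank correlation with `x` and with
#'   `y` must be strictly below 1 in magnitude.
#' @inheritParams spearman
#' @return A `rank_cor` object (see [spearman()]).
#' @export
partial_spearman <- function(x, y, z, p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    abort("`x`, `y` and `z` must have equal length.")
  }
  if (n < 4L) {
    abort("Need n >= 4 for a one-controller partial correlation.")
  }
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  rz <- rank_transform(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0) {
    abort("Constant vector: partial Spearman correlation is undefined.")
  }
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    abort("The controller is rank-identical to a variable (|r| = 1): partial correlation undefined.")
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(-1, min(1, r))
  use_exact <- p_method == "exact" || (p_method == "auto" && n <= 8L)
  if (use_exact) {
    p <- exact_partial_p(rx, ry, rz, r)
    stat <- NA_real_; df <- NA_real_; used <- "exact"
  } else {
    df <- n - 3
    p <- t_approx_p(r, df)
    stat <- if (1 - r^2 <= .Machine$double.eps) sign(r) * Inf else
      r * sqrt(df / (1 - r^2))
    used <- "t"
  }
  new_rank_cor(r, p, n, "partial_spearman", "z", stat, df, used)
}

#' Screen functional categories against a response
#'
#' For every functional-category proportion column, computes the simple
#' Spearman correlation with the response (mass-specific metabolic rate, or
#' lifespan) and the body-mass-controlled partial Spearman correlation.
#' Rows with a partial p-value below `alpha` are retained and sorted in
#' descending order of the partial coefficient -- the machine-readable
#' analogue of a category-association table. Benjamini-Hochberg q-values
#' over the partial p-values are reported alongside but are not used for
#' retention (raw p at `alpha` is the primary rule).
#'
#' @param profiles A data frame or matrix of category proportions, one row
#'   per organism and one numeric column per category (include the oxic
#'   pseudo-category to rank it uniformly; see [profiles_wide()]).
#' @param q Response vector, row-aligned with `profiles`.
#' @param mass Body-mass vector (grams), row-aligned; the partial
#'   correlations control for it.
#' @param alpha Retention threshold on the partial p-value (default 0.05).
#' @param keep_all Return all categories (with a `retained` flag) instead
#'   of only the retained ones.
#' @return A tibble with columns `category`, `n`, `r_s`, `p`,
#'   `r_s_partial`, `p_partial`, `q_value`, `retained`.
#' @export
correlation_screen <- function(profiles, q, mass, alpha = 0.05,
                               keep_all = FALSE) {
  profiles <- as.data.frame(profiles)
  num <- vapply(profiles, is.numeric, logical(1))
  profiles <- profiles[, num, drop = FALSE]
  if (ncol(profiles) == 0L) {
    abort("`profiles` has no numeric category columns.")
  }
  if (length(q) != nrow(profiles) || length(mass) != nrow(profiles)) {
    abort("`q` and `mass` must be row-aligned with `profiles`.")
  }
  keep_rows <- !is.na(q) & !is.na(mass) &
    stats::complete.cases(profiles)
  if (sum(keep_rows) < nrow(profiles)) {
    inform(sprintf("Dropped %d organism(s) with missing response, mass or proportions.",
                   sum(!keep_rows)))
  }
  profiles <- profiles[keep_rows, , drop = FALSE]
  q <- q[keep_rows]; mass <- mass[keep_rows]
  if (nrow(profiles) < 4L) {
    abort("Fewer than 4 organisms: cannot run the correlation screen.")
  }
  constant <- vapply(profiles, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warn(sprintf("Dropped constant categor%s: %s",
                 if (sum(constant) == 1) "y" else "ies",
                 paste(names(profiles)[constant], collapse = ", ")))
    profiles <- profiles[, !constant, drop = FALSE]
  }
  if (ncol(profiles) == 0L) {
    abort("All categories are constant across organisms.")
  }
  rows <- purrr::imap(profiles, function(v, nm) {
    simple <- spearman(v, q, p_method = "t")
    partial <- tryCatch(
      partial_spearman(v, q, mass, p_method = "t"),
      error = function(e) {
        # e.g. category ranks coincide with mass ranks at tiny n
        warn(sprintf("Partial correlation unavailable for '%s': %s", nm,
                     conditionMessage(e)))
        list(r = NA_real_, p = NA_real_)
      }
    )
    tibble(category = nm, n = simple$n,
           r_s = simple$r, p = simple$p,
           r_s_partial = partial$r, p_partial = partial$p)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      q_value = stats::p.adjust(.data$p_partial, method = "BH"),
      retained = .data$p_partial < alpha
    ) |>
    dplyr::arrange(dplyr::desc(.data$r_s_partial))
  if (!keep_all) {
    out <- dplyr::filter(out, .data$retained)
  }
  attr(out, "alpha") <- alpha
  out
}

#' Partial correlations within subgroups
#'
#' Evaluates the body-mass-controlled (or other-controller) partial
#' Spearman correlation separately within each level of a grouping trait
#' (e.g. flight capability: volant vs non-volant). Groups with fewer than
#' four complete records, or with a degenerate (constant) variable, are
#' skipped with a warning.
#'
#' @param data A data frame.
#' @param x,y,control Column names (strings) of the two correlated
#'   variables and the controller.
#' @param group Column name of the grouping trait.
#' @inheritParams spearman
#' @return A tibble with one row per usable group level: `group`, `level`,
#'   `n`, `r_s_partial`, `p_partial`.
#' @export
subgroup_partial <- function(data, x, y, control, group,
                             p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  for (col in c(x, y, control, group)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", col))
    }
  }
  levels_ <- unique(data[[group]][!is.na(data[[group]])])
  rows <- lapply(levels_, function(lv) {
    sub <- data[!is.na(data[[group]]) & data[[group]] == lv, , drop = FALSE]
    cc <- stats::complete.cases(sub[, c(x, y, control)])
    sub <- sub[cc, , drop = FALSE]
    if (nrow(sub) < 4L) {
      warn(sprintf("Group %s = %s has n = %d (< 4); skipped.",
                   group, format(lv), nrow(sub)))
      return(NULL)
    }
    res <- tryCatch(
      partial_spearman(sub[[x]], sub[[y]], sub[[control]], p_method = p_method),
      error = function(e) {
        warn(sprintf("Group %s = %s skipped: %s", group, format(lv),
                     conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      return(NULL)
    }
    tibble(group = group, level = format(lv), n = res$n,
           r_s_partial = res$r, p_partial = res$p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(group = character(), level = character(), n = integer(),
                  r_s_partial = double(), p_partial = double())
  }
  out
}
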