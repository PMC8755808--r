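#' Spearman rank correlation between FST and elevational floor
#'
#' Tests whether population differentiation increases with a species'
#' altitudinal floor (the lowest elevation at which it occurs). The
#' correlation uses average-rank tie handling; the p-value comes from the
#' permutation distribution of the rank statistic: exact enumeration of all
#' n! orderings when n <= 10, seeded Monte-Carlo permutation otherwise (the
#' permutation count is reported either way).
#'
#' @param records Tibble with at least `species`, `fst`, `floor_m`;
#'   optionally `include` (logical) and `region`.
#' @param exclude Character vector of species labels to drop (configuration,
#'   never hard-coded).
#' @param p_method `"auto"` (exact when n <= 10), `"exact"`, or
#'   `"monte_carlo"`.
#' @param n_perm Monte-Carlo permutation count (default 9999).
#' @param seed Seed for Monte-Carlo permutation.
#' @param alternative `"greater"` (default; the directional hypothesis that
#'   differentiation rises with floor), `"two.sided"` or `"less"`.
#' @return One-row tibble: `r`, `p`, `n`, `method`, `n_perm`, `alternative`,
#'   `excluded`. With constant FST or floor, `r` and `p` are `NA` and the
#'   reason is recorded in `method`.
#' @export
spearman_fst_floor <- function(records, exclude = character(),
                               p_method = c("auto", "exact", "monte_carlo"),
                               n_perm = 9999, seed = NULL,
                               alternative = c("greater", "two.sided",
                                               "less")) {
  p_method <- match.arg(p_method)
  alternative <- match.arg(alternative)
  records <- tibble::as_tibble(records)
  if (!all(c("species", "fst", "floor_m") %in% names(records)))
    stop("records need columns species, fst, floor_m", call. = FALSE)
  if ("include" %in% names(records)) records <- records[records$include, ]
  records <- records[!records$species %in% exclude, ]
  n <- nrow(records)
  if (n < 5) stop("need >= 5 records after exclusions", call. = FALSE)
  x <- records$fst; y <- records$floor_m
  base_row <- tibble::tibble(n = n, alternative = alternative,
                             excluded = paste(exclude, collapse = ","))
  if (var(x) == 0 || var(y) == 0) {
    return(dplyr::bind_cols(tibble::tibble(r = NA_real_, p = NA_real_),
                            base_row,
                            tibble::tibble(method = "undefined (constant input)",
                                           n_perm = NA_real_)))
  }
  r <- cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  exact <- p_method == "exact" || (p_method == "auto" && n <= 10)
  if (exact && n > 10)
    stop("exact enumeration supports n <= 10", call. = FALSE)
  if (exact) {
    cnt <- cpp_spearman_perm_exact(rx, ry)
    p <- switch(alternative,
                greater = cnt[1] / cnt[4],
                less = cnt[2] / cnt[4],
                two.sided = min(1, cnt[3] / cnt[4]))
    method <- "exact permutation"
    n_perm_used <- cnt[4]
  } else {
    s_obs <- sum(rx * ry)
    center <- sum(rx) * sum(ry) / n
    perm <- run_seeded(seed, {
      vapply(seq_len(n_perm), function(i) sum(rx * sample(ry)), numeric(1))
    })
    p <- switch(alternative,
                greater = (1 + sum(perm >= s_obs - 1e-9)) / (1 + n_perm),
                less = (1 + sum(perm <= s_obs + 1e-9)) / (1 + n_perm),
                two.sided = (1 + sum(abs(perm - center) >=
                                       abs(s_obs - center) - 1e-9)) /
                  (1 + n_perm))
    method <- "Monte-Carlo permutation"
    n_perm_used <- n_perm
  }
  dplyr::bind_cols(tibble::tibble(r = r, p = p), base_row,
                   tibble::tibble(method = method, n_perm = n_perm_used))[,
    c("r", "p", "n", "method", "n_perm", "alternative", "excluded")]
}

#' FST-versus-floor scatter
#'
#' @param records As in [spearman_fst_floor()].
#' @return A ggplot.
#' @export
plot_fst_floor <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$floor_m, .data$fst)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "elevational floor (m)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
}
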