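#' Weir-Cockerham FST between two populations
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) are computed from sample
#' sizes, allele frequencies and observed heterozygosities following Weir &
#' Cockerham's estimator for two alleles; the multilocus estimate is the
#' ratio of sums \eqn{\hat\theta = \sum a / \sum (a + b + c)} (not the mean of
#' per-site ratios). Sites monomorphic in the pooled sample have undefined
#' components and are excluded from the sums (and counted).
#'
#' @param geno An `mg_geno`.
#' @param pop_labels Optional population label per sample (defaults to the
#'   sample table's `population`); exactly two populations with at least two
#'   diploids each.
#' @return An object of class `mg_fst`: `theta` (multilocus), `theta_clamped`
#'   (negative estimates clamped at 0 for convenience), per-site tibble
#'   `by_site` with components and per-site estimates, `pair`, `n_sites_used`
#'   and `n_excluded`.
#' @export
wc_fst <- function(geno, pop_labels = NULL) {
  stopifnot(inherits(geno, "mg_geno"))
  pop_labels <- pop_labels %||% geno$samples$population
  comp <- wc_components(geno$geno, pop_labels)
  used <- comp$defined
  theta <- sum(comp$a[used]) / sum((comp$a + comp$b + comp$c)[used])
  by_site <- tibble::tibble(
    chrom = geno$sites$chrom, pos = geno$sites$pos,
    a = comp$a, b = comp$b, c = comp$c,
    theta_site = ifelse(used, comp$a / (comp$a + comp$b + comp$c), NA_real_),
    used = used)
  structure(list(theta = theta, theta_clamped = max(theta, 0),
                 by_site = by_site,
                 pair = paste(comp$pops, collapse = " vs "),
                 n_sites_used = sum(used), n_excluded = sum(!used)),
            class = "mg_fst")
}

# Weir & Cockerham (1984) two-allele variance components for r = 2
# populations; vectorized over sites. Returns per-site a, b, c and a
# defined flag (FALSE for sites monomorphic in the pooled sample or with an
# undersized population after missingness).
wc_components <- function(G, pop_labels) {
  pops <- unique(pop_labels)
  if (length(pops) != 2)
    stop("wc_fst needs exactly two populations", call. = FALSE)
  idx <- lapply(pops, function(p) which(pop_labels == p))
  if (any(lengths(idx) < 2))
    stop("each population needs >= 2 diploids", call. = FALSE)
  r <- 2
  n_i <- sapply(idx, function(j) rowSums(!is.na(G[, j, drop = FALSE])))
  p_i <- sapply(idx, function(j)
    rowSums(G[, j, drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(idx, function(j)
    rowSums(G[, j, drop = FALSE] == 1L, na.rm = TRUE)) / n_i
  if (is.null(dim(n_i))) { # single-site edge
    n_i <- matrix(n_i, 1); p_i <- matrix(p_i, 1); h_i <- matrix(h_i, 1)
  }
  C <- rowSums(n_i)
  nbar <- C / r
  nc <- (C - rowSums(n_i^2) / C) / (r - 1)
  pbar <- rowSums(n_i * p_i) / C
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / C
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  defined <- pbar > 0 & pbar < 1 & apply(n_i >= 2, 1, all)
  list(a = a, b = b, c = c_, defined = defined, pops = pops)
}

#' @export
print.mg_fst <- function(x, ...) {
  cat("<mg_fst> ", x$pair, ": multilocus theta = ", signif(x$theta, 4),
      " (", x$n_sites_used, " sites used, ", x$n_excluded, " excluded)\n",
      sep = "")
  invisible(x)
}

#' @describeIn wc_fst One-row summary tibble.
#' @param x An `mg_fst`.
#' @param ... Unused.
#' @export
glance.mg_fst <- function(x, ...) {
  tibble::tibble(pair = x$pair, theta = x$theta,
                 theta_clamped = x$theta_clamped,
                 n_sites_used = x$n_sites_used, n_excluded = x$n_excluded)
}

#' Pairwise FST between strata (e.g. elevation bands)
#'
#' Applies the same Weir-Cockerham estimator to every pair of strata. Strata
#' with fewer than two diploids are reported as undefined rather than dropped
#' silently; a single stratum yields an empty table with a warning.
#'
#' @param geno An `mg_geno`.
#' @param stratum_labels One label per sample (e.g. elevation bands built from
#'   `elevation_m`).
#' @return Tibble with one row per stratum pair: sizes, `theta`,
#'   `theta_clamped`, `n_sites_used` and a `defined` flag.
#' @export
fst_by_stratum <- function(geno, stratum_labels) {
  stopifnot(inherits(geno, "mg_geno"))
  strata <- unique(stratum_labels)
  if (length(strata) < 2) {
    warning("fewer than two strata; returning empty table")
    return(tibble::tibble(stratum1 = character(), stratum2 = character(),
                          n1 = integer(), n2 = integer(),
                          theta = numeric(), theta_clamped = numeric(),
                          n_sites_used = integer(), defined = logical()))
  }
  pairs <- utils::combn(strata, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    j <- which(stratum_labels %in% pr)
    n1 <- sum(stratum_labels == pr[1]); n2 <- sum(stratum_labels == pr[2])
    if (n1 < 2 || n2 < 2) {
      return(tibble::tibble(stratum1 = as.character(pr[1]),
                            stratum2 = as.character(pr[2]),
                            n1 = n1, n2 = n2, theta = NA_real_,
                            theta_clamped = NA_real_, n_sites_used = NA_integer_,
                            defined = FALSE))
    }
    f <- wc_fst(subset_geno(geno, j = j), stratum_labels[j])
    tibble::tibble(stratum1 = as.character(pr[1]),
                   stratum2 = as.character(pr[2]),
                   n1 = n1, n2 = n2, theta = f$theta,
                   theta_clamped = f$theta_clamped,
                   n_sites_used = f$n_sites_used, defined = TRUE)
  })
}

#' Label-permutation test for FST
#'
#' One-sided test of theta > 0 by permuting population labels across samples.
#'
#' @param geno An `mg_geno`.
#' @param pop_labels Labels (two populations).
#' @param n_perm Number of permutations (default 199).
#' @param seed Integer seed.
#' @return List with `theta`, `p` (one-sided, add-one corrected) and `n_perm`.
#' @export
fst_permutation_test <- function(geno, pop_labels = NULL, n_perm = 199, seed) {
  pop_labels <- pop_labels %||% geno$samples$population
  obs <- wc_fst(geno, pop_labels)$theta
  perm <- run_seeded(seed, {
    vapply(seq_len(n_perm), function(i)
      wc_fst(geno, sample(pop_labels))$theta, numeric(1))
  })
  list(theta = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm), n_perm = n_perm)
}
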