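#' Pairwise kinship from called genotypes (KING-robust)
#'
#' Estimates the kinship coefficient phi for every sample pair from counts of
#' shared heterozygotes and opposite homozygotes:
#' \deqn{\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} counts sites at which both samples are heterozygous,
#' \eqn{N_{AA,aa}} counts opposite homozygotes, and \eqn{N_{Aa}(\cdot)} counts
#' heterozygous sites per sample (within the pair's shared non-missing sites).
#' The estimator needs no allele-frequency model, is invariant to ref/alt
#' label swaps, and is scaled so duplicates give ~0.5, parent-offspring and
#' full sibs ~0.25, half-sibs ~0.125 and unrelated panmictic pairs ~0.
#'
#' @param geno An `mg_geno` with biallelic genotypes (run [filter_sites()]
#'   first; missing calls are tolerated pairwise).
#' @return An object of class `mg_kinship`: `phi` (symmetric matrix, diagonal
#'   reported as 0.5 by convention), `n_informative` (pairwise count of shared
#'   non-missing sites; pairs with fewer than 100 are flagged unreliable),
#'   `n_missing` per sample, and `samples`.
#' @export
kinship_matrix <- function(geno) {
  stopifnot(inherits(geno, "mg_geno"))
  if (n_samples(geno) < 2) stop("need >= 2 samples", call. = FALSE)
  G <- geno$geno
  het <- (G == 1L); het[is.na(het)] <- FALSE
  hom0 <- (G == 0L); hom0[is.na(hom0)] <- FALSE
  hom2 <- (G == 2L); hom2[is.na(hom2)] <- FALSE
  called <- !is.na(G)
  storage.mode(het) <- storage.mode(hom0) <- storage.mode(hom2) <-
    storage.mode(called) <- "numeric"
  n_both_het <- crossprod(het)
  n_opp <- crossprod(hom0, hom2) + crossprod(hom2, hom0)
  # heterozygote counts restricted to each pair's shared called sites
  het_shared_i <- crossprod(het, called)          # rows i: het(i) & called(j)
  denom <- het_shared_i + t(het_shared_i)
  n_inf <- crossprod(called)
  phi <- (n_both_het - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- 0.5
  dimnames(phi) <- list(geno$samples$sample_id, geno$samples$sample_id)
  dimnames(n_inf) <- dimnames(phi)
  structure(list(phi = phi, n_informative = n_inf,
                 n_missing = colSums(is.na(G)),
                 samples = geno$samples),
            class = "mg_kinship")
}

#' @export
print.mg_kinship <- function(x, ...) {
  n <- nrow(x$phi)
  off <- x$phi[upper.tri(x$phi)]
  cat("<mg_kinship> ", n, " samples; off-diagonal phi range [",
      signif(min(off, na.rm = TRUE), 3), ", ",
      signif(max(off, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

#' @describeIn kinship_matrix Long-format pairs: `sample1`, `sample2`, `phi`,
#'   `n_sites`, `unreliable` (fewer than 100 informative sites or undefined
#'   phi).
#' @param x An `mg_kinship`.
#' @param ... Unused.
#' @export
tidy.mg_kinship <- function(x, ...) {
  ids <- rownames(x$phi)
  pairs <- which(upper.tri(x$phi), arr.ind = TRUE)
  tibble::tibble(
    sample1 = ids[pairs[, 1]], sample2 = ids[pairs[, 2]],
    phi = x$phi[pairs],
    n_sites = x$n_informative[pairs],
    unreliable = x$n_informative[pairs] < 100 | is.na(x$phi[pairs]))
}

#' Flag and greedily exclude close relatives
#'
#' Pairs with kinship above `threshold` are considered closely related. The
#' exclusion set is built greedily: repeatedly remove the sample participating
#' in the most above-threshold pairs until none remain; ties are broken toward
#' the sample with more missing genotype calls, then the lexicographically
#' larger id. For an isolated related pair this drops exactly one member.
#'
#' @param kin An `mg_kinship`.
#' @param threshold Kinship threshold (default 0.06).
#' @return Character vector of excluded sample ids, with attribute
#'   `flagged_pairs` (tibble of above-threshold pairs).
#' @export
flag_related <- function(kin, threshold = 0.06) {
  stopifnot(inherits(kin, "mg_kinship"))
  pairs <- tidy(kin)
  flagged <- pairs[!is.na(pairs$phi) & pairs$phi > threshold, ]
  excluded <- character()
  edges <- flagged[, c("sample1", "sample2")]
  n_missing <- kin$n_missing
  while (nrow(edges)) {
    ids <- c(edges$sample1, edges$sample2)
    deg <- sort(table(ids), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    if (length(top) > 1) {
      miss <- n_missing[top]
      top <- top[miss == max(miss)]
      top <- max(top)  # lexicographically larger id
    }
    excluded <- c(excluded, top)
    edges <- edges[edges$sample1 != top & edges$sample2 != top, , drop = FALSE]
  }
  structure(excluded, flagged_pairs = flagged)
}
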