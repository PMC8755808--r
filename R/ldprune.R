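#' Linkage-disequilibrium pruning of SNPs
#'
#' Sliding-window greedy pruning on genotype-dosage correlations (composite
#' LD), with the indep-pairwise semantics familiar from PLINK: windows of
#' `window_sites` consecutive candidate sites advanced by `step_sites`; within
#' a window, for every retained pair with squared correlation above
#' `r2_threshold` the later site is removed and the earlier kept
#' (deterministic). Monomorphic sites have undefined correlation, which is
#' treated as 0, so they are always retained.
#'
#' @param geno An `mg_geno` with complete genotypes.
#' @param window_sites Window size in variant count (default 100).
#' @param step_sites Variant count by which the window advances (default 5).
#' @param r2_threshold Squared-correlation threshold (default 0.5).
#' @return Integer vector of retained site indices (row indices into
#'   `geno$sites`).
#' @export
ld_prune <- function(geno, window_sites = 100, step_sites = 5,
                     r2_threshold = 0.5) {
  stopifnot(inherits(geno, "mg_geno"))
  if (anyNA(geno$geno)) stop("ld_prune needs complete genotypes", call. = FALSE)
  S <- n_sites(geno)
  if (S < 2) return(seq_len(S))
  removed <- logical(S)
  G <- geno$geno
  for (start in seq(1, S, by = step_sites)) {
    w <- start:min(start + window_sites - 1, S)
    cand <- w[!removed[w]]
    if (length(cand) < 2) next
    cc <- suppressWarnings(cor(G[cand, , drop = FALSE] |> t()))
    cc[is.na(cc)] <- 0
    r2 <- cc^2
    for (a in seq_len(length(cand) - 1)) {
      if (removed[cand[a]]) next
      hits <- which(r2[a, ] > r2_threshold)
      hits <- hits[hits > a]
      if (length(hits)) removed[cand[hits]] <- TRUE
    }
    if (start + window_sites - 1 >= S) break
  }
  which(!removed)
}
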