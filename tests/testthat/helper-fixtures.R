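# Shared fixtures and independent oracles. Everything here is built in code
# at test time; oracles deliberately re-derive quantities through a different
# code path than the package implementation.

# A small genotype matrix from raw pieces (complete, biallelic by default).
make_geno <- function(dosage, pops = NULL, depth = NULL, qual = NULL,
                      chrom = "chr1") {
  S <- nrow(dosage); N <- ncol(dosage)
  pops <- pops %||% rep("popA", N)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(N)),
    population = pops, elevation_m = NA_real_, species = "spX")
  sites <- tibble::tibble(
    chrom = rep(chrom, S), pos = seq_len(S) * 10L,
    ref = rep("A", S), alt = rep("T", S),
    qual = qual %||% rep(60, S), is_indel = FALSE, dist_indel = Inf,
    multiallelic = FALSE)
  depth <- depth %||% matrix(30, S, N)
  storage.mode(dosage) <- "integer"
  geno_matrix(sites, dosage, depth, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir & Cockerham (1984) components evaluated site-by-site in plain loops:
# the arithmetic oracle against which the vectorized estimator is checked.
oracle_wc_theta <- function(dosage, pops) {
  labs <- unique(pops)
  stopifnot(length(labs) == 2)
  A <- 0; ABC <- 0
  per_site <- numeric(0)
  for (s in seq_len(nrow(dosage))) {
    g <- dosage[s, ]
    n <- c(sum(pops == labs[1]), sum(pops == labs[2]))
    p <- c(sum(g[pops == labs[1]]) / (2 * n[1]),
           sum(g[pops == labs[2]]) / (2 * n[2]))
    h <- c(mean(g[pops == labs[1]] == 1), mean(g[pops == labs[2]] == 1))
    pbar_all <- sum(n * p) / sum(n)
    if (pbar_all <= 0 || pbar_all >= 1) { per_site <- c(per_site, NA); next }
    r <- 2
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    ssq <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; ABC <- ABC + a + b + cc
    per_site <- c(per_site, a / (a + b + cc))
  }
  list(theta = A / ABC, per_site = per_site)
}

# Brute-force joint SFS by per-site counting with nested loops.
oracle_joint_sfs <- function(dosage, pops) {
  labs <- unique(pops)
  n_hap <- vapply(labs, function(p) 2L * sum(pops == p), integer(1))
  arr <- array(0, dim = unname(n_hap) + 1L)
  for (s in seq_len(nrow(dosage))) {
    counts <- vapply(labs, function(p) sum(dosage[s, pops == p]), numeric(1))
    ix <- matrix(counts + 1, 1)
    arr[ix] <- arr[ix] + 1
  }
  arr
}

# Greedy windowed LD pruning re-implemented naively (site-by-site loops).
oracle_ld_prune <- function(dosage, window, step, r2max) {
  S <- nrow(dosage)
  removed <- rep(FALSE, S)
  for (start in seq(1, S, by = step)) {
    w <- start:min(start + window - 1, S)
    cand <- w[!removed[w]]
    if (length(cand) < 2) next
    for (ai in seq_along(cand)) {
      for (bi in seq_along(cand)) {
        if (bi <= ai) next
        i <- cand[ai]; j <- cand[bi]
        if (removed[i] || removed[j]) next
        r <- suppressWarnings(cor(dosage[i, ], dosage[j, ]))
        if (!is.na(r) && r^2 > r2max) removed[j] <- TRUE
      }
    }
    if (start + window - 1 >= S) break
  }
  which(!removed)
}

# Minimal vertex covers of a small graph by exhaustive search.
oracle_min_vertex_cover_size <- function(edges_mat) {
  verts <- unique(as.vector(edges_mat))
  n <- length(verts)
  best <- n
  for (k in 0:n) {
    combos <- utils::combn(verts, k, simplify = FALSE)
    for (cv in combos) {
      covered <- apply(edges_mat, 1, function(e) any(e %in% cv))
      if (all(covered)) return(k)
    }
  }
  best
}
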