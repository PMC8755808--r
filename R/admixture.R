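#' Maximum-likelihood admixture proportions
#'
#' Fits the classic admixture model: each sample's genome is a mixture over K
#' clusters with ancestry proportions Q (rows summing to 1) and per-cluster
#' allele frequencies P; each dosage g at a site is binomial with success
#' probability `q . p`. The likelihood is maximized by EM (block relaxation
#' over Q and P), whose log-likelihood is non-decreasing at every iteration.
#' Replicate runs differ only by the random-initialization seed, so the
#' replicate dispersion needed by the Evanno statistic comes from multi-start
#' variation.
#'
#' @param geno An `mg_geno` with complete genotypes, ideally LD-pruned.
#' @param K Number of clusters (`1 <= K <=` number of samples).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood gain (default 1e-6).
#' @return An object of class `mg_admixture`: `Q` (tibble samples x K), `P`
#'   (K x sites matrix, entries clamped inside `[1e-6, 1 - 1e-6]`), `lnL`,
#'   `lnL_path`, `K`, `seed`, `iterations`, `converged`. `lnL` includes the
#'   binomial coefficient term, so at K = 1 it equals the closed-form binomial
#'   log-likelihood at the pooled allele frequencies.
#' @export
admixture_fit <- function(geno, K, seed, max_iter = 500, tol = 1e-6) {
  stopifnot(inherits(geno, "mg_geno"))
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n_samples(geno))
    stop("K exceeds the number of samples", call. = FALSE)
  if (anyNA(geno$geno))
    stop("admixture_fit needs complete genotypes", call. = FALSE)
  G <- dosage_t(geno)          # N x L
  N <- nrow(G); L <- ncol(G)
  eps <- 1e-6
  pool <- pmin(pmax(colMeans(G) / 2, eps), 1 - eps)
  const <- sum(lchoose(2, G))  # binomial coefficient term (parameter-free)
  init <- run_seeded(seed, {
    Q <- matrix(rexp(N * K), N, K)
    Q <- Q / rowSums(Q)
    P <- matrix(pmin(pmax(
      rep(pool, each = K) + runif(K * L, -0.1, 0.1), eps), 1 - eps), K, L)
    list(Q = Q, P = P)
  })
  Q <- init$Q; P <- init$P
  loglik <- function(Fmat) {
    sum(G * log(Fmat) + (2 - G) * log1p(-Fmat)) + const
  }
  Fmat <- Q %*% P
  ll <- loglik(Fmat)
  path <- ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # E-step responsibilities folded into multiplicative updates
    A <- G / Fmat          # N x L
    B <- (2 - G) / (1 - Fmat)
    # per-cluster expected ancestral-allele and derived-allele gamete counts
    EA <- (A %*% t(P)) * Q       # N x K: sum_l g * q p / f
    EB <- (B %*% t((1 - P))) * Q
    Qn <- (EA + EB) / (2 * L)
    Qn <- Qn / rowSums(Qn)
    num <- (t(Q) %*% A) * P      # K x L
    den <- num + (t(Q) %*% B) * (1 - P)
    Pn <- num / den
    Pn <- pmin(pmax(Pn, eps), 1 - eps)
    Q <- Qn; P <- Pn
    Fmat <- Q %*% P
    ll_new <- loglik(Fmat)
    path <- c(path, ll_new)
    if (is.finite(ll) && ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  Qt <- tibble::as_tibble(Q, .name_repair = ~ paste0("Q", seq_len(K)))
  Qt <- dplyr::bind_cols(
    tibble::tibble(sample_id = geno$samples$sample_id,
                   population = geno$samples$population), Qt)
  structure(list(Q = Qt, P = P, lnL = ll, lnL_path = path, K = K,
                 seed = seed, iterations = iter, converged = converged),
            class = "mg_admixture")
}

#' @export
print.mg_admixture <- function(x, ...) {
  cat("<mg_admixture> K = ", x$K, ", lnL = ", format(x$lnL), " (",
      x$iterations, " iterations", if (x$converged) ", converged", ")\n",
      sep = "")
  invisible(x)
}

#' @describeIn admixture_fit Long-format ancestry proportions.
#' @param x An `mg_admixture`.
#' @param ... Unused.
#' @export
tidy.mg_admixture <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("Q"),
                      names_to = "cluster", values_to = "proportion")
}

#' @describeIn admixture_fit One-row fit summary.
#' @export
glance.mg_admixture <- function(x, ...) {
  tibble::tibble(K = x$K, lnL = x$lnL, iterations = x$iterations,
                 converged = x$converged, seed = x$seed)
}

#' @describeIn admixture_fit Stacked ancestry barplot.
#' @param object An `mg_admixture`.
#' @export
autoplot.mg_admixture <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$proportion,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~ .data$population, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Evanno delta-K over replicate admixture runs
#'
#' Summarizes replicate clustering fits across a K range by the second-order
#' rate of change of the mean log-likelihood, normalized by the replicate
#' standard deviation: `deltaK(K) = |m[L(K+1)] - 2 m[L(K)] + m[L(K-1)]| /
#' s[L(K)]`. The statistic is undefined at the endpoints of the K range; the
#' supported cluster number is the interior K maximizing deltaK. A zero
#' replicate standard deviation is floored at `sd_floor` (recorded in the
#' table) rather than crashing.
#'
#' @param runs List of `mg_admixture` fits (several replicates per K), or a
#'   data frame with columns `K` and `lnL`.
#' @param sd_floor Floor applied to zero replicate standard deviations
#'   (default 1e-6).
#' @return An object of class `mg_evanno`: `table` (per-K tibble with
#'   `n_runs`, `mean_lnL`, `sd_lnL`, `sd_floored`, `delta_k`) and `best_k`
#'   (`NA` when no interior K exists).
#' @export
evanno_delta_k <- function(runs, sd_floor = 1e-6) {
  d <- if (is.data.frame(runs)) {
    tibble::as_tibble(runs)
  } else {
    purrr::map_dfr(runs, function(r) tibble::tibble(K = r$K, lnL = r$lnL))
  }
  if (!all(c("K", "lnL") %in% names(d)))
    stop("runs must provide K and lnL", call. = FALSE)
  tab <- d |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(n_runs = dplyr::n(), mean_lnL = mean(.data$lnL),
                     sd_lnL = sd(.data$lnL), .groups = "drop") |>
    dplyr::arrange(.data$K)
  ks <- tab$K
  if (length(ks) < 3 || any(diff(ks) != 1))
    if (length(ks) < 3)
      warning("need >= 3 consecutive K values; delta-K undefined everywhere")
  if (any(tab$n_runs < 2))
    warning("fewer than 2 replicates for some K; sd is undefined there")
  tab$sd_floored <- is.na(tab$sd_lnL) | tab$sd_lnL < sd_floor
  sd_use <- ifelse(tab$sd_floored, sd_floor, tab$sd_lnL)
  m <- tab$mean_lnL
  n <- length(m)
  dk <- rep(NA_real_, n)
  if (n >= 3)
    dk[2:(n - 1)] <- abs(m[3:n] - 2 * m[2:(n - 1)] + m[1:(n - 2)]) /
      sd_use[2:(n - 1)]
  tab$delta_k <- dk
  best_k <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  structure(list(table = tab, best_k = best_k), class = "mg_evanno")
}

#' @export
print.mg_evanno <- function(x, ...) {
  print(as.data.frame(x$table))
  cat("best K:", x$best_k, "\n")
  invisible(x)
}

#' @describeIn evanno_delta_k The per-K table.
#' @param x An `mg_evanno`.
#' @param ... Unused.
#' @export
tidy.mg_evanno <- function(x, ...) x$table

#' @describeIn evanno_delta_k Delta-K profile plot.
#' @param object An `mg_evanno`.
#' @export
autoplot.mg_evanno <- function(object, ...) {
  d <- object$table[!is.na(object$table$delta_k), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$K, .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}
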