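#' Principal component analysis of genotype dosages
#'
#' Eigen-decomposition of the covariance of centered, variance-standardized
#' dosages (samples as observations). Zero-variance sites are skipped. Axis
#' signs are fixed by convention (first nonzero loading positive), making the
#' result deterministic.
#'
#' @param geno An `mg_geno` with complete genotypes, ideally LD-pruned.
#' @param n_axes Number of leading axes to return (default 10, capped by the
#'   data).
#' @return An object of class `mg_pca`: `scores` (tibble with `sample_id`,
#'   `population` and `PC*` columns), `var_explained`, `loadings`.
#' @export
pca_genotypes <- function(geno, n_axes = 10) {
  stopifnot(inherits(geno, "mg_geno"))
  if (n_samples(geno) < 3) stop("need >= 3 samples", call. = FALSE)
  if (anyNA(geno$geno)) stop("pca needs complete genotypes", call. = FALSE)
  X <- dosage_t(geno)  # samples x sites
  v <- apply(X, 2, var)
  keep <- which(v > 0)
  n_axes <- min(n_axes, length(keep), nrow(X) - 1)
  if (!length(keep) || n_axes < 1) {
    scores <- tibble::tibble(sample_id = geno$samples$sample_id,
                             population = geno$samples$population,
                             PC1 = 0, PC2 = 0)
    return(structure(list(scores = scores, var_explained = c(0, 0),
                          loadings = NULL), class = "mg_pca"))
  }
  Xs <- scale(X[, keep, drop = FALSE], center = TRUE, scale = TRUE)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  for (a in seq_len(ncol(rot))) {
    nz <- which(abs(rot[, a]) > 1e-12)[1]
    if (!is.na(nz) && rot[nz, a] < 0) {
      rot[, a] <- -rot[, a]
      pc$x[, a] <- -pc$x[, a]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_axes), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = geno$samples$sample_id,
                   population = geno$samples$population), scores)
  structure(list(scores = scores, var_explained = ve[seq_len(n_axes)],
                 loadings = rot), class = "mg_pca")
}

#' @export
print.mg_pca <- function(x, ...) {
  cat("<mg_pca> ", nrow(x$scores), " samples; leading axes explain ",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn pca_genotypes Scores tibble.
#' @param x An `mg_pca`.
#' @param ... Unused.
#' @export
tidy.mg_pca <- function(x, ...) x$scores

#' @describeIn pca_genotypes Scatter of the two leading axes, colored by
#'   population.
#' @param object An `mg_pca`.
#' @export
autoplot.mg_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  colour = "population") +
    ggplot2::theme_minimal()
}
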