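#' Genotype matrix container
#'
#' The substrate of every statistic in the package: biallelic diploid
#' genotypes as an integer alt-allele dosage matrix (sites x samples, values
#' 0/1/2 or `NA`), per-sample read depth, a sites tibble with positional and
#' quality metadata, and a samples tibble (`sample_id`, `population`,
#' `elevation_m`, `species`).
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `is_indel`, `dist_indel` (bp to nearest indel record, `Inf` if
#'   none), `multiallelic`.
#' @param geno Integer matrix, sites x samples.
#' @param depth Numeric matrix of per-sample read depth, same shape.
#' @param samples Tibble of sample records; `sample_id` must be unique and
#'   match the genotype columns.
#' @return An object of class `mg_geno`.
#' @export
geno_matrix <- function(sites, geno, depth, samples) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$sample_id))
    abort_field("samples", "sample_id must be unique")
  if (!is.matrix(geno) || nrow(geno) != nrow(sites) ||
      ncol(geno) != nrow(samples))
    abort_field("geno", "must be a sites x samples matrix")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    abort_field("geno", "dosages must be 0, 1, 2 or NA")
  if (!is.null(depth) && (nrow(depth) != nrow(geno) || ncol(depth) != ncol(geno)))
    abort_field("depth", "must match the genotype matrix shape")
  # positions strictly increasing within a chromosome
  if (nrow(sites) > 1) {
    ok <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
    if (!all(unlist(ok)))
      abort_field("sites", "positions must be strictly increasing within a chromosome")
  }
  colnames(geno) <- samples$sample_id
  if (!is.null(depth)) colnames(depth) <- samples$sample_id
  structure(list(sites = sites, geno = geno, depth = depth, samples = samples),
            class = "mg_geno")
}

#' @export
print.mg_geno <- function(x, ...) {
  cat("<mg_geno> ", nrow(x$sites), " sites x ", nrow(x$samples), " samples (",
      sum(is.na(x$geno)), " missing calls)\n", sep = "")
  pops <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mg_geno <- function(x) dim(x$geno)

n_sites <- function(geno) nrow(geno$geno)
n_samples <- function(geno) ncol(geno$geno)

# subset sites (i) and/or samples (j) keeping all slots aligned
subset_geno <- function(x, i = NULL, j = NULL) {
  if (!is.null(i)) {
    x$sites <- x$sites[i, , drop = FALSE]
    x$geno <- x$geno[i, , drop = FALSE]
    if (!is.null(x$depth)) x$depth <- x$depth[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    x$samples <- x$samples[j, , drop = FALSE]
    x$geno <- x$geno[, j, drop = FALSE]
    if (!is.null(x$depth)) x$depth <- x$depth[, j, drop = FALSE]
  }
  x
}

#' Drop samples from a genotype matrix
#'
#' Typically used with the exclusion list from [flag_related()].
#'
#' @param geno An `mg_geno`.
#' @param sample_ids Character vector of sample ids to remove.
#' @return The reduced `mg_geno`.
#' @export
drop_samples <- function(geno, sample_ids) {
  keep <- !geno$samples$sample_id %in% sample_ids
  subset_geno(geno, j = which(keep))
}

# dosage matrix with samples as rows (the orientation most statistics want)
dosage_t <- function(geno) t(geno$geno)
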