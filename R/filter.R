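#' Site filter configuration
#'
#' Encodes the standard resequencing site filters: per-sample read depth
#' within `[min_depth, max_depth]`, site quality at least `min_qual`,
#' exclusion of sites within `indel_proximity_bp` of an indel record, only
#' biallelic SNPs, and complete genotypes across all individuals.
#'
#' The depth rule is applied per sample by default (a site fails if any
#' sample's depth falls outside the bounds, consistent with requiring a
#' genotype in every individual); `depth_rule = "site_sum"` instead compares
#' the summed depth across samples to the same bounds.
#'
#' @param min_depth,max_depth Read-depth bounds (defaults 10 and 100; a site
#'   with depth 9 fails, "less than 10").
#' @param min_qual Minimum Phred site quality (default 20; QUAL 19.9 fails,
#'   QUAL 20.0 passes).
#' @param indel_proximity_bp Symmetric exclusion window around indel records
#'   (default 5 bp).
#' @param biallelic_only Drop multi-allelic records (default `TRUE`).
#' @param require_complete Drop sites with any missing genotype (default
#'   `TRUE`).
#' @param depth_rule `"per_sample"` (default) or `"site_sum"`.
#' @return An object of class `mg_filter_config`.
#' @export
site_filter_config <- function(min_depth = 10, max_depth = 100, min_qual = 20,
                               indel_proximity_bp = 5, biallelic_only = TRUE,
                               require_complete = TRUE,
                               depth_rule = c("per_sample", "site_sum")) {
  depth_rule <- match.arg(depth_rule)
  if (min_depth > max_depth) abort_field("min_depth", "must be <= max_depth")
  if (min(min_depth, max_depth, min_qual, indel_proximity_bp) < 0)
    abort_field("thresholds", "all thresholds must be >= 0")
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_qual = min_qual,
                 indel_proximity_bp = indel_proximity_bp,
                 biallelic_only = biallelic_only,
                 require_complete = require_complete,
                 depth_rule = depth_rule),
            class = "mg_filter_config")
}

#' Apply site filters to a genotype matrix
#'
#' Surviving sites satisfy all configured rules simultaneously; the rule order
#' never affects the surviving set, and the removal report attributes each
#' removed site to every rule it violates (so per-rule counts can sum to more
#' than the number of removed sites). Filtering is idempotent.
#'
#' @param geno An `mg_geno`.
#' @param cfg An [site_filter_config()].
#' @return A list: `geno` (the filtered `mg_geno`), `removed` (tibble of
#'   per-rule violation counts), `n_removed`, and `violations` (logical
#'   site x rule matrix).
#' @export
filter_sites <- function(geno, cfg = site_filter_config()) {
  stopifnot(inherits(geno, "mg_geno"), inherits(cfg, "mg_filter_config"))
  S <- n_sites(geno)
  viol <- matrix(FALSE, S, 5,
                 dimnames = list(NULL, c("depth", "qual", "indel_proximity",
                                         "not_biallelic", "missing_call")))
  if (!is.null(geno$depth)) {
    if (cfg$depth_rule == "per_sample") {
      bad <- geno$depth < cfg$min_depth | geno$depth > cfg$max_depth
      viol[, "depth"] <- rowSums(bad, na.rm = TRUE) > 0 | rowSums(is.na(bad)) > 0
    } else {
      tot <- rowSums(geno$depth, na.rm = TRUE)
      viol[, "depth"] <- tot < cfg$min_depth | tot > cfg$max_depth
    }
  }
  viol[, "qual"] <- is.na(geno$sites$qual) | geno$sites$qual < cfg$min_qual
  viol[, "indel_proximity"] <- geno$sites$is_indel |
    geno$sites$dist_indel <= cfg$indel_proximity_bp
  if (cfg$biallelic_only)
    viol[, "not_biallelic"] <- geno$sites$multiallelic
  if (cfg$require_complete)
    viol[, "missing_call"] <- rowSums(is.na(geno$geno)) > 0 &
      !geno$sites$multiallelic
  # a multi-allelic record's dosages are NA by construction; do not double-count
  keep <- rowSums(viol) == 0
  removed <- tibble::tibble(rule = colnames(viol),
                            n = unname(colSums(viol[!keep, , drop = FALSE])))
  if (!any(keep))
    message("filter_sites: no sites survive the configured filters")
  list(geno = subset_geno(geno, i = which(keep)), removed = removed,
       n_removed = sum(!keep), violations = viol)
}

#' Write the per-rule removal report
#'
#' @param filtered Result of [filter_sites()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(filtered, path) {
  readr::write_tsv(filtered$removed, path)
  invisible(path)
}
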