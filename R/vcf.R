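#' Write a genotype matrix to a VCF v4.2 file
#'
#' Emits CHROM/POS (1-based), REF/ALT, QUAL and per-sample `GT:DP` records.
#' Genotypes are written unphased (`0/0`, `0/1`, `1/1`, `./.`). With the same
#' input the output is byte-identical across runs.
#'
#' @param geno An `mg_geno`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "mg_geno"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=montgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples$sample_id), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno$geno), ncol(geno$geno))
  ok <- !is.na(geno$geno)
  gt[ok] <- gt_code[geno$geno[ok] + 1L]
  dp <- if (is.null(geno$depth)) {
    matrix(".", nrow(geno$geno), ncol(geno$geno))
  } else {
    format(geno$depth, trim = TRUE, scientific = FALSE)
  }
  cells <- matrix(paste(gt, dp, sep = ":"), nrow(geno$geno))
  body <- paste(
    geno$sites$chrom, geno$sites$pos, ".",
    geno$sites$ref, geno$sites$alt,
    ifelse(is.na(geno$sites$qual), ".",
           formatC(geno$sites$qual, format = "f", digits = 1)),
    "PASS", ".", "GT:DP",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write / read the sample map
#'
#' The sample map is a TSV with columns `sample_id`, `population`,
#' `elevation_m`, `species`.
#'
#' @param samples Tibble of sample records.
#' @param path File path.
#' @return `write_sample_map()`: `path` invisibly; `read_sample_map()`: a
#'   tibble.
#' @export
write_sample_map <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "population", "elevation_m",
                               "species")], path)
  invisible(path)
}

#' @rdname write_sample_map
#' @export
read_sample_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    elevation_m = readr::col_double(),
    species = readr::col_character()))
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 with `GT` (and optionally `DP`) FORMAT fields. Indel
#' records are retained only to compute each SNP's distance to the nearest
#' indel, then excluded from the SNP matrix. Records with more than one ALT
#' allele are carried with a `multiallelic` flag (their dosages are `NA`) so
#' that [filter_sites()] can remove and count them.
#'
#' @param path VCF file path.
#' @param sample_map Tibble as returned by [read_sample_map()], or a path to
#'   one. Every VCF sample must appear in the map.
#' @return An `mg_geno`.
#' @export
read_vcf <- function(path, sample_map) {
  if (is.character(sample_map)) sample_map <- read_sample_map(sample_map)
  sample_map <- tibble::as_tibble(sample_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing_map <- setdiff(vcf_samples, sample_map$sample_id)
  if (length(missing_map))
    stop("VCF samples absent from the sample map: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  samples <- sample_map[match(vcf_samples, sample_map$sample_id), ]
  pos <- as.integer(fix$POS)
  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt)
  first_alt <- sub(",.*", "", alt)
  is_indel <- nchar(ref) != 1L | (nchar(first_alt) != 1L & !multi) |
    (multi & vapply(strsplit(alt, ","), function(a) any(nchar(a) != 1L),
                    logical(1)))
  # distance to nearest indel record, per chromosome
  dist_indel <- rep(Inf, length(pos))
  for (ch in unique(fix$CHROM)) {
    ix <- which(fix$CHROM == ch)
    ind <- ix[is_indel[ix]]
    if (!length(ind)) next
    for (i in ix) dist_indel[i] <- min(abs(pos[i] - pos[ind]))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  flat <- known[gt_raw]
  bad <- !is.na(gt_raw) & is.na(flat) & gt_raw != "./." & gt_raw != ".|." &
    !grepl("^\\.", gt_raw)
  bad <- bad & !multi[row(gt_raw)]  # multi-allelic codes stay NA, flagged
  if (any(bad)) {
    r <- which(bad, arr.ind = TRUE)[1, 1]
    stop(sprintf("malformed genotype '%s' at record %d (%s:%d)",
                 gt_raw[which(bad)[1]], r, fix$CHROM[r], pos[r]),
         call. = FALSE)
  }
  dosage[] <- flat
  dosage[multi, ] <- NA_integer_  # multi-allelic codes have no biallelic dosage
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  sites <- tibble::tibble(chrom = fix$CHROM, pos = pos, ref = ref,
                          alt = first_alt, qual = qual,
                          is_indel = is_indel, dist_indel = dist_indel,
                          multiallelic = multi)
  keep <- !is_indel
  dosage <- dosage[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]
  geno_matrix(sites[keep, ], dosage, dp, samples)
}
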