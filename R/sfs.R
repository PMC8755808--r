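#' Joint site-frequency spectrum container
#'
#' @param counts D-dimensional array (D = 1-3) of site counts over allele
#'   count cells; dimension d has extent `2 n_d + 1` for `n_d` diploids.
#' @param pops Ordered population labels.
#' @param n_hap Haploid sample sizes (2n per population).
#' @param folded Whether the spectrum is a minor-allele spectrum.
#' @param monomorphic Monomorphic site count (`NA` when the callable length is
#'   unknown).
#' @param callable_length Callable genome length in bp, or `NA`.
#' @return An object of class `mg_sfs`.
#' @export
joint_sfs_obj <- function(counts, pops, n_hap, folded = FALSE,
                          monomorphic = NA_real_,
                          callable_length = NA_real_) {
  counts <- as.array(counts)
  dimnames(counts) <- NULL
  dim(counts) <- unname(dim(counts))
  n_hap <- unname(n_hap)
  if (length(dim(counts)) != length(pops))
    abort_field("counts", "one dimension per population")
  if (any(dim(counts) != n_hap + 1))
    abort_field("counts", "dimension d must have extent n_hap[d] + 1")
  structure(list(counts = counts, pops = pops, n_hap = as.integer(n_hap),
                 folded = folded, monomorphic = monomorphic,
                 callable_length = callable_length),
            class = "mg_sfs")
}

#' Build the joint allele-frequency spectrum from genotypes
#'
#' Cell `(i, j, ...)` counts the sites whose alt (or minor, when folded)
#' allele count is `i` copies in population 1, `j` in population 2, and so
#' on. When `callable_length` is supplied the monomorphic mass
#' `callable_length - segregating sites` is carried along, which is what makes
#' absolute population sizes identifiable in the demographic likelihood.
#' Spectra are folded by default: with no outgroup the ancestral allele is
#' unknown, so the minor-allele spectrum is the safe summary.
#'
#' @param geno An `mg_geno` with complete biallelic genotypes (run the site
#'   filters first; missing genotypes are an error here).
#' @param pop_labels Optional label per sample (defaults to the sample
#'   table); 1-3 populations.
#' @param folded Fold to the minor-allele spectrum (default `TRUE`).
#' @param callable_length Optional callable genome length in bp.
#' @return An `mg_sfs`.
#' @export
joint_sfs <- function(geno, pop_labels = NULL, folded = TRUE,
                      callable_length = NULL) {
  stopifnot(inherits(geno, "mg_geno"))
  if (anyNA(geno$geno))
    stop("joint_sfs needs complete genotypes; run filter_sites first",
         call. = FALSE)
  pop_labels <- pop_labels %||% geno$samples$population
  pops <- unique(pop_labels)
  if (length(pops) > 3) stop("at most 3 populations", call. = FALSE)
  counts_by_pop <- sapply(pops, function(p)
    rowSums(geno$geno[, pop_labels == p, drop = FALSE]))
  if (n_sites(geno) == 1) counts_by_pop <- matrix(counts_by_pop, nrow = 1)
  n_hap <- vapply(pops, function(p) 2L * sum(pop_labels == p), integer(1))
  dims <- n_hap + 1L
  arr <- array(0, dim = dims)
  idx <- as.matrix(counts_by_pop) + 1L
  for (s in seq_len(nrow(idx))) {
    arr[matrix(idx[s, ], 1)] <- arr[matrix(idx[s, ], 1)] + 1
  }
  mono <- if (is.null(callable_length)) NA_real_ else
    callable_length - n_sites(geno)
  out <- joint_sfs_obj(arr, pops, n_hap, folded = FALSE, monomorphic = mono,
                       callable_length = callable_length %||% NA_real_)
  if (folded) fold_sfs(out) else out
}

# index grid of an sfs array: matrix of allele counts per cell (0-based)
sfs_cells <- function(dims) {
  g <- do.call(expand.grid, lapply(dims, function(d) 0:(d - 1)))
  as.matrix(g)
}

# per-dims cache of fold maps and cell grids: the likelihood path runs these
# thousands of times per fit on identical geometry
.mg_geom_cache <- new.env(parent = emptyenv())

sfs_geometry <- function(dims) {
  key <- paste(dims, collapse = "x")
  hit <- .mg_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  cells <- sfs_cells(dims)
  n_hap <- dims - 1L
  tot <- rowSums(cells)
  n_tot <- sum(n_hap)
  comp <- matrix(rep(n_hap, each = nrow(cells)), ncol = length(dims)) - cells
  # lexicographic comparison of each cell with its complement
  lex_le <- rep(TRUE, nrow(cells))
  decided <- rep(FALSE, nrow(cells))
  for (d in seq_len(ncol(cells))) {
    lt <- !decided & cells[, d] < comp[, d]
    gt <- !decided & cells[, d] > comp[, d]
    lex_le[gt] <- FALSE
    decided <- decided | lt | gt
  }
  fold_target <- ifelse(tot > n_tot / 2 | (2 * tot == n_tot & !lex_le),
                        # linear index of the complement cell
                        1L + as.vector((comp %*% cumprod(c(1, dims[-length(dims)])))),
                        seq_len(nrow(cells)))
  folded_support <- tabulate(fold_target[tot > 0 & tot < n_tot],
                             nbins = nrow(cells)) > 0
  out <- list(cells = cells, tot = tot, n_tot = n_tot,
              fold_target = as.integer(fold_target),
              support_unfolded = tot > 0 & tot < n_tot,
              support_folded = folded_support)
  .mg_geom_cache[[key]] <- out
  out
}

fold_fast <- function(x, dims) {
  g <- sfs_geometry(dims)
  out <- numeric(length(x))
  agg <- rowsum(as.vector(x), g$fold_target)
  out[as.integer(rownames(agg))] <- agg
  array(out, dim = dims)
}

# fold a counts (or probability-mass) array onto minor-allele cells;
# cells with pooled count above n_tot/2 map to their complement, cells on the
# fold line map to the lexicographically smaller of the cell and its
# complement (integer-preserving and idempotent)
fold_array <- function(arr) {
  dims <- dim(arr)
  n_hap <- dims - 1L
  cells <- sfs_cells(dims)
  tot <- rowSums(cells)
  n_tot <- sum(n_hap)
  comp <- matrix(rep(n_hap, each = nrow(cells)), ncol = length(dims)) - cells
  lex_smaller <- function(a, b) {
    # is row-vector a lexicographically <= b
    for (d in seq_along(a)) {
      if (a[d] < b[d]) return(TRUE)
      if (a[d] > b[d]) return(FALSE)
    }
    TRUE
  }
  out <- array(0, dim = dims)
  for (r in seq_len(nrow(cells))) {
    v <- arr[matrix(cells[r, ] + 1L, 1)]
    if (v == 0) next
    target <- if (tot[r] > n_tot / 2) comp[r, ]
    else if (tot[r] * 2 == n_tot && !lex_smaller(cells[r, ], comp[r, ]))
      comp[r, ]
    else cells[r, ]
    out[matrix(target + 1L, 1)] <- out[matrix(target + 1L, 1)] + v
  }
  out
}

#' Fold a spectrum to minor-allele counts
#'
#' Total count is conserved and folding is idempotent; folding an already
#' folded spectrum returns it unchanged with a warning.
#'
#' @param sfs An `mg_sfs`.
#' @return The folded `mg_sfs`.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "mg_sfs"))
  if (sfs$folded) {
    warning("spectrum is already folded; returned unchanged")
    return(sfs)
  }
  sfs$counts <- fold_array(sfs$counts)
  sfs$folded <- TRUE
  sfs
}

#' @export
print.mg_sfs <- function(x, ...) {
  cat("<mg_sfs> ", paste(x$pops, collapse = " x "), " (2n = ",
      paste(x$n_hap, collapse = ", "), "), ",
      if (x$folded) "folded" else "unfolded", ", ",
      format(sum(x$counts)), " segregating sites",
      if (!is.na(x$monomorphic)) paste0(", ", format(x$monomorphic),
                                        " monomorphic"), "\n", sep = "")
  invisible(x)
}

#' @describeIn joint_sfs Long-format cell counts.
#' @param x An `mg_sfs`.
#' @param ... Unused.
#' @export
tidy.mg_sfs <- function(x, ...) {
  cells <- sfs_cells(dim(x$counts))
  colnames(cells) <- paste0("count_", x$pops)
  dplyr::bind_cols(tibble::as_tibble(cells),
                   tibble::tibble(n_sites = as.vector(x$counts)))
}

#' @describeIn joint_sfs Heatmap (2D) or barplot (1D) of the spectrum.
#' @param object An `mg_sfs`.
#' @export
autoplot.mg_sfs <- function(object, ...) {
  d <- tidy(object)
  if (length(object$pops) == 1) {
    names(d)[1] <- "count"
    return(ggplot2::ggplot(d[d$count > 0, ],
                           ggplot2::aes(.data$count, .data$n_sites)) +
             ggplot2::geom_col() + ggplot2::theme_minimal() +
             ggplot2::labs(x = "allele count", y = "sites"))
  }
  names(d)[1:2] <- c("count1", "count2")
  ggplot2::ggplot(d, ggplot2::aes(.data$count1, .data$count2,
                                  fill = log10(.data$n_sites + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(sites + 1)") +
    ggplot2::labs(x = object$pops[1], y = object$pops[2]) +
    ggplot2::theme_minimal()
}

#' Write / read observed spectra in the fastsimcoal2-style text dialect
#'
#' One-dimensional spectra are written as a `"1 observations"` header, a row
#' of `d<pop>_<count>` labels and one row of counts. Two-dimensional spectra
#' use the `jointMAFpop1_0` layout: columns are population 1 cells (`d0_*`),
#' rows population 2 (`d1_*`). Three-dimensional spectra use the
#' multi-dimensional layout: a header naming the number of demes and haploid
#' sample sizes, then the flattened counts (population 1 index fastest). All
#' counts are tab-separated; the round trip is bit-exact.
#'
#' @param sfs An `mg_sfs` (1-3 populations).
#' @param path Output (or input) file path.
#' @return `write_obs()`: `path` invisibly. `read_obs()`: an `mg_sfs`
#'   (population labels `pop1`, `pop2`, ... and `folded` as recorded in the
#'   header comment).
#' @export
write_obs <- function(sfs, path) {
  stopifnot(inherits(sfs, "mg_sfs"))
  d <- length(sfs$pops)
  con <- file(path, open = "wb")
  on.exit(close(con))
  fold_tag <- if (sfs$folded) "MAF" else "DAF"
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE)
  if (d == 1) {
    lines <- c(sprintf("1 observations. %s", fold_tag),
               paste(sprintf("d0_%d", 0:sfs$n_hap[1]), collapse = "\t"),
               paste(fmt(as.vector(sfs$counts)), collapse = "\t"))
  } else if (d == 2) {
    header <- paste(c("", sprintf("d0_%d", 0:sfs$n_hap[1])), collapse = "\t")
    rows <- vapply(0:sfs$n_hap[2], function(j) {
      paste(c(sprintf("d1_%d", j), fmt(sfs$counts[, j + 1])), collapse = "\t")
    }, character(1))
    lines <- c(sprintf("1 observations. %s", fold_tag), header, rows)
  } else {
    lines <- c(sprintf("1 observations. %s. No. of demes and sample sizes are on next line",
                       fold_tag),
               paste(c(d, sfs$n_hap), collapse = "\t"),
               paste(fmt(as.vector(sfs$counts)), collapse = "\t"))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_obs
#' @export
read_obs <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^1 observations", lines[1]))
    stop("parse error at line 1: expected '1 observations' header",
         call. = FALSE)
  folded <- grepl("MAF", lines[1])
  if (grepl("No. of demes", lines[1])) {
    hdr <- as.integer(strsplit(lines[2], "\t")[[1]])
    d <- hdr[1]; n_hap <- hdr[-1]
    vals <- as.numeric(strsplit(lines[3], "\t")[[1]])
    if (length(vals) != prod(n_hap + 1))
      stop("parse error at line 3: ", length(vals),
           " counts do not match declared sample sizes", call. = FALSE)
    counts <- array(vals, dim = n_hap + 1)
  } else if (length(lines) >= 3 && grepl("^d1_", lines[3])) {
    labels <- strsplit(lines[2], "\t")[[1]]
    labels <- labels[labels != ""]
    if (!all(grepl("^d0_\\d+$", labels)))
      stop("parse error at line 2: malformed column labels", call. = FALSE)
    n1 <- length(labels) - 1L
    rows <- lines[-(1:2)]
    n2 <- length(rows) - 1L
    counts <- matrix(0, n1 + 1, n2 + 1)
    for (j in seq_along(rows)) {
      fields <- strsplit(rows[j], "\t")[[1]]
      if (fields[1] != sprintf("d1_%d", j - 1))
        stop("parse error at line ", j + 2, ": expected row label d1_",
             j - 1, call. = FALSE)
      v <- as.numeric(fields[-1])
      if (length(v) != n1 + 1)
        stop("parse error at line ", j + 2,
             ": count row does not match declared sample size", call. = FALSE)
      counts[, j] <- v
    }
    n_hap <- c(n1, n2)
    d <- 2
  } else {
    labels <- strsplit(lines[2], "\t")[[1]]
    if (!all(grepl("^d0_\\d+$", labels)))
      stop("parse error at line 2: malformed axis labels", call. = FALSE)
    vals <- as.numeric(strsplit(lines[3], "\t")[[1]])
    if (length(vals) != length(labels))
      stop("parse error at line 3: counts do not match axis labels",
           call. = FALSE)
    counts <- array(vals, dim = length(vals))
    n_hap <- length(vals) - 1L
    d <- 1
  }
  joint_sfs_obj(counts, pops = paste0("pop", seq_len(d)), n_hap = n_hap,
                folded = folded)
}

#' Marginalize a joint spectrum onto one population
#'
#' @param sfs An `mg_sfs`.
#' @param pop Population label (or index) to keep.
#' @return A 1-population `mg_sfs`. Only meaningful for unfolded spectra
#'   (folding does not commute with marginalization).
#' @export
marginal_sfs <- function(sfs, pop) {
  stopifnot(inherits(sfs, "mg_sfs"))
  k <- if (is.character(pop)) match(pop, sfs$pops) else pop
  if (is.na(k)) stop("unknown population", call. = FALSE)
  m <- apply(sfs$counts, k, sum)
  joint_sfs_obj(array(m, dim = length(m)), pops = sfs$pops[k],
                n_hap = sfs$n_hap[k], folded = sfs$folded,
                monomorphic = sfs$monomorphic,
                callable_length = sfs$callable_length)
}
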