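#' Configure a synthetic resequencing dataset
#'
#' Bundles everything [simulate_dataset()] needs: the generating demographic
#' model, diploid sample sizes, the target number of independent SNP loci,
#' the callable genome length (which carries the monomorphic mass used by the
#' demographic likelihood), sequencing-noise models and the seed. Defaults
#' emulate a typical montane-bird resequencing panel: 9-18 diploids per
#' population, negative-binomial read depth (mean 30, dispersion 15) and
#' Gaussian site quality (mean 50, sd 12), chosen so that roughly 5-10% of
#' sites fail the default site filters.
#'
#' @param model An [demographic_model()].
#' @param samples_per_pop Integer vector of diploid counts, one per model
#'   population (each `>= 2`).
#' @param n_sites Target number of independent SNP loci (`mutation_mode =
#'   "fixed"`: exactly this many sites, one per locus).
#' @param callable_length Total callable genome length in bp (`>= n_sites`).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output files.
#' @param halfsib_pairs Optional list of 2-long character vectors naming
#'   sample pairs to replace by planted half-siblings (see
#'   [inject_halfsibs()]).
#' @param depth_model Length-2 numeric `(mean, dispersion)` of the
#'   negative-binomial per-sample read depth.
#' @param qual_model Length-2 numeric `(mean, sd)` of Gaussian site quality.
#' @param mutation_mode `"fixed"` (default): one mutation per locus, placed on
#'   a branch chosen proportional to its length, so exactly `n_sites`
#'   segregating sites. `"poisson"`: `n_loci` independent loci of equal length
#'   summing to `callable_length`, each receiving
#'   `Poisson(mu * locus_length * total branch length)` mutations, so the
#'   segregating-site count is itself a random outcome of the model.
#' @param n_loci Number of loci in `"poisson"` mode.
#' @return An object of class `mg_sim_config`.
#' @export
simulation_config <- function(model, samples_per_pop, n_sites = 5000,
                              callable_length = 1e7, seed,
                              halfsib_pairs = NULL,
                              depth_model = c(30, 15),
                              qual_model = c(50, 12),
                              mutation_mode = c("fixed", "poisson"),
                              n_loci = 1000) {
  stopifnot(inherits(model, "mg_model"))
  mutation_mode <- match.arg(mutation_mode)
  if (length(samples_per_pop) != length(model$pop_labels))
    abort_field("samples_per_pop", "one diploid count per model population")
  if (any(samples_per_pop < 2))
    abort_field("samples_per_pop", "need >= 2 diploids per population")
  if (n_sites < 1) abort_field("n_sites", "must be >= 1")
  if (callable_length < n_sites)
    abort_field("callable_length", "must be >= n_sites")
  if (missing(seed) || is.null(seed)) abort_field("seed", "a seed is required")
  structure(list(model = model, samples_per_pop = as.integer(samples_per_pop),
                 n_sites = as.integer(n_sites),
                 callable_length = as.numeric(callable_length),
                 seed = as.integer(seed), halfsib_pairs = halfsib_pairs,
                 depth_model = depth_model, qual_model = qual_model,
                 mutation_mode = mutation_mode, n_loci = as.integer(n_loci)),
            class = "mg_sim_config")
}

sample_table <- function(config, elevation = NULL, species = "sp1") {
  pops <- config$model$pop_labels
  n <- config$samples_per_pop
  ids <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s_%02d", pops[k], seq_len(n[k]))))
  tibble::tibble(sample_id = ids,
                 population = rep(pops, n),
                 elevation_m = if (is.null(elevation)) NA_real_ else elevation,
                 species = species)
}

haploid_to_dosage <- function(hap) {
  # columns come in pairs (2i-1, 2i) per diploid
  n <- ncol(hap) / 2
  hap[, 2 * seq_len(n) - 1, drop = FALSE] + hap[, 2 * seq_len(n), drop = FALSE]
}

#' Simulate a synthetic SNP dataset under a demographic model
#'
#' Draws independent, non-recombining coalescent genealogies under the
#' configured model, places mutations, converts haplotypes to unphased diploid
#' dosages, plants any configured half-sibling pairs, and attaches simulated
#' per-sample read depth and site quality so the site filters have realistic
#' material to remove. Every emitted site is biallelic and segregating in the
#' pooled sample.
#'
#' @param config An [simulation_config()].
#' @return A list with elements `geno` (an `mg_geno`) and `truth` (the
#'   generating parameter values, planted pedigree and seed).
#' @examples
#' m <- im_model(ne1 = 1e4, ne2 = 1e4, ne_anc = 1e4, t_div = 5e4)
#' sim <- simulate_dataset(simulation_config(m, c(4, 4), n_sites = 100,
#'                                           callable_length = 1e5, seed = 1))
#' sim$geno
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "mg_sim_config"))
  model <- config$model
  ss <- 2L * config$samples_per_pop
  pars <- model_engine_pars(model)
  if (config$mutation_mode == "fixed") {
    hap <- cpp_sim_snps(pars, ss, config$n_sites,
                        derive_seed(config$seed, 1))
    locus <- seq_len(nrow(hap))
    chrom <- rep("chr1", nrow(hap))
    spacing <- max(1, floor(config$callable_length / max(1, nrow(hap))))
    pos <- seq_len(nrow(hap)) * spacing
  } else {
    locus_len <- config$callable_length / config$n_loci
    res <- cpp_sim_loci(pars, ss, config$n_loci, model$mu * locus_len,
                        derive_seed(config$seed, 1))
    hap <- res$derived
    locus <- res$locus
    chrom <- sprintf("locus_%05d", locus)
    pos <- run_seeded(derive_seed(config$seed, 2), {
      unsplit(lapply(split(seq_along(locus), locus), function(ix)
        sort(sample.int(max(length(ix), as.integer(locus_len)), length(ix)))),
        locus)
    })
  }
  geno <- haploid_to_dosage(hap)
  storage.mode(geno) <- "integer"
  S <- nrow(geno)
  samples <- sample_table(config)
  noise <- run_seeded(derive_seed(config$seed, 3), {
    list(ref_alt = matrix(replicate(S, sample(c("A", "C", "G", "T"), 2)),
                          nrow = 2),
         depth = matrix(rnbinom(S * nrow(samples),
                                size = config$depth_model[2],
                                mu = config$depth_model[1]), nrow = S),
         qual = pmax(round_half_away(
           rnorm(S, config$qual_model[1], config$qual_model[2]), 1), 0))
  })
  ref_alt <- noise$ref_alt; depth <- noise$depth; qual <- noise$qual
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = ref_alt[1, ], alt = ref_alt[2, ],
                          qual = qual, is_indel = FALSE,
                          dist_indel = Inf, multiallelic = FALSE)
  g <- geno_matrix(sites, geno, depth, samples)
  pedigree <- NULL
  if (!is.null(config$halfsib_pairs) && length(config$halfsib_pairs)) {
    g <- inject_halfsibs(g, config$halfsib_pairs,
                         seed = derive_seed(config$seed, 4))
    pedigree <- attr(g, "pedigree")
  }
  truth <- list(
    model = list(pop_labels = model$pop_labels, ne = model$ne,
                 growth = model$growth,
                 migration = model$migration,
                 events = as.data.frame(model$events),
                 mu = model$mu, gen_time = model$gen_time),
    samples_per_pop = config$samples_per_pop,
    n_sites = S, callable_length = config$callable_length,
    mutation_mode = config$mutation_mode,
    pedigree = if (is.null(pedigree)) NULL else as.data.frame(pedigree),
    seed = config$seed)
  list(geno = g, truth = truth)
}

#' Replace two samples by planted half-siblings
#'
#' The two named samples are replaced by simulated offspring that share
#' exactly one parent. The shared parent's genotype is drawn from the
#' population allele frequencies under Hardy-Weinberg; each offspring receives
#' one gamete dropped from that parent and one independent gamete drawn from
#' the population frequencies, giving an expected kinship coefficient of
#' 0.125. All other samples are untouched.
#'
#' @param geno An `mg_geno`.
#' @param pair_spec List of 2-long character vectors of sample ids (each pair
#'   within one population that has at least 3 samples). An empty list returns
#'   the matrix unchanged.
#' @param seed Integer seed.
#' @return The modified `mg_geno` with a `pedigree` attribute (tibble with
#'   `sample1`, `sample2`, `population`, `relationship`).
#' @export
inject_halfsibs <- function(geno, pair_spec, seed) {
  stopifnot(inherits(geno, "mg_geno"))
  if (is.character(pair_spec)) pair_spec <- list(pair_spec)
  if (!length(pair_spec)) return(geno)
  ped <- list()
  run_seeded(seed, {
    for (pair in pair_spec) {
      if (length(pair) != 2)
        abort_field("pair_spec", "each pair must name two samples")
      ix <- match(pair, geno$samples$sample_id)
      if (anyNA(ix))
        stop("pair names missing sample(s): ",
             paste(pair[is.na(ix)], collapse = ", "), call. = FALSE)
      pop <- unique(geno$samples$population[ix])
      if (length(pop) != 1)
        abort_field("pair_spec", "pair members must share a population")
      members <- which(geno$samples$population == pop)
      if (length(members) < 3)
        abort_field("pair_spec",
                    "target population needs >= 3 samples to draw parental gametes")
      p <- rowMeans(geno$geno[, members, drop = FALSE], na.rm = TRUE) / 2
      p <- pmin(pmax(p, 0), 1)
      S <- length(p)
      parent <- rbinom(S, 2L, p)
      for (child in ix) {
        from_parent <- rbinom(S, 1L, parent / 2)
        from_pop <- rbinom(S, 1L, p)
        geno$geno[, child] <- as.integer(from_parent + from_pop)
      }
      ped[[length(ped) + 1]] <- tibble::tibble(
        sample1 = pair[1], sample2 = pair[2], population = pop,
        relationship = "half-sib")
    }
  })
  attr(geno, "pedigree") <- dplyr::bind_rows(ped)
  geno
}

#' Simulate a multi-species covariate panel linking elevation to migration
#'
#' Generates one two-population dataset per species, with the forward
#' migration rate of each species set by a mapping of its elevational floor
#' (the lowest elevation at which the species occurs). Downstream, FST per
#' species against floor exercises the rank-correlation stage under a known
#' effect direction.
#'
#' @param n_species Number of species (`>= 5`).
#' @param floor_to_migration Function mapping floor (m) to a symmetric forward
#'   migration rate. A non-monotone mapping is accepted but flagged in the
#'   truth metadata.
#' @param base_model Two-population `mg_model` template; its migration matrix
#'   is replaced per species.
#' @param seed Integer seed.
#' @param floors Elevational floors in metres (default: evenly spaced
#'   100-2800 m).
#' @param samples_per_pop Diploid counts per population (default `c(8, 8)`).
#' @param n_sites SNP loci per species.
#' @return A tibble with one row per species: `species`, `elevation_floor`,
#'   `migration`, list-columns `geno` and `truth`, and attribute
#'   `monotone_mapping`.
#' @export
simulate_covariate_panel <- function(n_species, floor_to_migration, base_model,
                                     seed, floors = NULL,
                                     samples_per_pop = c(8, 8),
                                     n_sites = 2000) {
  if (n_species < 5) abort_field("n_species", "need >= 5 species")
  stopifnot(inherits(base_model, "mg_model"),
            length(base_model$pop_labels) == 2)
  floors <- floors %||% seq(100, 2800, length.out = n_species)
  m_rates <- vapply(floors, floor_to_migration, numeric(1))
  if (any(m_rates < 0) || any(m_rates >= 1))
    abort_field("floor_to_migration", "mapped rates must lie in [0, 1)")
  monotone <- all(diff(m_rates[order(floors)]) <= 0) ||
    all(diff(m_rates[order(floors)]) >= 0)
  rows <- lapply(seq_len(n_species), function(i) {
    mod <- base_model
    mod$migration[1, 2] <- m_rates[i]
    mod$migration[2, 1] <- m_rates[i]
    cfg <- simulation_config(mod, samples_per_pop, n_sites = n_sites,
                             callable_length = max(1e6, n_sites * 100),
                             seed = derive_seed(seed, i * 7))
    sim <- simulate_dataset(cfg)
    sim$geno$samples$species <- sprintf("species_%02d", i)
    sim$truth$elevation_floor <- floors[i]
    sim$truth$migration_rate <- m_rates[i]
    sim$truth$monotone_mapping <- monotone
    tibble::tibble(species = sprintf("species_%02d", i),
                   elevation_floor = floors[i], migration = m_rates[i],
                   geno = list(sim$geno), truth = list(sim$truth))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "monotone_mapping") <- monotone
  out
}
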