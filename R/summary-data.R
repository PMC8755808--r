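#' Published demographic summary estimates
#'
#' Best-model demographic estimates for eighteen Indo-Pacific bird species
#' with population pairs across the Moluccan islands (Buru/Seram) and the New
#' Guinean mountain ranges (Mount Wilhelm, Huon, Mount Scratchley): current
#' and ancestral effective population sizes, divergence times in years,
#' per-generation forward migration rates per direction, and the printed
#' effective number of migrants per generation. Shipped in long format
#' (`region`, `comparison`, `species`, `quantity`, `from`, `to`, `value`)
#' and used to exercise the derived-quantity identities
#' (`Nm = Ne_source x M`, year scaling at a 2-year generation time).
#'
#' @return A tibble.
#' @export
divergence_summary <- function() {
  path <- system.file("extdata", "divergence_summary.tsv",
                      package = "montgen", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(), comparison = readr::col_character(),
    species = readr::col_character(), quantity = readr::col_character(),
    from = readr::col_character(), to = readr::col_character(),
    value = readr::col_double()))
}

#' Recompute migrant numbers from the summary table
#'
#' For every directed pair, builds a [demographic_model()] from the published
#' sizes and migration rates and runs [derive_quantities()], returning the
#' recomputed `Nm = Ne_source x M` (full precision and display rounding)
#' alongside the printed value.
#'
#' @param summary Tibble from [divergence_summary()] (the default).
#' @return Tibble: `species`, `from`, `to`, `ne_source`, `m`, `nm`,
#'   `nm_display`, `nm_printed`, `matches_printed`.
#' @export
summary_nm_table <- function(summary = divergence_summary()) {
  split_sp <- split(summary, paste(summary$species, summary$comparison))
  purrr::map_dfr(split_sp, function(d) {
    ne <- d[d$quantity == "ne", ]
    pops <- ne$from
    mig <- matrix(0, length(pops), length(pops),
                  dimnames = list(pops, pops))
    mrows <- d[d$quantity == "m", ]
    mig[cbind(match(mrows$from, pops), match(mrows$to, pops))] <- mrows$value
    t_y <- d$value[d$quantity == "t_div_y"]
    gen_time <- 2
    ev <- tibble::tibble(time = t_y / gen_time, kind = "join",
                         pop = pops[2], pop_to = pops[1],
                         size = NA_real_, growth = NA_real_)
    model <- demographic_model(pops, ne = ne$value, migration = mig,
                               events = ev, gen_time = gen_time)
    dq <- derive_quantities(model)
    printed <- d[d$quantity == "nm_printed", c("from", "to", "value")]
    names(printed)[3] <- "nm_printed"
    out <- dplyr::left_join(dq$nm, printed, by = c("from", "to"))
    out$species <- d$species[1]
    out$matches_printed <- abs(out$nm_display - out$nm_printed) < 1e-9
    out[, c("species", "from", "to", "ne_source", "m", "nm", "nm_display",
            "nm_printed", "matches_printed")]
  })
}

#' Mean divergence time per region
#'
#' Averages the published per-species divergence times within a region and
#' converts to millions of years (display rounding to one decimal).
#'
#' @param summary Tibble from [divergence_summary()].
#' @param region Region label (`"New Guinea"` or `"Moluccas"`).
#' @return A list: `n`, `mean_my`, `mean_my_display`.
#' @export
mean_divergence_time <- function(summary = divergence_summary(),
                                 region = "New Guinea") {
  t_y <- summary$value[summary$quantity == "t_div_y" &
                         summary$region == region]
  list(n = length(t_y), mean_my = mean(t_y) / 1e6,
       mean_my_display = round_half_away(mean(t_y) / 1e6, 1))
}
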