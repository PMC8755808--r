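#' Define an isolation-with-migration demographic model
#'
#' A demographic model describes 2 or 3 present-day populations with diploid
#' effective sizes, optional exponential growth, a forward migration matrix,
#' and an ordered set of timed events (divergence joins and instantaneous size
#' changes) back in time. Time is measured in generations before sampling.
#'
#' The migration convention is forward: `migration[i, j]` is the
#' per-generation probability that an individual in population `j` originates
#' from population `i`. Internally this equals the backward jump rate of a
#' coalescent lineage in `j` toward `i`, so no numerical conversion is needed;
#' the effective number of migrants per generation from `i` to `j` is
#' `Ne_i * migration[i, j]` (see [derive_quantities()]).
#'
#' @param pop_labels Character vector of 2 or 3 population labels.
#' @param ne Diploid effective sizes per population at sampling time.
#' @param growth Forward per-generation exponential growth rates (0 = constant
#'   size). Going back in time a population growing at rate `r` shrinks as
#'   `N(t) = N(0) * exp(-r t)`.
#' @param migration Square forward migration matrix (entries in `[0, 1)`,
#'   diagonal ignored). Default: no migration.
#' @param events Tibble with columns `time` (generations), `kind`
#'   (`"join"` or `"resize"`), `pop` (label of the affected population),
#'   `pop_to` (join target label; `NA` for resize), `size`, `growth`
#'   (post-event values for resize; `NA` for join). Divergence is expressed as
#'   a join of the daughter into the surviving lineage followed by a resize of
#'   the survivor to the ancestral size.
#' @param mu Mutation rate per site per generation (default `3e-9`, the
#'   passerine rate; use `2e-9` for kingfishers).
#' @param gen_time Generation time in years (default 2).
#'
#' @return An object of class `mg_model`.
#' @seealso [im_model()] for the common two-population shortcut,
#'   [build_model()] for the fitting catalogue.
#' @export
demographic_model <- function(pop_labels, ne, growth = NULL, migration = NULL,
                              events = NULL, mu = 3e-9, gen_time = 2) {
  k <- length(pop_labels)
  if (k < 1 || k > 3) abort_field("pop_labels", "need 1-3 populations")
  if (anyDuplicated(pop_labels)) abort_field("pop_labels", "labels must be unique")
  if (length(ne) != k) abort_field("ne", "one size per population")
  if (any(!is.finite(ne)) || any(ne <= 0)) abort_field("ne", "sizes must be > 0")
  growth <- growth %||% rep(0, k)
  if (length(growth) != k) abort_field("growth", "one rate per population")
  migration <- migration %||% matrix(0, k, k)
  if (!is.matrix(migration) || any(dim(migration) != k))
    abort_field("migration", sprintf("must be a %d x %d matrix", k, k))
  diag(migration) <- 0
  if (any(migration < 0) || any(migration >= 1))
    abort_field("migration", "entries must lie in [0, 1)")
  if (is.null(events)) {
    events <- tibble::tibble(time = numeric(), kind = character(),
                             pop = character(), pop_to = character(),
                             size = numeric(), growth = numeric())
  }
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    if (any(!events$kind %in% c("join", "resize")))
      abort_field("events", "kind must be 'join' or 'resize'")
    if (any(!is.finite(events$time)) || any(events$time < 0))
      abort_field("events", "event times must be finite and >= 0")
    if (is.unsorted(events$time))
      abort_field("events", "events must be ordered by time")
    if (any(!events$pop %in% pop_labels))
      abort_field("events", "event pop not among pop_labels")
    joins <- events[events$kind == "join", ]
    if (nrow(joins) && any(!joins$pop_to %in% pop_labels))
      abort_field("events", "join target not among pop_labels")
    rs <- events[events$kind == "resize", ]
    if (nrow(rs) && (any(!is.finite(rs$size)) || any(rs$size <= 0)))
      abort_field("events", "resize sizes must be > 0")
    # a population must not be referenced after the join that removes it
    for (p in pop_labels) {
      jt <- joins$time[joins$pop == p]
      if (length(jt)) {
        later <- events$time > min(jt) &
          (events$pop == p | (events$kind == "join" & !is.na(events$pop_to) &
                                events$pop_to == p))
        if (any(later))
          abort_field("events",
                      sprintf("population '%s' referenced after it was joined away", p))
      }
    }
  }
  structure(list(pop_labels = pop_labels, ne = as.numeric(ne),
                 growth = as.numeric(growth), migration = migration,
                 events = events, mu = mu, gen_time = gen_time),
            class = "mg_model")
}

#' Two-population isolation-with-migration shortcut
#'
#' Builds the canonical two-population model: daughters of sizes `ne1`, `ne2`
#' diverged `t_div` generations ago from an ancestor of size `ne_anc`, with
#' optional forward migration and exponential growth in the daughters.
#'
#' @param ne1,ne2 Present-day diploid sizes.
#' @param ne_anc Ancestral diploid size.
#' @param t_div Divergence time in generations.
#' @param m12,m21 Forward migration rates (pop1 to pop2 and back).
#' @param g1,g2 Exponential growth rates in the daughters.
#' @param pop_labels Labels, default `c("pop1", "pop2")`.
#' @inheritParams demographic_model
#' @return An `mg_model`.
#' @export
im_model <- function(ne1, ne2, ne_anc, t_div, m12 = 0, m21 = 0,
                     g1 = 0, g2 = 0, pop_labels = c("pop1", "pop2"),
                     mu = 3e-9, gen_time = 2) {
  mig <- matrix(c(0, m21, m12, 0), 2, 2,
                dimnames = list(pop_labels, pop_labels))
  ev <- tibble::tibble(
    time = c(t_div, t_div),
    kind = c("join", "resize"),
    pop = c(pop_labels[2], pop_labels[1]),
    pop_to = c(pop_labels[1], NA),
    size = c(NA, ne_anc),
    growth = c(NA, 0))
  demographic_model(pop_labels, ne = c(ne1, ne2), growth = c(g1, g2),
                    migration = mig, events = ev, mu = mu, gen_time = gen_time)
}

# Internal fast constructor: used by the fitting catalogue, whose inputs are
# already constrained by the parameter-space bounds, so the full validation
# of demographic_model() is redundant on the likelihood hot path.
new_mg_model <- function(pop_labels, ne, growth, migration, events,
                         mu, gen_time) {
  structure(list(pop_labels = pop_labels, ne = as.numeric(ne),
                 growth = as.numeric(growth), migration = migration,
                 events = events, mu = mu, gen_time = gen_time),
            class = "mg_model")
}

# Convert an mg_model to the flat list consumed by the C++ engine
# (0-based population indices, events as a numeric matrix sorted by time).
model_engine_pars <- function(model) {
  stopifnot(inherits(model, "mg_model"))
  k <- length(model$pop_labels)
  ev <- model$events
  if (nrow(ev)) {
    m <- matrix(0, nrow(ev), 6)
    m[, 1] <- ev$time
    m[, 2] <- ifelse(ev$kind == "join", 0, 1)
    m[, 3] <- match(ev$pop, model$pop_labels) - 1
    m[, 4] <- ifelse(ev$kind == "join", match(ev$pop_to, model$pop_labels) - 1, 0)
    m[, 5] <- ifelse(ev$kind == "resize", ev$size, 0)
    m[, 6] <- ifelse(ev$kind == "resize", ifelse(is.na(ev$growth), 0, ev$growth), 0)
  } else {
    m <- matrix(0, 0, 6)
  }
  list(npop = k, sizes = model$ne, growth = model$growth,
       migration = unname(model$migration), events = m)
}

#' @export
print.mg_model <- function(x, ...) {
  cat("<mg_model> ", length(x$pop_labels), " population(s): ",
      paste(x$pop_labels, collapse = ", "), "\n", sep = "")
  cat("  Ne:", format(x$ne, big.mark = ","), "\n")
  if (any(x$growth != 0)) cat("  growth:", signif(x$growth, 3), "\n")
  if (any(x$migration > 0)) {
    cat("  forward migration:\n")
    print(signif(x$migration, 3))
  }
  if (nrow(x$events)) {
    cat("  events:\n")
    print(as.data.frame(x$events))
  }
  cat("  mu =", x$mu, " generation time =", x$gen_time, "y\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fitting catalogue
# ---------------------------------------------------------------------------

catalogue_ids <- function() {
  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x",
    "3pop_null", "3pop_mig")
}

par_row <- function(name, lower, upper, log10 = TRUE) {
  tibble::tibble(name = name, lower = lower, upper = upper, log10 = log10)
}

# Default search bounds: log-uniform Ne in [1e3, 1e7], T in [1e2, 1e7]
# generations, m in [1e-10, 1e-2], growth in [-1e-3, 1e-3]. These bracket
# every published estimate this package targets by at least an order of
# magnitude and are overridable via the `bounds` argument of build_model().
default_bounds <- function() {
  list(ne = c(1e3, 1e7), t = c(1e2, 1e7), m = c(1e-10, 1e-2),
       growth = c(-1e-3, 1e-3), ratio_bot = c(1e-3, 0.999),
       ratio_exp = c(1.001, 1e3), t_frac = c(0.01, 0.99))
}

#' Build a catalogue demographic model template for fitting
#'
#' The two-population catalogue mirrors the ten divergence scenarios commonly
#' contrasted for montane taxon pairs: (i) a null model with no growth and no
#' migration, (ii) migration but no growth, (iii) exponential growth but no
#' migration, (iv) growth and migration, a historical size-change event giving
#' each daughter a bottleneck (v) with and (vi) without migration, a sudden
#' expansion (vii) with and (viii) without migration, and the mixed scenarios
#' (ix) bottleneck in population 1 with expansion in population 2 and (x) the
#' reverse. Bottleneck/expansion direction is enforced through bounds on the
#' ratio of current to historical size (ratio < 1 = decline toward the
#' present, i.e. a bottleneck; ratio > 1 = sudden expansion). `3pop_null` and
#' `3pop_mig` extend the null/migration models to three populations with
#' nested divergence times `T1 <= T2` (topology `((pop1, pop3), pop2)`).
#'
#' @param id Catalogue identifier, one of
#'   `r paste(catalogue_ids(), collapse = ", ")`.
#' @param pop_labels Two (or, for `3pop_*`, three) population labels.
#' @param mu Mutation rate per site per generation.
#' @param gen_time Generation time in years.
#' @param bounds Optional named list overriding entries of the default search
#'   bounds (`ne`, `t`, `m`, `growth`, `ratio_bot`, `ratio_exp`, `t_frac`).
#'
#' @return An object of class `mg_model_spec`: the free-parameter space
#'   (tibble `space` with name/lower/upper/log10), the number of free
#'   parameters `k`, and an `assemble(theta)` closure producing an
#'   [demographic_model()] from a named parameter vector.
#' @export
build_model <- function(id, pop_labels = c("pop1", "pop2"),
                        mu = 3e-9, gen_time = 2, bounds = NULL) {
  id <- as.character(id)
  if (!id %in% catalogue_ids())
    stop("unknown catalogue id '", id, "'; available: ",
         paste(catalogue_ids(), collapse = ", "), call. = FALSE)
  b <- default_bounds()
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  three <- id %in% c("3pop_null", "3pop_mig")
  if (three && length(pop_labels) != 3)
    abort_field("pop_labels", "3-population models need three labels")
  if (!three && length(pop_labels) != 2)
    abort_field("pop_labels", "two-population models need two labels")

  sp <- dplyr::bind_rows(
    par_row("ne1", b$ne[1], b$ne[2]),
    par_row("ne2", b$ne[1], b$ne[2]),
    if (three) par_row("ne3", b$ne[1], b$ne[2]),
    if (three) par_row("ne_anc13", b$ne[1], b$ne[2]),
    par_row("ne_anc", b$ne[1], b$ne[2]),
    par_row("t_div", b$t[1], b$t[2]),
    if (three) par_row("t1_frac", b$t_frac[1], b$t_frac[2], log10 = FALSE))
  has_mig <- id %in% c("ii", "iv", "v", "vii", "ix", "x", "3pop_mig")
  if (has_mig && !three)
    sp <- dplyr::bind_rows(sp, par_row("m12", b$m[1], b$m[2]),
                           par_row("m21", b$m[1], b$m[2]))
  if (has_mig && three)
    sp <- dplyr::bind_rows(sp,
      par_row("m12", b$m[1], b$m[2]), par_row("m21", b$m[1], b$m[2]),
      par_row("m13", b$m[1], b$m[2]), par_row("m31", b$m[1], b$m[2]),
      par_row("m23", b$m[1], b$m[2]), par_row("m32", b$m[1], b$m[2]))
  if (id %in% c("iii", "iv"))
    sp <- dplyr::bind_rows(sp,
      par_row("g1", b$growth[1], b$growth[2], log10 = FALSE),
      par_row("g2", b$growth[1], b$growth[2], log10 = FALSE))
  if (id %in% c("v", "vi", "vii", "viii", "ix", "x")) {
    r1 <- if (id %in% c("v", "vi", "ix")) b$ratio_bot else b$ratio_exp
    r2 <- if (id %in% c("v", "vi", "x")) b$ratio_bot else b$ratio_exp
    sp <- dplyr::bind_rows(sp,
      par_row("t_event_frac", b$t_frac[1], b$t_frac[2], log10 = FALSE),
      par_row("ratio1", r1[1], r1[2]),
      par_row("ratio2", r2[1], r2[2]))
  }

  assemble <- if (!three) {
    function(theta) {
      th <- as.list(theta)
      t_div <- th$t_div
      if (!is.null(th$t_event_frac)) {
        te <- th$t_event_frac * t_div
        ev <- data.frame(
          time = c(te, te, t_div, t_div),
          kind = c("resize", "resize", "join", "resize"),
          pop = c(pop_labels, pop_labels[2], pop_labels[1]),
          pop_to = c(NA, NA, pop_labels[1], NA),
          size = c(th$ne1 / th$ratio1, th$ne2 / th$ratio2, NA, th$ne_anc),
          growth = c(0, 0, NA, 0))
      } else {
        ev <- data.frame(
          time = c(t_div, t_div), kind = c("join", "resize"),
          pop = c(pop_labels[2], pop_labels[1]),
          pop_to = c(pop_labels[1], NA),
          size = c(NA, th$ne_anc), growth = c(NA, 0))
      }
      mig <- matrix(0, 2, 2, dimnames = list(pop_labels, pop_labels))
      if (!is.null(th$m12)) { mig[1, 2] <- th$m12; mig[2, 1] <- th$m21 }
      growth <- c(th$g1 %||% 0, th$g2 %||% 0)
      new_mg_model(pop_labels, ne = c(th$ne1, th$ne2), growth = growth,
                   migration = mig, events = ev,
                   mu = mu, gen_time = gen_time)
    }
  } else {
    function(theta) {
      th <- as.list(theta)
      t2 <- th$t_div
      t1 <- th$t1_frac * t2
      ev <- data.frame(
        time = c(t1, t1, t2, t2),
        kind = c("join", "resize", "join", "resize"),
        pop = c(pop_labels[3], pop_labels[1], pop_labels[2], pop_labels[1]),
        pop_to = c(pop_labels[1], NA, pop_labels[1], NA),
        size = c(NA, th$ne_anc13, NA, th$ne_anc),
        growth = c(NA, 0, NA, 0))
      mig <- matrix(0, 3, 3, dimnames = list(pop_labels, pop_labels))
      if (!is.null(th$m12)) {
        mig[1, 2] <- th$m12; mig[2, 1] <- th$m21
        mig[1, 3] <- th$m13; mig[3, 1] <- th$m31
        mig[2, 3] <- th$m23; mig[3, 2] <- th$m32
      }
      new_mg_model(pop_labels, ne = c(th$ne1, th$ne2, th$ne3),
                   growth = rep(0, 3), migration = mig, events = ev,
                   mu = mu, gen_time = gen_time)
    }
  }

  structure(list(id = id, pop_labels = pop_labels, space = sp,
                 k = nrow(sp), mu = mu, gen_time = gen_time,
                 assemble = assemble),
            class = "mg_model_spec")
}

#' @export
print.mg_model_spec <- function(x, ...) {
  cat("<mg_model_spec> catalogue model '", x$id, "' (k = ", x$k,
      " free parameters)\n", sep = "")
  print(as.data.frame(x$space))
  invisible(x)
}
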