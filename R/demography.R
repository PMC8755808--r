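#' Expected site-frequency spectrum by coalescent simulation
#'
#' Simulates `n_replicates` genealogies under the model and accumulates, for
#' every joint-SFS cell, the total length of branches subtending exactly that
#' sample configuration: under the infinite-sites model the probability that
#' a mutation produces configuration `(i, j, ...)` is proportional to that
#' expected branch length. With a fixed seed the output is identical from run
#' to run, which is what makes the composite-likelihood surface deterministic
#' during optimization (common random numbers).
#'
#' @param model An `mg_model`.
#' @param n_hap Haploid sample sizes, one per model population (must match
#'   the observed spectrum being fitted).
#' @param n_replicates Number of genealogies (default 10000; below 100 the
#'   Monte-Carlo error dominates and a warning is issued).
#' @param seed Integer seed.
#' @return An object of class `mg_expected_sfs`: `lengths` (array of mean
#'   branch length per cell, unfolded), `total_length` (mean total tree
#'   length in generations), `n_replicates`, `seed`, and the Monte-Carlo
#'   standard error scale `mc_se` (per-cell, from the per-replicate variance
#'   approximation).
#' @export
expected_sfs <- function(model, n_hap, n_replicates = 10000, seed) {
  stopifnot(inherits(model, "mg_model"))
  if (length(n_hap) != length(model$pop_labels))
    abort_field("n_hap", "one haploid size per model population")
  if (n_replicates < 100)
    warning("n_replicates < 100: Monte-Carlo error will dominate")
  arr <- cpp_expected_sfs_lengths(model_engine_pars(model),
                                  as.integer(n_hap),
                                  as.integer(n_replicates), seed)
  d <- length(n_hap)
  dims <- dim(arr)[seq_len(d)]
  lengths <- array(arr, dim = dims)
  structure(list(lengths = lengths, total_length = sum(lengths),
                 n_replicates = n_replicates, seed = seed,
                 pops = model$pop_labels, n_hap = as.integer(n_hap)),
            class = "mg_expected_sfs")
}

#' @export
print.mg_expected_sfs <- function(x, ...) {
  cat("<mg_expected_sfs> ", paste(x$pops, collapse = " x "),
      " (2n = ", paste(x$n_hap, collapse = ", "), "), ",
      x$n_replicates, " replicates, mean total length ",
      format(signif(x$total_length, 4)), " generations\n", sep = "")
  invisible(x)
}

# Per-cell probabilities aligned to an observed spectrum. With monomorphic
# mass: q_cell = mu * E[branch length in cell] (expected mutations per site),
# p_mono = 1 - sum(q). Without: normalized branch lengths. The floor
# eps = 1 / (10 * n_replicates * n_cells) keeps ln(0) out of the likelihood.
expected_probs <- function(exp_sfs, folded, mu = NULL, use_mono = FALSE) {
  len <- exp_sfs$lengths
  geom <- sfs_geometry(dim(len))
  if (folded) len <- fold_fast(len, dim(len))
  support <- if (folded) geom$support_folded else geom$support_unfolded
  eps <- 1 / (10 * exp_sfs$n_replicates * sum(support))
  if (use_mono) {
    q <- mu * as.vector(len)
    q[support] <- pmax(q[support], eps * mu * exp_sfs$total_length)
    p_mono <- 1 - sum(q[support])
    if (p_mono <= 0)
      stop("expected polymorphism mass exceeds 1; check mu and model scale",
           call. = FALSE)
    list(q = q, p_mono = p_mono, support = support)
  } else {
    q <- as.vector(len) / sum(len[support])
    q[support] <- pmax(q[support], eps)
    q[support] <- q[support] / sum(q[support])
    list(q = q, p_mono = NA_real_, support = support)
  }
}

#' Composite multinomial log-likelihood of an observed spectrum
#'
#' `lnCL = sum_cells m_i ln p_i`, treating SNPs as independent draws from the
#' model-expected cell probabilities. Zero-count cells contribute exactly 0
#' regardless of their probability. When the observed spectrum carries
#' monomorphic mass (a callable length), the monomorphic cell enters with
#' probability `1 - sum(q)` where `q = mu * expected branch length per cell`;
#' otherwise cell probabilities are the normalized expected branch lengths.
#'
#' @param obs An `mg_sfs`, or a bare numeric vector of counts.
#' @param expected An `mg_expected_sfs` matching `obs` in populations and
#'   sample sizes, or (when `obs` is a bare vector) a probability vector of
#'   the same length.
#' @param mu Mutation rate per site per generation; required when the
#'   observed spectrum carries monomorphic mass.
#' @return The composite log-likelihood (scalar).
#' @examples
#' composite_loglik(c(3, 1), c(0.75, 0.25))  # -2.2493
#' @export
composite_loglik <- function(obs, expected, mu = NULL) {
  if (is.numeric(obs) && is.numeric(expected)) {
    if (length(obs) != length(expected))
      stop("cell mismatch between counts and probabilities", call. = FALSE)
    use <- obs > 0
    return(sum(obs[use] * log(expected[use])))
  }
  stopifnot(inherits(obs, "mg_sfs"), inherits(expected, "mg_expected_sfs"))
  if (!all(dim(obs$counts) == (expected$n_hap + 1)[seq_along(dim(obs$counts))]))
    stop("cell mismatch: observed and expected spectra have different shapes",
         call. = FALSE)
  use_mono <- !is.na(obs$monomorphic)
  if (use_mono && is.null(mu))
    stop("mu is required when the observed spectrum carries monomorphic mass",
         call. = FALSE)
  pr <- expected_probs(expected, folded = obs$folded, mu = mu,
                       use_mono = use_mono)
  m <- as.vector(obs$counts)
  ll <- sum(m[pr$support & m > 0] * log(pr$q[pr$support & m > 0]))
  off <- m > 0 & !pr$support
  if (any(off))
    stop("observed counts in cells outside the model support", call. = FALSE)
  if (use_mono) ll <- ll + obs$monomorphic * log(pr$p_mono)
  ll
}

#' Fit a catalogue model to an observed spectrum
#'
#' Multi-start bounded maximization of the composite likelihood. Each start
#' draws its initial free parameters from the search space (log-uniform where
#' flagged) and refines them by Nelder-Mead on logit-transformed coordinates,
#' against a deterministic likelihood surface (the expected-SFS seed is fixed
#' for the whole fit). The search runs at a reduced replicate count
#' (`search_replicates`); the best `n_polish` starts are then re-polished at
#' the full `n_replicates`, and the overall best start is reported, with all
#' start end-points retained for diagnostics.
#'
#' @param obs An `mg_sfs` (1-3 populations; carries monomorphic mass when
#'   absolute sizes should be identifiable).
#' @param catalogue_id A [build_model()] id, or an `mg_model_spec`.
#' @param n_starts Independent starts (default 100).
#' @param seed Integer seed (drives start draws and the common-random-numbers
#'   expected-SFS stream).
#' @param n_replicates Expected-SFS genealogies per likelihood evaluation at
#'   polish stage (default 10000).
#' @param search_replicates Genealogies during the search stage (default
#'   2000).
#' @param n_polish Number of best starts re-polished at full replicates
#'   (default 3).
#' @param maxit Nelder-Mead iterations per start (default 150 search, half
#'   that at polish).
#' @param mu,gen_time Mutation rate and generation time used for scaling
#'   (defaults 3e-9 and 2).
#' @param bounds Optional bound overrides passed to [build_model()].
#' @param extra_starts Optional list of named parameter vectors used as
#'   additional starts (e.g. a known generating truth in ascent tests, or a
#'   previous fit's optimum); refined exactly like random starts.
#' @param final_replicates Replicate count of the final high-precision polish
#'   round (default four times `n_replicates`).
#' @return An object of class `mg_fit`: `estimates` (named vector),
#'   `lnCL` (composite log-likelihood of the final estimates, evaluated on a
#'   validation common-random-numbers stream so that AIC comparisons are not
#'   biased by optimization against one frozen Monte-Carlo draw; `lnCL_opt`
#'   keeps the optimization-stream value), `k`, `AIC` (= 2k - 2 lnCL
#'   exactly), `model_id`, `derived`
#'   (see [derive_quantities()]), `model` (the assembled `mg_model` at the
#'   optimum), `starts` (tibble of all start end-points), `obs_signature`,
#'   `seed`, `convergence`.
#' @export
fit_model <- function(obs, catalogue_id, n_starts = 100, seed,
                      n_replicates = 10000, search_replicates = 2000,
                      n_polish = 3, maxit = 150,
                      mu = 3e-9, gen_time = 2, bounds = NULL,
                      extra_starts = NULL,
                      final_replicates = 4 * n_replicates) {
  stopifnot(inherits(obs, "mg_sfs"))
  spec <- if (inherits(catalogue_id, "mg_model_spec")) catalogue_id
  else build_model(catalogue_id, pop_labels = obs$pops, mu = mu,
                   gen_time = gen_time, bounds = bounds)
  if (length(spec$pop_labels) != length(obs$pops))
    stop("model populations do not match the observed spectrum", call. = FALSE)
  sp <- spec$space
  k <- nrow(sp)
  use_mono <- !is.na(obs$monomorphic)
  crn_seed <- derive_seed(seed, 1009)

  to_theta <- function(z) {
    u <- 1 / (1 + exp(-z))
    x <- numeric(k)
    lg <- sp$log10
    x[lg] <- 10^(log10(sp$lower[lg]) +
                   u[lg] * (log10(sp$upper[lg]) - log10(sp$lower[lg])))
    x[!lg] <- sp$lower[!lg] + u[!lg] * (sp$upper[!lg] - sp$lower[!lg])
    setNames(x, sp$name)
  }
  to_z <- function(theta) {
    u <- numeric(k)
    lg <- sp$log10
    x <- pmin(pmax(unname(theta[sp$name]), sp$lower), sp$upper)
    u[lg] <- (log10(x[lg]) - log10(sp$lower[lg])) /
      (log10(sp$upper[lg]) - log10(sp$lower[lg]))
    u[!lg] <- (x[!lg] - sp$lower[!lg]) / (sp$upper[!lg] - sp$lower[!lg])
    stats::qlogis(pmin(pmax(u, 0.001), 0.999))
  }
  # With monomorphic mass present, the global coalescent scale c is profiled
  # out analytically at every evaluation: scaling all sizes and times by c
  # multiplies every expected branch length by c, so the scale maximizing the
  # likelihood is c* = S / ((S + m0) mu T_total) in closed form (the dadi-style
  # optimal theta rescaling). The optimizer then searches the shape manifold
  # only, and the reported estimates are the rescaled parameters.
  S_obs <- sum(obs$counts)
  m0_obs <- obs$monomorphic
  scale_names <- intersect(c("ne1", "ne2", "ne3", "ne_anc", "ne_anc13",
                             "t_div"), sp$name)
  rate_names <- intersect(c("m12", "m21", "m13", "m31", "m23", "m32",
                            "g1", "g2"), sp$name)
  c_star <- function(th, total_length) {
    cs <- S_obs / ((S_obs + m0_obs) * spec$mu * total_length)
    b <- sp[match(scale_names, sp$name), ]
    cs <- min(cs, min(b$upper / th[scale_names]))
    max(cs, max(b$lower / th[scale_names]))
  }
  apply_scale <- function(th, cs) {
    th[scale_names] <- th[scale_names] * cs
    if (length(rate_names)) {
      b <- sp[match(rate_names, sp$name), ]
      th[rate_names] <- pmin(pmax(th[rate_names] / cs, b$lower), b$upper)
    }
    if ("t1_frac" %in% names(th) || "t_event_frac" %in% names(th)) {
      # fractions are scale-free
    }
    th
  }
  negll <- function(z, reps) {
    ll <- tryCatch({
      th <- to_theta(z)
      model <- spec$assemble(th)
      ex <- expected_sfs(model, obs$n_hap, n_replicates = reps,
                         seed = crn_seed)
      if (use_mono) {
        cs <- c_star(th, ex$total_length)
        ex$lengths <- ex$lengths * cs
        ex$total_length <- ex$total_length * cs
      }
      composite_loglik(obs, ex, mu = spec$mu)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  final_theta <- function(z, reps) {
    th <- to_theta(z)
    if (!use_mono) return(th)
    model <- spec$assemble(th)
    ex <- expected_sfs(model, obs$n_hap, n_replicates = reps,
                       seed = crn_seed)
    apply_scale(th, c_star(th, ex$total_length))
  }
  starts_z <- run_seeded(derive_seed(seed, 7), {
    matrix(stats::qlogis(runif(n_starts * k, 0.02, 0.98)), n_starts, k)
  })
  nm <- function(z, reps, maxit, reltol = 1e-7, step = 1) {
    optim(z, negll, reps = reps, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = reltol,
                         parscale = rep(step, length(z))))
  }
  # restarted Nelder-Mead: a fresh simplex around the incumbent recovers from
  # simplex collapse, which single-run NM suffers from in 6-8 dimensions
  nm_rounds <- function(z, reps, maxit, rounds, gain_tol, step = 1) {
    v_old <- Inf; o <- NULL
    for (r in seq_len(rounds)) {
      o <- nm(z, reps, maxit, step = step)
      z <- o$par
      if (v_old - o$value < gain_tol) break
      v_old <- o$value
    }
    list(z = z, value = o$value, conv = o$convergence)
  }
  # method-of-moments warm grid (Watterson sizes crossed with
  # divergence-time and migration grids); grid points and user-supplied
  # extra starts are triaged exactly like random starts
  grid <- moment_grid(obs, spec, to_z)
  if (nrow(grid)) {
    # keep the best migration variant within every divergence-time multiplier
    # so refinement always spans the time/migration degeneracy
    gv <- apply(grid, 1, negll, reps = max(500, ceiling(search_replicates / 2)))
    tm <- attr(grid, "t_mult")
    keep <- unlist(lapply(split(seq_along(gv), tm),
                          function(ix) ix[which.min(gv[ix])]))
    grid <- grid[keep, , drop = FALSE]
  }
  if (!is.null(extra_starts))
    grid <- rbind(grid,
                  do.call(rbind, lapply(extra_starts, function(th)
                    to_z(unlist(th)))))
  all_starts <- rbind(starts_z, grid)
  n_all <- nrow(all_starts)
  n_grid <- nrow(grid)
  # coarse-to-fine multi-start: every start gets a short refinement at low
  # replicate count; the most promising starts (always including the best
  # warm-grid candidates, which cover the divergence-time/migration
  # degeneracy) are refined in restarted rounds at the search replicate
  # count and the best few re-polished at the full replicate count (all
  # under common random numbers)
  search <- vector("list", n_all)
  reps_a <- max(250, ceiling(search_replicates / 2))
  for (s in seq_len(n_all)) {
    o <- nm(all_starts[s, ], reps_a, min(maxit, 120))
    search[[s]] <- list(z = o$par, value = o$value, conv = o$convergence)
  }
  vals <- vapply(search, `[[`, numeric(1), "value")
  refine_ix <- head(order(vals), max(min(3, n_all), n_polish))
  if (n_grid)
    refine_ix <- unique(c(refine_ix, n_starts + seq_len(n_grid)))
  for (s in refine_ix) {
    search[[s]] <- nm_rounds(search[[s]]$z, search_replicates, maxit,
                             rounds = 3, gain_tol = 1)
  }
  vals2 <- vapply(search, `[[`, numeric(1), "value")
  vals2[-refine_ix] <- Inf
  polish_ix <- head(order(vals2), max(1, n_polish))
  best <- NULL
  polished <- list()
  for (s in polish_ix) {
    o <- nm_rounds(search[[s]]$z, n_replicates, maxit, rounds = 2,
                   gain_tol = 1)
    polished[[length(polished) + 1]] <-
      list(start = s, z = o$z, value = o$value, conv = o$conv)
    if (is.null(best) || o$value < best$value) best <- polished[[length(polished)]]
  }
  # high-replicate final polish: a restarted round at final_replicates walks
  # the estimate down the shallow likelihood valley that residual Monte-Carlo
  # curvature noise flattens at lower replicate counts
  hp <- nm_rounds(best$z, final_replicates, min(maxit, 150), rounds = 1,
                  gain_tol = 0.75)
  best$z <- hp$z; best$value <- hp$value; best$conv <- hp$conv
  estimates <- final_theta(best$z, final_replicates)
  # The reported composite likelihood is evaluated on a validation
  # common-random-numbers stream distinct from the optimization stream:
  # optimizing against one frozen Monte-Carlo draw lets richer models chase
  # its noise, which would bias AIC comparisons toward extra parameters.
  val_seed <- derive_seed(seed, 2027)
  val_replicates <- max(final_replicates, 50000)
  lnCL <- tryCatch({
    model_hat <- spec$assemble(estimates)
    ex_val <- expected_sfs(model_hat, obs$n_hap,
                           n_replicates = val_replicates, seed = val_seed)
    composite_loglik(obs, ex_val, mu = spec$mu)
  }, error = function(e) NA_real_)
  if (!is.finite(lnCL)) lnCL <- -best$value
  lnCL_opt <- -best$value
  model <- spec$assemble(estimates)
  aic <- 2 * k - 2 * lnCL
  starts_tbl <- tibble::tibble(
    start = seq_len(n_all),
    warm_start = seq_len(n_all) > n_starts,
    lnCL_search = -vapply(search, `[[`, numeric(1), "value"),
    converged = vapply(search, function(s) s$conv == 0, logical(1)),
    polished = seq_len(n_all) %in% polish_ix)
  fit <- structure(list(
    model_id = spec$id, estimates = estimates, lnCL = lnCL,
    lnCL_opt = lnCL_opt, k = k,
    AIC = aic, model = model, spec = spec,
    derived = NULL,
    starts = starts_tbl, best_start = best$start,
    n_replicates = n_replicates, search_replicates = search_replicates,
    seed = seed, crn_seed = crn_seed,
    obs_signature = obs_signature(obs),
    convergence = best$conv == 0,
    use_mono = use_mono), class = "mg_fit")
  fit$derived <- derive_quantities(fit)
  fit
}

# Method-of-moments warm-start grid on the z (logit) scale. Sizes come from
# per-population Watterson estimates (polymorphic-site counts against the
# callable length); the split time from the heterozygosity-based FST of the
# spectrum via the drift relation T = -2 Ne ln(1 - FST) is crossed with
# multipliers covering the time/migration degeneracy, and migration-bearing
# models add a migration grid. Returns a 0-row matrix when the spectrum
# carries no monomorphic mass (sizes are then not identifiable by moments).
moment_grid <- function(obs, spec, to_z) {
  sp <- spec$space
  if (is.na(obs$monomorphic) || length(obs$n_hap) != 2)
    return(matrix(numeric(0), 0, nrow(sp)))
  L <- obs$monomorphic + sum(obs$counts)
  mu <- spec$mu
  cells <- sfs_cells(dim(obs$counts))
  cnt <- as.vector(obs$counts)
  poly_k <- function(k) sum(cnt[cells[, k] >= 1 & cells[, k] <= obs$n_hap[k] - 1])
  ne_k <- vapply(1:2, function(k) {
    a_n <- sum(1 / seq_len(obs$n_hap[k] - 1))
    max(poly_k(k) / (4 * mu * L * a_n), 1.1 * min(sp$lower[sp$log10]))
  }, numeric(1))
  # heterozygosity-based FST over polymorphic cells
  p1 <- cells[, 1] / obs$n_hap[1]; p2 <- cells[, 2] / obs$n_hap[2]
  hs <- sum(cnt * (p1 * (1 - p1) + p2 * (1 - p2)))
  pbar <- (cells[, 1] + cells[, 2]) / sum(obs$n_hap)
  ht <- sum(cnt * 2 * pbar * (1 - pbar))
  fst <- if (ht > 0) max(1 - hs / ht, 0.005) else 0.05
  ne_h <- 2 / (1 / ne_k[1] + 1 / ne_k[2])
  t0 <- min(max(-2 * ne_h * log(1 - min(fst, 0.95)), 200), 9e6)
  extras <- setdiff(sp$name, c("ne1", "ne2", "ne_anc", "t_div"))
  has_mig <- "m12" %in% sp$name
  fill <- function(t_mult, m) {
    th <- c(ne1 = ne_k[1], ne2 = ne_k[2],
            ne_anc = sqrt(ne_k[1] * ne_k[2]),
            t_div = min(max(t0 * t_mult, sp$lower[sp$name == "t_div"]),
                        sp$upper[sp$name == "t_div"]))
    for (nm in extras) {
      th[nm] <- switch(nm,
                       m12 = m, m21 = m, m13 = m, m31 = m, m23 = m, m32 = m,
                       g1 = 0, g2 = 0,
                       t_event_frac = 0.5, t1_frac = 0.5,
                       ratio1 = , ratio2 = {
                         b <- sp[sp$name == nm, ]
                         sqrt(b$lower * b$upper)
                       },
                       ne_anc13 = sqrt(ne_k[1] * ne_k[2]))
    }
    to_z(th[sp$name])
  }
  t_mults <- c(0.5, 2, 8, 32)
  m_grid <- if (has_mig) c(1e-7, 1e-6, 1e-5, 1e-4) else 1e-9
  out <- do.call(rbind, lapply(t_mults, function(tm)
    do.call(rbind, lapply(m_grid, function(m) fill(tm, m)))))
  attr(out, "t_mult") <- rep(t_mults, each = length(m_grid))
  out
}

obs_signature <- function(obs) {
  c(sum(obs$counts), length(obs$counts), obs$monomorphic,
    as.numeric(obs$folded))
}

#' @export
print.mg_fit <- function(x, ...) {
  cat("<mg_fit> model '", x$model_id, "': lnCL = ", format(x$lnCL),
      ", k = ", x$k, ", AIC = ", format(x$AIC), "\n", sep = "")
  print(signif(x$estimates, 4))
  invisible(x)
}

#' @describeIn fit_model Parameter estimates as a tibble.
#' @param x An `mg_fit`.
#' @param ... Unused.
#' @export
tidy.mg_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' @describeIn fit_model One-row fit summary.
#' @export
glance.mg_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, k = x$k, lnCL = x$lnCL, AIC = x$AIC,
                 converged = x$convergence, best_start = x$best_start,
                 seed = x$seed)
}

#' Rank fitted models by AIC
#'
#' `AIC = 2k - 2 lnCL`; models are sorted ascending, ties broken by smaller k
#' and then catalogue order. All fits must target the same observed spectrum.
#'
#' @param fits List of `mg_fit` objects (>= 2).
#' @return An object of class `mg_model_selection`: tibble `table` with
#'   `model_id`, `k`, `lnCL`, `AIC`, `delta_AIC`, and `best_id`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits", call. = FALSE)
  sigs <- lapply(fits, `[[`, "obs_signature")
  same <- vapply(sigs, function(s) isTRUE(all.equal(s, sigs[[1]])), logical(1))
  if (!all(same))
    stop("fits were made on different observed spectra", call. = FALSE)
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(model_id = f$model_id, k = f$k, lnCL = f$lnCL, AIC = f$AIC))
  cat_order <- match(tab$model_id, catalogue_ids())
  ord <- order(tab$AIC, tab$k, cat_order)
  tab <- tab[ord, ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  structure(list(table = tab, best_id = tab$model_id[1]),
            class = "mg_model_selection")
}

#' @export
print.mg_model_selection <- function(x, ...) {
  print(as.data.frame(x$table))
  cat("best model:", x$best_id, "\n")
  invisible(x)
}

#' @describeIn select_model The ranking table.
#' @param x An `mg_model_selection`.
#' @param ... Unused.
#' @export
tidy.mg_model_selection <- function(x, ...) x$table

#' Derived demographic quantities
#'
#' Converts a fit's natural-scale estimates into the quantities a summary
#' table reports: divergence time in years (`T_generations x generation
#' time`), and the effective number of migrants per generation per direction,
#' `Nm[A -> B] = Ne_A x m[A -> B]` (source population size times the forward
#' migration rate). Values are reported at full precision together with the
#' conventional display rounding (Ne to the nearest 10,000; Nm to one
#' decimal, rounding half away from zero).
#'
#' @param fit An `mg_fit`, or a named estimate vector via `estimates`.
#' @param mu Mutation rate (taken from the fit's model if omitted).
#' @param gen_time Generation time in years (likewise).
#' @return A list: `t_div_years`, `t_div_years_display`, tibble `nm` (`from`,
#'   `to`, `ne_source`, `m`, `nm`, `nm_display`), `ne_display`.
#' @export
derive_quantities <- function(fit, mu = NULL, gen_time = NULL) {
  if (inherits(fit, "mg_model")) {
    model <- fit
    joins <- model$events[model$events$kind == "join", ]
    t_div <- if (nrow(joins)) max(joins$time) else NA_real_
  } else {
    model <- fit$model
    t_div <- unname(fit$estimates["t_div"])
  }
  gen_time <- gen_time %||% model$gen_time
  labs <- model$pop_labels
  mig <- model$migration
  ne <- setNames(model$ne, labs)
  combos <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
  combos <- combos[combos$from != combos$to, ]
  nm <- tibble::tibble(
    from = combos$from, to = combos$to,
    ne_source = unname(ne[combos$from]),
    m = mig[cbind(match(combos$from, labs), match(combos$to, labs))])
  nm$nm <- nm$ne_source * nm$m
  nm$nm_display <- round_half_away(nm$nm, 1)
  list(t_div_years = t_div * gen_time,
       t_div_years_display = round_half_away(t_div * gen_time / 1e4) * 1e4,
       nm = nm,
       ne_display = round_half_away(ne / 1e4) * 1e4)
}

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates `n_boot` spectra from the fitted model at the observed site
#' count (multinomial draws from the model-expected cell probabilities,
#' including the monomorphic cell when the observed spectrum carries one),
#' refits each with a reduced number of starts initialized from the original
#' optimum, and reports percentile intervals per parameter.
#'
#' @param fit An `mg_fit`.
#' @param obs The observed `mg_sfs` the fit was made on.
#' @param n_boot Bootstrap replicates (warning below 20).
#' @param seed Integer seed.
#' @param n_starts Starts per bootstrap refit (default 3).
#' @param level Interval level (default 0.95).
#' @return Tibble with `term`, `estimate`, `lower`, `upper`, plus attribute
#'   `replicates` (matrix of bootstrap estimates).
#' @export
bootstrap_ci <- function(fit, obs, n_boot = 50, seed, n_starts = 3,
                         level = 0.95) {
  stopifnot(inherits(fit, "mg_fit"), inherits(obs, "mg_sfs"))
  if (n_boot < 20) warning("n_boot < 20: intervals will be unstable")
  ex <- expected_sfs(fit$model, obs$n_hap, n_replicates = fit$n_replicates,
                     seed = fit$crn_seed)
  use_mono <- !is.na(obs$monomorphic)
  pr <- expected_probs(ex, folded = obs$folded, mu = fit$spec$mu,
                       use_mono = use_mono)
  S <- sum(obs$counts)
  total <- if (use_mono) S + obs$monomorphic else S
  probs <- pr$q[pr$support]
  if (use_mono) probs <- c(probs, pr$p_mono) else probs <- probs / sum(probs)
  reps <- run_seeded(seed, {
    lapply(seq_len(n_boot), function(b)
      as.vector(rmultinom(1, total, probs)))
  })
  est_mat <- matrix(NA_real_, n_boot, length(fit$estimates),
                    dimnames = list(NULL, names(fit$estimates)))
  for (b in seq_len(n_boot)) {
    counts <- numeric(length(pr$q))
    draw <- reps[[b]]
    mono_b <- if (use_mono) draw[length(draw)] else NA_real_
    counts[pr$support] <- draw[seq_len(sum(pr$support))]
    obs_b <- obs
    obs_b$counts <- array(counts, dim = dim(obs$counts))
    obs_b$monomorphic <- mono_b
    f <- fit_model(obs_b, fit$spec, n_starts = n_starts,
                   seed = derive_seed(seed, b),
                   n_replicates = fit$n_replicates,
                   search_replicates = fit$search_replicates,
                   n_polish = 1, maxit = 60)
    est_mat[b, ] <- f$estimates
  }
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    term = names(fit$estimates),
    estimate = unname(fit$estimates),
    lower = apply(est_mat, 2, quantile, alpha),
    upper = apply(est_mat, 2, quantile, 1 - alpha))
  attr(out, "replicates") <- est_mat
  out
}
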