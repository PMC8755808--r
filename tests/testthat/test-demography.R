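test_that("the model catalogue exposes the documented parameter counts and constraints", {
  expect_equal(build_model("i")$k, 4)
  expect_equal(build_model("ii")$k, 6)
  expect_equal(build_model("iii")$k, 6)
  expect_equal(build_model("iv")$k, 8)
  expect_equal(build_model("v")$k, 9)
  expect_equal(build_model("vi")$k, 7)
  expect_equal(build_model("vii")$k, 9)
  expect_equal(build_model("viii")$k, 7)
  expect_equal(build_model("ix")$k, 9)
  expect_equal(build_model("x")$k, 9)
  # null model: migration and growth are fixed at zero
  spec_i <- build_model("i")
  m_i <- spec_i$assemble(c(ne1 = 1e4, ne2 = 2e4, ne_anc = 3e4, t_div = 1e5))
  expect_true(all(m_i$migration == 0))
  expect_true(all(m_i$growth == 0))
  # ix: bottleneck in pop 1 (ratio < 1), sudden expansion in pop 2 (> 1)
  sp_ix <- build_model("ix")$space
  expect_lt(sp_ix$upper[sp_ix$name == "ratio1"], 1)
  expect_gt(sp_ix$lower[sp_ix$name == "ratio2"], 1)
  sp_x <- build_model("x")$space
  expect_gt(sp_x$lower[sp_x$name == "ratio1"], 1)
  expect_lt(sp_x$upper[sp_x$name == "ratio2"], 1)
  expect_error(build_model("nope"), "unknown catalogue id")
  # event models place the size change before the divergence join
  m_v <- build_model("v")$assemble(c(
    ne1 = 1e4, ne2 = 1e4, ne_anc = 2e4, t_div = 1e5, m12 = 1e-6, m21 = 1e-6,
    t_event_frac = 0.5, ratio1 = 0.2, ratio2 = 0.2))
  ev <- m_v$events
  expect_lt(min(ev$time[ev$kind == "resize" & ev$pop == "pop1"]),
            max(ev$time[ev$kind == "join"]))
  # 3-population variants
  expect_equal(build_model("3pop_null", c("a", "b", "c"))$k, 7)
  expect_equal(build_model("3pop_mig", c("a", "b", "c"))$k, 13)
})

test_that("expected_sfs reproduces neutral closed forms and is seed-deterministic", {
  m1 <- demographic_model("popA", ne = 1e4)
  ex <- expected_sfs(m1, 12, n_replicates = 20000, seed = 8)
  p <- ex$lengths[2:12] / sum(ex$lengths[2:12])
  p_exp <- (1 / (1:11)) / sum(1 / (1:11))
  se <- sqrt(p_exp * (1 - p_exp) / 20000) / sum(1 / (1:11)) * (1:11)
  expect_true(all(abs(p - p_exp) / p_exp < 0.1))
  expect_equal(ex$total_length, 4e4 * sum(1 / (1:11)), tolerance = 0.02)
  ex2 <- expected_sfs(m1, 12, n_replicates = 20000, seed = 8)
  expect_identical(ex$lengths, ex2$lengths)
  expect_warning(expected_sfs(m1, 12, n_replicates = 50, seed = 1),
                 "Monte-Carlo")
})

test_that("expected_sfs agrees with the site simulator under an identical model", {
  # dual route: branch-length weighting vs realized mutations, same model
  m <- im_model(1e4, 1e4, 1e4, 1e6, m12 = 2.5e-5, m21 = 2.5e-5)
  ex <- expected_sfs(m, c(4, 4), n_replicates = 30000, seed = 6)
  p_exp <- ex$lengths / sum(ex$lengths)
  sim <- simulate_dataset(simulation_config(m, c(2, 2), n_sites = 30000,
                                            callable_length = 1e7, seed = 60))
  s <- joint_sfs(sim$geno, folded = FALSE)
  p_obs <- s$counts / sum(s$counts)
  for (cell in which(p_exp > 0.005)) {
    se <- sqrt(p_exp[cell] * (1 - p_exp[cell]) / 30000) +
      sqrt(p_exp[cell] * (1 - p_exp[cell]) / sum(s$counts))
    expect_lt(abs(p_obs[cell] - p_exp[cell]), 4 * se)
  }
})

test_that("composite likelihood matches hand arithmetic and the MLE property", {
  expect_equal(composite_loglik(c(3, 1), c(0.75, 0.25)), -2.2493,
               tolerance = 1e-4 / 2.2493)
  # zero-count cells contribute exactly 0
  expect_equal(composite_loglik(c(3, 0, 1), c(0.7, 0.05, 0.25)),
               composite_loglik(c(3, 1), c(0.7, 0.25)))
  expect_error(composite_loglik(c(1, 2), c(0.5, 0.3, 0.2)), "mismatch")
  # among probability vectors, lnCL is maximized at the empirical frequencies
  m <- c(5, 1, 0, 3, 2, 9)
  p_hat <- m / sum(m)
  ll_hat <- composite_loglik(m, pmax(p_hat, 1e-12))
  set.seed(2)
  for (i in 1:200) {
    p <- rexp(6); p <- p / sum(p)
    expect_lte(composite_loglik(m, p), ll_hat + 1e-12)
  }
})

test_that("AIC identities, ranking and tie-breaking are exact", {
  mk_fit <- function(id, lnCL, k) {
    structure(list(model_id = id, lnCL = lnCL, k = k, AIC = 2 * k - 2 * lnCL,
                   obs_signature = c(1, 2, 3, 4)), class = "mg_fit")
  }
  expect_equal(mk_fit("i", -100, 3)$AIC, 206)
  fits <- list(mk_fit("i", -100, 4), mk_fit("ii", -100, 6),
               mk_fit("iii", -95, 6), mk_fit("iv", -90, 8))
  sel <- select_model(fits)
  # hand computation: AICs are 208, 212, 202, 196
  expect_equal(sel$table$AIC, c(196, 202, 208, 212))
  expect_equal(sel$best_id, "iv")
  expect_equal(sel$table$delta_AIC, c(0, 6, 12, 16))
  # equal lnCL: smaller k ranks first
  sel2 <- select_model(list(mk_fit("ii", -100, 6), mk_fit("i", -100, 4)))
  expect_equal(sel2$best_id, "i")
  bad <- mk_fit("i", -1, 4); bad$obs_signature <- c(9, 9, 9, 9)
  expect_error(select_model(list(fits[[1]], bad)), "different observed")
})

test_that("derived quantities reproduce the published Nm and year identities", {
  tab <- summary_nm_table()
  # Ne 910,000 at m = 1e-5 gives 9.1 migrants per generation
  rha <- tab[tab$species == "Rhipidura albolimbata" & tab$from == "Wilhelm", ]
  expect_equal(rha$nm_display, 9.1)
  tox <- tab[tab$species == "Toxorhamphus novaeguineae" &
               tab$from == "Wilhelm" & tab$to == "Huon", ]
  expect_equal(tox$nm_display, 4.7)
  # zero migration gives zero migrants
  expect_true(all(tab$nm[tab$m == 0] == 0))
  # most printed values verify exactly; the known exceptions are recorded
  expect_gte(sum(tab$matches_printed), nrow(tab) - 2)
  # year scaling: 50,000 generations at 2 years per generation
  m <- im_model(1e4, 1e4, 1e4, 5e4)
  dq <- derive_quantities(m)
  expect_equal(dq$t_div_years, 1e5)
})

test_that("mean published divergence for New Guinea converts to 1.2 My", {
  md <- mean_divergence_time(region = "New Guinea")
  expect_equal(md$n, 13)
  expect_equal(md$mean_my_display, 1.2)
})

test_that("likelihood surface is deterministic and improves from truth under ascent", {
  truth <- im_model(2e4, 2e4, 2e4, 8e4, m12 = 2e-5, m21 = 2e-5)
  sim <- simulate_dataset(simulation_config(truth, c(6, 6),
                                            callable_length = 2e6, seed = 71,
                                            mutation_mode = "poisson",
                                            n_loci = 1000))
  obs <- joint_sfs(sim$geno, folded = TRUE, callable_length = 2e6)
  f1 <- fit_model(obs, "ii", n_starts = 4, seed = 3, n_replicates = 2000,
                  search_replicates = 800, n_polish = 1, maxit = 120)
  f2 <- fit_model(obs, "ii", n_starts = 4, seed = 3, n_replicates = 2000,
                  search_replicates = 800, n_polish = 1, maxit = 120)
  expect_identical(f1$lnCL, f2$lnCL)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$lnCL)
  # a start at the generating truth cannot end below the truth likelihood
  truth_par <- c(ne1 = 2e4, ne2 = 2e4, ne_anc = 2e4, t_div = 8e4,
                 m12 = 2e-5, m21 = 2e-5)
  f3 <- fit_model(obs, "ii", n_starts = 1, seed = 3, n_replicates = 2000,
                  search_replicates = 2000, n_polish = 1, maxit = 150,
                  extra_starts = list(truth_par))
  ex <- expected_sfs(truth, obs$n_hap, n_replicates = 2000,
                     seed = f3$crn_seed)
  ll_truth <- composite_loglik(obs, ex, mu = 3e-9)
  expect_gte(f3$lnCL_opt, ll_truth)
})

test_that("bootstrap intervals are deterministic given the seed and cover the estimate", {
  truth <- im_model(2e4, 2e4, 2e4, 1e5)
  sim <- simulate_dataset(simulation_config(truth, c(5, 5),
                                            callable_length = 2e6, seed = 83,
                                            mutation_mode = "poisson",
                                            n_loci = 800))
  obs <- joint_sfs(sim$geno, folded = TRUE, callable_length = 2e6)
  fit <- fit_model(obs, "i", n_starts = 3, seed = 2, n_replicates = 1500,
                   search_replicates = 600, n_polish = 1, maxit = 100)
  expect_warning(
    ci <- bootstrap_ci(fit, obs, n_boot = 6, seed = 11, n_starts = 1),
    "n_boot")
  expect_warning(
    ci2 <- bootstrap_ci(fit, obs, n_boot = 6, seed = 11, n_starts = 1),
    "n_boot")
  expect_equal(ci$lower, ci2$lower)
  expect_true(all(ci$lower <= ci$upper))
  reps <- attr(ci, "replicates")
  expect_equal(dim(reps), c(6, 4))
  # bootstrap estimates scatter around the fitted values, not at the bounds
  expect_true(all(is.finite(reps)))
})

test_that("a 3-population model with no migration and equal split times reduces to pairwise", {
  spec3 <- build_model("3pop_null", c("a", "b", "c"))
  th <- c(ne1 = 2e4, ne2 = 1.5e4, ne3 = 1e4, ne_anc13 = 2e4, ne_anc = 3e4,
          t_div = 1e5, t1_frac = 1)  # both joins at the same time
  m3 <- spec3$assemble(th)
  ex3 <- expected_sfs(m3, c(8, 8, 8), n_replicates = 15000, seed = 4)
  # marginal over population c should match the plain two-population model
  m2 <- im_model(2e4, 1.5e4, 3e4, 1e5, pop_labels = c("a", "b"))
  ex2 <- expected_sfs(m2, c(8, 8), n_replicates = 15000, seed = 14)
  marg <- apply(ex3$lengths, c(1, 2), sum)
  # the (a,b) marginal of the 3-population tree equals the 2-population
  # process cell for cell, except that the segment between the (a,b) MRCA
  # and the global root adds mass only to the all-derived corner; exclude
  # the two corner cells from both and compare shapes
  d <- dim(marg)
  mask <- matrix(TRUE, d[1], d[2])
  mask[1, 1] <- mask[d[1], d[2]] <- FALSE
  p3 <- marg * mask / sum(marg[mask])
  p2 <- ex2$lengths * mask / sum(ex2$lengths[mask])
  big <- which(p2 > 0.01)
  for (cell in big) {
    se <- sqrt(p2[cell] * (1 - p2[cell]) / 15000) * 2
    expect_lt(abs(p3[cell] - p2[cell]), 3 * se + 0.05 * p2[cell])
  }
})
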