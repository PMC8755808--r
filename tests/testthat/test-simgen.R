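test_that("simulation is deterministic: same config and seed give identical VCF bytes", {
  m <- im_model(1e4, 1e4, 1e4, 5e4)
  cfg <- simulation_config(m, c(4, 4), n_sites = 150, callable_length = 1e6,
                           seed = 42)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_dataset(cfg)$geno, f1)
  write_vcf(simulate_dataset(cfg)$geno, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the data
  cfg2 <- simulation_config(m, c(4, 4), n_sites = 150, callable_length = 1e6,
                            seed = 43)
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_dataset(cfg2)$geno, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("every simulated site is biallelic, segregating, with dosage genotypes", {
  m <- im_model(2e4, 1e4, 1.5e4, 2e5, m12 = 1e-5)
  sim <- simulate_dataset(simulation_config(m, c(6, 5), n_sites = 400,
                                            callable_length = 1e6, seed = 7))
  g <- sim$geno
  expect_equal(nrow(g$sites), 400)
  expect_true(all(g$geno %in% 0:2))
  ac <- rowSums(g$geno)
  expect_true(all(ac > 0 & ac < 2 * 11))
  expect_true(all(diff(g$sites$pos) > 0))
  expect_equal(sim$truth$model$ne, c(2e4, 1e4))
})

test_that("deep divergence with no migration gives near-fixed populations (high FST)", {
  ne <- 5e3
  m <- im_model(ne, ne, ne, 20 * 2 * ne)  # 20 coalescent units of separation
  sim <- simulate_dataset(simulation_config(m, c(10, 10), n_sites = 5000,
                                            callable_length = 1e7, seed = 9))
  fst <- wc_fst(sim$geno)
  expect_gte(fst$theta, 0.8)
})

test_that("segregating sites in poisson mode match Watterson's expectation", {
  # one population, n = 6 diploids (12 haploids): E[S] = theta * sum_{1}^{11} 1/i
  ne <- 1e4; mu <- 3e-9
  n_loci <- 300; locus_len <- 1e4
  m <- demographic_model("popA", ne = ne, mu = mu)
  cfg <- simulation_config(m, samples_per_pop = 6, n_sites = 1,
                           callable_length = n_loci * locus_len, seed = 31,
                           mutation_mode = "poisson", n_loci = n_loci)
  sim <- simulate_dataset(cfg)
  S_obs <- nrow(sim$geno$sites)
  theta_locus <- 4 * ne * mu * locus_len
  ES_locus <- theta_locus * sum(1 / (1:11))
  # var[S] per locus (neutral): E[S] + theta^2 * sum 1/i^2
  VS_locus <- ES_locus + theta_locus^2 * sum(1 / (1:11)^2)
  se <- sqrt(n_loci * VS_locus)
  expect_lt(abs(S_obs - n_loci * ES_locus), 3 * se)
})

test_that("unfolded single-population SFS is proportional to 1/i", {
  m <- demographic_model("popA", ne = 1e4)
  sim <- simulate_dataset(simulation_config(m, 6, n_sites = 20000,
                                            callable_length = 1e7, seed = 13))
  sfs <- joint_sfs(sim$geno, folded = FALSE)
  counts <- as.vector(sfs$counts)[2:12]
  p_exp <- (1 / (1:11)) / sum(1 / (1:11))
  expected <- sum(counts) * p_exp
  # 3 sigma per cell, binomial MC error
  se <- sqrt(sum(counts) * p_exp * (1 - p_exp))
  expect_true(all(abs(counts - expected) < 3.5 * se))
})

test_that("symmetric island model yields a symmetric joint SFS", {
  m <- im_model(1e4, 1e4, 1e4, 1e6, m12 = 2.5e-5, m21 = 2.5e-5)
  ex <- expected_sfs(m, c(8, 8), n_replicates = 20000, seed = 3)
  L <- ex$lengths
  p <- L / sum(L)
  # symmetric cells should agree within Monte-Carlo error
  npair <- 0; nfail <- 0
  for (i in 1:9) for (j in 1:9) {
    if (i >= j) next
    se <- sqrt((p[i, j] + p[j, i]) / 20000)  # crude per-pair MC scale
    if (p[i, j] + p[j, i] < 1e-4) next
    npair <- npair + 1
    if (abs(p[i, j] - p[j, i]) > 3 * se) nfail <- nfail + 1
  }
  expect_lt(nfail / npair, 0.05)
})

test_that("config validation rejects degenerate models and inputs", {
  expect_error(demographic_model("a", ne = 0), "ne")
  expect_error(demographic_model(c("a", "b"), ne = c(1e4, 1e4),
                                 events = tibble::tibble(
                                   time = c(100, 50), kind = "resize",
                                   pop = "a", pop_to = NA, size = 1e3,
                                   growth = 0)),
               "ordered")
  m <- im_model(1e4, 1e4, 1e4, 1e4)
  expect_error(simulation_config(m, c(1, 4), n_sites = 10,
                                 callable_length = 100, seed = 1),
               "diploids")
  expect_error(simulation_config(m, c(4, 4), n_sites = 10,
                                 callable_length = 5, seed = 1),
               "callable_length")
  expect_error(simulation_config(m, c(4, 4), n_sites = 10,
                                 callable_length = 100), "seed")
  # a population referenced after its join is invalid
  expect_error(demographic_model(
    c("a", "b"), ne = c(1e4, 1e4),
    events = tibble::tibble(
      time = c(100, 200), kind = c("join", "resize"),
      pop = c("b", "b"), pop_to = c("a", NA),
      size = c(NA, 1e3), growth = c(NA, 0))),
    "joined away")
})

test_that("planted half-sibs estimate kinship near 0.125 and duplicates near 0.5", {
  m <- demographic_model("popA", ne = 2e4)
  cfg <- simulation_config(m, 8, n_sites = 50000, callable_length = 1e7,
                           seed = 21)
  sim <- simulate_dataset(cfg)
  # restrict to reasonably common sites, as a real kinship workflow would
  p <- rowMeans(sim$geno$geno) / 2
  keep <- which(p >= 0.05 & p <= 0.95)
  g <- montgen:::subset_geno(sim$geno, i = keep)
  g2 <- inject_halfsibs(g, list(c("popA_01", "popA_02")), seed = 5)
  kin <- kinship_matrix(g2)
  expect_equal(kin$phi["popA_01", "popA_02"], 0.125, tolerance = 0.015 / 0.125)
  ped <- attr(g2, "pedigree")
  expect_equal(ped$relationship, "half-sib")
  # duplicate limit: copying a sample gives phi ~ 0.5
  g3 <- g
  g3$geno[, "popA_03"] <- g3$geno[, "popA_04"]
  kin3 <- kinship_matrix(g3)
  expect_equal(kin3$phi["popA_03", "popA_04"], 0.5, tolerance = 0.02)
  # empty pair spec is the identity
  expect_identical(inject_halfsibs(g, list(), seed = 1)$geno, g$geno)
  # unknown sample errors
  expect_error(inject_halfsibs(g, list(c("popA_01", "nope")), seed = 1),
               "missing sample")
})

test_that("covariate panel records floors, rates and monotonicity", {
  base <- im_model(5e3, 5e3, 5e3, 4e4)
  pan <- simulate_covariate_panel(
    6, function(f) 1e-4 * exp(-f / 500), base, seed = 2,
    samples_per_pop = c(4, 4), n_sites = 300)
  expect_equal(nrow(pan), 6)
  expect_true(attr(pan, "monotone_mapping"))
  expect_true(all(diff(pan$migration) < 0))
  expect_s3_class(pan$geno[[1]], "mg_geno")
  expect_error(simulate_covariate_panel(1, identity, base, seed = 1),
               "n_species")
  # non-monotone mapping accepted but flagged
  pan2 <- simulate_covariate_panel(
    5, function(f) 1e-5 * (1 + sin(f / 100)), base, seed = 3,
    samples_per_pop = c(4, 4), n_sites = 50)
  expect_false(attr(pan2, "monotone_mapping"))
  expect_false(pan2$truth[[1]]$monotone_mapping)
})
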