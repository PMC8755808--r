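make_fixture_vcf <- function(path) {
  # 5 hand-built records: clean SNP, triallelic, indel, SNP next to the
  # indel, SNP with a missing call
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s01", "s02"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50.0\tPASS\t.\tGT:DP\t0/1:30\t1/1:25",
    "chr1\t200\t.\tG\tA,C\t44.0\tPASS\t.\tGT:DP\t1/2:30\t0/1:31",
    "chr1\t300\t.\tAT\tA\t60.0\tPASS\t.\tGT:DP\t0/1:28\t0/0:30",
    "chr1\t303\t.\tC\tG\t55.0\tPASS\t.\tGT:DP\t0/0:30\t0/1:33",
    "chr1\t400\t.\tT\tC\t47.0\tPASS\t.\tGT:DP\t./.:10\t1/1:30")
  writeLines(lines, path)
  path
}

fixture_map <- tibble::tibble(
  sample_id = c("s01", "s02"), population = c("p1", "p1"),
  elevation_m = c(1000, 1500), species = "spX")

test_that("read_vcf parses SNPs, flags multiallelics, measures indel distance", {
  path <- make_fixture_vcf(tempfile(fileext = ".vcf"))
  g <- read_vcf(path, fixture_map)
  # the indel record itself is excluded from the SNP matrix
  expect_equal(nrow(g$sites), 4)
  expect_equal(g$sites$pos, c(100L, 200L, 303L, 400L))
  expect_equal(g$sites$multiallelic, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(g$sites$dist_indel, c(200, 100, 3, 100))
  expect_equal(g$geno[1, ], c(s01 = 1L, s02 = 2L))
  expect_true(all(is.na(g$geno[2, ])))  # multiallelic codes carried as NA
  expect_true(is.na(g$geno[4, "s01"]))
  expect_equal(g$depth[1, ], c(s01 = 30, s02 = 25))
})

test_that("read_vcf round-trips the simulator output exactly", {
  m <- im_model(1e4, 1e4, 1e4, 5e4)
  sim <- simulate_dataset(simulation_config(m, c(4, 4), n_sites = 120,
                                            callable_length = 1e6, seed = 5))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, path)
  g2 <- read_vcf(path, sim$geno$samples)
  expect_equal(unname(g2$geno), unname(sim$geno$geno))
  expect_equal(unname(g2$depth), unname(sim$geno$depth * 1.0))
  expect_equal(g2$sites$qual, sim$geno$sites$qual)
  expect_equal(g2$samples$population, sim$geno$samples$population)
})

test_that("read_vcf rejects samples absent from the map and malformed genotypes", {
  path <- make_fixture_vcf(tempfile(fileext = ".vcf"))
  expect_error(read_vcf(path, fixture_map[1, ]), "absent from the sample map")
  bad <- readLines(path)
  bad[5] <- "chr1\t100\t.\tA\tT\t50.0\tPASS\t.\tGT:DP\t0/9:30\t1/1:25"
  bad_path <- tempfile(fileext = ".vcf")
  writeLines(bad, bad_path)
  expect_error(read_vcf(bad_path, fixture_map), "malformed genotype")
})

test_that("filter boundaries follow the published thresholds exactly", {
  # depth 9 removed ("less than 10"); depth 10 kept; qual 19.9 out, 20.0 in
  dosage <- matrix(c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 0L), 4, 2)
  depth <- matrix(30, 4, 2)
  depth[1, 1] <- 9
  depth[2, 1] <- 10
  qual <- c(60, 60, 19.9, 20.0)
  g <- make_geno(dosage, pops = c("p1", "p1"), depth = depth, qual = qual)
  out <- filter_sites(g)
  expect_equal(which(!seq_len(4) %in% NA & rowSums(out$violations) == 0),
               c(2L, 4L))
  expect_equal(out$violations[, "depth"], c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$violations[, "qual"], c(FALSE, FALSE, TRUE, FALSE))
})

test_that("a 12-site hand-built fixture filters down to the 4 clean sites", {
  # 2 low-depth, 1 high-depth, 2 low-qual, 1 triallelic, 1 near an indel,
  # 1 with a missing call, 4 clean
  S <- 12; N <- 3
  dosage <- matrix(1L, S, N); dosage[, 2] <- 0L
  depth <- matrix(50, S, N)
  qual <- rep(60, S)
  depth[1, 1] <- 5; depth[2, 3] <- 9          # low depth
  depth[3, 2] <- 150                           # high depth
  qual[4] <- 10; qual[5] <- 19.9               # low qual
  sites <- tibble::tibble(
    chrom = "chr1", pos = seq_len(S) * 100L, ref = "A", alt = "T",
    qual = qual, is_indel = FALSE, dist_indel = Inf, multiallelic = FALSE)
  sites$multiallelic[6] <- TRUE
  sites$dist_indel[7] <- 3                     # within the 5 bp indel window
  dosage[8, 2] <- NA                           # missing call
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            population = "p1", elevation_m = NA_real_,
                            species = "spX")
  g <- geno_matrix(sites, dosage, depth, samples)
  out <- filter_sites(g)
  expect_equal(nrow(out$geno$sites), 4)
  expect_equal(out$geno$sites$pos, c(900L, 1000L, 1100L, 1200L))
  expect_equal(out$n_removed, 8)
  expect_equal(out$removed$n[out$removed$rule == "depth"], 3)
  expect_equal(out$removed$n[out$removed$rule == "qual"], 2)
  expect_equal(out$removed$n[out$removed$rule == "not_biallelic"], 1)
  expect_equal(out$removed$n[out$removed$rule == "indel_proximity"], 1)
  expect_equal(out$removed$n[out$removed$rule == "missing_call"], 1)
})

test_that("filtering is idempotent and matches union-of-violations arithmetic", {
  m <- im_model(1e4, 1e4, 1e4, 1e5)
  sim <- simulate_dataset(simulation_config(m, c(5, 5), n_sites = 500,
                                            callable_length = 1e6, seed = 17))
  out1 <- filter_sites(sim$geno)
  out2 <- filter_sites(out1$geno)
  expect_equal(out2$n_removed, 0)
  expect_equal(out2$geno$sites, out1$geno$sites)
  # survivors = total - |union of per-rule violation sets|
  union_size <- sum(rowSums(out1$violations) > 0)
  expect_equal(nrow(out1$geno$sites), 500 - union_size)
  # rule order invariance: applying single rules in any order gives the same
  # surviving set as the simultaneous filter
  cfg_depth <- site_filter_config(min_qual = 0, indel_proximity_bp = 0,
                                  biallelic_only = FALSE,
                                  require_complete = FALSE)
  cfg_qual <- site_filter_config(min_depth = 0, max_depth = Inf,
                                 indel_proximity_bp = 0,
                                 biallelic_only = FALSE,
                                 require_complete = FALSE)
  seq1 <- filter_sites(filter_sites(sim$geno, cfg_depth)$geno, cfg_qual)$geno
  seq2 <- filter_sites(filter_sites(sim$geno, cfg_qual)$geno, cfg_depth)$geno
  expect_equal(seq1$sites, seq2$sites)
})
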