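test_that("all generators are bit-reproducible under a fixed seed", {
  t1 <- gen_trajectory_dataset(1.2, n_populations = 1, census_size = 500, seed = 3)
  t2 <- gen_trajectory_dataset(1.2, n_populations = 1, census_size = 500, seed = 3)
  expect_identical(t1$observations, t2$observations)
  c1 <- gen_competition_dataset(0.5, n_blocks = 3, seed = 3)
  c2 <- gen_competition_dataset(0.5, n_blocks = 3, seed = 3)
  expect_identical(c1$records, c2$records)
  s1 <- gen_snp_dataset(n_individuals = 20, n_loci = 12, seed = 3)
  s2 <- gen_snp_dataset(n_individuals = 20, n_loci = 12, seed = 3)
  expect_identical(s1$snps$genotypes, s2$snps$genotypes)
  m1 <- gen_male_fitness_dataset(1, n_plates = 6, seed = 3)
  m2 <- gen_male_fitness_dataset(1, n_plates = 6, seed = 3)
  expect_identical(m1$records, m2$records)
})

test_that("generated tables carry truth sidecars and round-trip through the readers", {
  dir <- tempfile("synth")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  t1 <- gen_trajectory_dataset(
    1.2, n_populations = 1, census_size = 500, seed = 5, out_dir = dir
  )
  expect_true(file.exists(file.path(dir, "trajectory.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "trajectory.truth.json"))
  expect_equal(truth$true_alpha, 1.2)
  back <- read_table(file.path(dir, "trajectory.tsv"), "trajectory")
  expect_equal(back, t1$observations, ignore_attr = TRUE)
  gen_competition_dataset(0.3, n_blocks = 2, seed = 5, out_dir = dir)
  comp <- read_table(file.path(dir, "competition.tsv"), "competition")
  expect_true(nrow(comp) > 0)
  gen_snp_dataset(n_individuals = 10, n_loci = 6, seed = 5, out_dir = dir)
  snps <- read_table(file.path(dir, "snps.tsv"), "snp")
  expect_s3_class(snps, "snp_matrix")
  expect_equal(ncol(snps$genotypes), 6)
})

test_that("a selfing allele with alpha = 0 sweeps and males vanish immediately", {
  d <- gen_trajectory_dataset(
    0, n_populations = 2, census_size = 2000,
    sample_generations = c(0, 5, 10), seed = 7
  )
  obs <- d$observations
  later <- obs[obs$generation > 0, ]
  expect_true(all(later$male_count == 0))
  # wt counts non-decreasing in expectation: compare first vs last sample
  first <- obs[obs$generation == 0, "n_wt_alleles"]
  last <- obs[obs$generation == 10, "n_wt_alleles"]
  expect_true(all(last >= first))
})

test_that("competition datasets recover the generating fitness after block centering", {
  d <- gen_competition_dataset(
    true_w = 0.5, n_blocks = 12, block_sd = 0.25, seed = 11
  )
  est <- competition_fitness(d$records)
  cent <- block_center_and_delta(est, d$truth$reference_label)
  exp_rows <- cent$population_id == d$truth$population_id
  # block-centered records share the block reference mean: use block-level
  # paired estimates for the standard error
  block_w <- tapply(cent$w_t[exp_rows], cent$block[exp_rows], mean)
  se <- sd(block_w) / sqrt(length(block_w))
  expect_lt(abs(mean(block_w) - 0.5), 2 * se + 0.02)
  # raw w is contaminated by the shared block effects
  expect_gt(sd(tapply(est$w[est$population_id == d$truth$reference_label],
                      est$block[est$population_id == d$truth$reference_label],
                      mean)), 0.05)
})

test_that("null competition datasets estimate w near zero", {
  d <- gen_competition_dataset(
    true_w = 0, n_blocks = 8, block_sd = 0, seed = 13
  )
  est <- competition_fitness(d$records)
  w_all <- est$w
  expect_lt(abs(mean(w_all)), 2 * sd(w_all) / sqrt(length(w_all)) + 0.01)
})

test_that("snp generator reaches the partial-selfing heterozygosity equilibrium", {
  # S = 0: 1 - Ho matches the Hardy-Weinberg expectation within 2 SE
  d0 <- gen_snp_dataset(
    n_individuals = 200, n_loci = 40, selfing_rate = 0,
    missing_rate = 0, block_r = 0, seed = 17
  )
  exp_ho <- mean(2 * d0$truth$allele_freqs * (1 - d0$truth$allele_freqs))
  obs_ho <- 1 - homozygosity(d0$snps)
  se <- sd(2 * d0$truth$allele_freqs * (1 - d0$truth$allele_freqs)) /
    sqrt(length(d0$truth$allele_freqs))
  expect_lt(abs(obs_ho - exp_ho), 2 * se + 0.02)
  # high selfing: excess homozygosity F = S / (2 - S) and strong block LD
  d9 <- gen_snp_dataset(
    n_individuals = 200, n_loci = 40, selfing_rate = 0.9,
    missing_rate = 0, block_r = 0.9, seed = 19
  )
  Fis <- 0.9 / (2 - 0.9)
  exp_ho9 <- (1 - Fis) * exp_ho
  expect_lt(abs((1 - homozygosity(d9$snps)) - (1 - Fis) *
                  mean(2 * d9$truth$allele_freqs * (1 - d9$truth$allele_freqs))),
            0.06)
  expect_gt(homozygosity(d9$snps), homozygosity(d0$snps))
  expect_gt(
    composite_ld_mean_r2(d9$snps)$mean_r2,
    composite_ld_mean_r2(d0$snps)$mean_r2
  )
})

test_that("male-fitness datasets recover w_m and tally injected QC violations", {
  d <- gen_male_fitness_dataset(
    true_w_m = 1.1, n_plates = 20, progeny_mean = 100, seed = 23
  )
  est <- male_fitness(d$records)
  se <- sd(est$w_m) / sqrt(nrow(est))
  expect_lt(abs(mean(est$w_m) - 1.1), 2 * se + 0.02)
  # injected violations are rejected exactly
  dq <- gen_male_fitness_dataset(
    true_w_m = 0, n_plates = 20,
    frac_few_females = 0.2, frac_few_progeny = 0.1, seed = 29
  )
  kept <- qc_filter_male_plates(dq$records)
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["few_females"]), 4)
  expect_equal(unname(rej["few_progeny"]), 2)
  expect_equal(nrow(kept), 14)
})
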