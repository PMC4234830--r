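hwe_genotypes <- function(n, p, seed) {
  # unphased genotypes at Hardy-Weinberg proportions
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(s)
    code
  }
  with_seed(seed, matrix(
    rbinom(n * length(p), 2, rep(p, each = n)),
    nrow = n
  ))
}

test_that("homozygosity averages per-locus heterozygote proportions", {
  g_all_het <- matrix(1, 10, 4)
  expect_equal(homozygosity(snp_matrix(g_all_het, rep("P", 10))), 0)
  g_all_hom <- matrix(rep(c(0, 2), 20), 10, 4)
  expect_equal(homozygosity(snp_matrix(g_all_hom, rep("P", 10))), 1)
  # two loci with het proportions 0.2 and 0.4 -> 1 - 0.3
  g <- cbind(
    c(1, 1, rep(0, 8)),
    c(1, 1, 1, 1, rep(2, 6))
  )
  expect_equal(homozygosity(snp_matrix(g, rep("P", 10))), 0.7)
  # missing calls excluded from the per-locus proportion
  g[1, 1] <- NA
  expect_equal(homozygosity(snp_matrix(g, rep("P", 10))), 1 - (1 / 9 + 0.4) / 2)
})

test_that("MAF filter removes loci strictly below the threshold", {
  # column MAFs: 0 (monomorphic), 0.04, 0.05, 0.3
  n <- 50
  g <- cbind(
    rep(0, n),
    c(rep(1, 4), rep(0, n - 4)),   # p = 4/100
    c(rep(1, 5), rep(0, n - 5)),   # p = 5/100
    c(rep(1, 30), rep(0, n - 30))  # p = 0.3
  )
  colnames(g) <- paste0("L", 1:4)
  out <- maf_filter(snp_matrix(g, rep("P", n)))
  expect_equal(colnames(out$genotypes), c("L3", "L4"))
  expect_equal(attr(out, "dropped_loci"), c("L1", "L2"))
})

test_that("composite LD equals 1 for duplicated or mirrored loci", {
  x <- hwe_genotypes(200, 0.4, seed = 5)[, 1]
  dup <- cbind(a = x, b = x)
  ld <- composite_ld_mean_r2(snp_matrix(dup, rep("P", 200)))
  expect_equal(ld$mean_r2, 1)
  # opposite allele coding: squaring removes the sign
  mir <- cbind(a = x, b = 2 - x)
  expect_equal(
    composite_ld_mean_r2(snp_matrix(mir, rep("P", 200)))$mean_r2, 1
  )
})

test_that("composite LD matches the joint-table oracle and vanishes for independent loci", {
  g <- hwe_genotypes(400, c(0.2, 0.35, 0.5), seed = 7)
  colnames(g) <- paste0("L", 1:3)
  ld <- composite_ld_mean_r2(snp_matrix(g, rep("P", 400)))
  for (k in seq_len(nrow(ld$pairs))) {
    ia <- ld$pairs$locus_a[k]
    ib <- ld$pairs$locus_b[k]
    expect_equal(
      ld$pairs$r2[k],
      oracle_composite_r2_table(g[, ia], g[, ib]),
      tolerance = 1e-10
    )
  }
  # null simulation: independent HWE loci at large n have mean r2 < 0.01
  g0 <- hwe_genotypes(1e4, seq(0.1, 0.5, length.out = 10), seed = 9)
  colnames(g0) <- paste0("N", 1:10)
  expect_lt(composite_ld_mean_r2(snp_matrix(g0, rep("P", 1e4)))$mean_r2, 0.01)
})

test_that("diversity statistics are invariant to allele relabelling", {
  g <- hwe_genotypes(150, c(0.25, 0.4, 0.45), seed = 11)
  colnames(g) <- paste0("L", 1:3)
  flipped <- g
  flipped[, 2] <- 2 - flipped[, 2]
  a <- snp_matrix(g, rep("P", 150))
  b <- snp_matrix(flipped, rep("P", 150))
  expect_equal(homozygosity(a), homozygosity(b))
  expect_equal(
    composite_ld_mean_r2(a)$mean_r2,
    composite_ld_mean_r2(b)$mean_r2
  )
})

test_that("LD is absent with fewer than two post-filter loci and composable with the filter", {
  # one common locus plus one rare locus that the MAF filter removes
  n <- 100
  g <- cbind(
    A = hwe_genotypes(n, 0.4, seed = 13)[, 1],
    B = c(1, rep(0, n - 1))
  )
  ld <- composite_ld_mean_r2(snp_matrix(g, rep("P", n)))
  expect_true(is.na(ld$mean_r2))
  expect_equal(ld$n_loci_used, 1)
  # filtering first then computing LD equals LD on the kept loci
  g3 <- cbind(g, C = hwe_genotypes(n, 0.3, seed = 17)[, 1])
  pre <- maf_filter(snp_matrix(g3, rep("P", n)))
  expect_equal(
    composite_ld_mean_r2(snp_matrix(g3, rep("P", n)))$mean_r2,
    composite_ld_mean_r2(pre)$mean_r2
  )
})

test_that("staged missing-data cleaning applies its three thresholds in order", {
  set.seed(19)
  g <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  colnames(g) <- paste0("L", 1:10)
  rownames(g) <- paste0("i", 1:20)
  g[, 1][1:17] <- NA                  # locus > 80% missing
  g[2, 2:10] <- NA                    # individual > 60% missing
  g[3:13, 3] <- NA                    # locus > 50% missing after stage 2
  out <- clean_snp_matrix(snp_matrix(g, rep("P", 20)))
  dropped <- attr(out, "dropped")
  expect_equal(dropped$loci_stage1, "L1")
  expect_equal(dropped$individuals_stage2, "i2")
  expect_equal(dropped$loci_stage3, "L3")
  expect_equal(ncol(out$genotypes), 8)
  expect_equal(nrow(out$genotypes), 19)
})

test_that("the diversity ANCOVA matches a projection-matrix oracle", {
  set.seed(23)
  n <- 37
  dat <- data.frame(
    population = paste0("p", 1:n),
    covariate = runif(n, 0.3, 0.9),
    system = rep(c("trioecy", "monoecy", "androdioecy"), length.out = n)
  )
  dat$delta_w_t <- 0.4 * (dat$system == "monoecy") + rnorm(n, 0, 0.2)
  fit <- diversity_fitness_ancova(dat)
  # residual d.f. = n - 4 with one covariate and a 3-level factor
  expect_equal(fit$table$df, c(1, 2, 33))
  oracle <- oracle_ancova_projection(dat$delta_w_t, dat$covariate, dat$system)
  expect_equal(fit$table$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(fit$table$f_value[1:2], oracle$f_value[1:2], tolerance = 1e-8)
  # the two-populations-short case: residual d.f. drops to 31
  fit35 <- diversity_fitness_ancova(dat[1:35, ])
  expect_equal(fit35$table$df[3], 31)
  # degenerate inputs are refused
  dat$covariate <- 0.5
  expect_error(diversity_fitness_ancova(dat), "constant")
})

test_that("snp matrices reject bad codes and all-missing loci", {
  expect_error(snp_matrix(matrix(3, 2, 2), c("a", "b")), "0, 1, 2")
  g <- matrix(c(1, 1, NA, NA), 2, 2)
  colnames(g) <- c("ok", "empty")
  expect_error(snp_matrix(g, c("a", "b")), "empty")
})
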