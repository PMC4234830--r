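test_that("transition fitness recovers exact logit-linear slopes", {
  # p_t/(1-p_t) = exp(0.3 t): OLS recovers 0.3 to machine precision
  gens <- c(0, 5, 10, 15)
  p <- 1 / (1 + exp(-(0.3 * gens - 2)))
  ser <- data.frame(
    generation = gens,
    n_wt_alleles = round(p * 1e6), n_total_alleles = 1e6
  )
  # use exact frequencies rather than rounded counts for the precision check
  y <- log(p / (1 - p))
  fit <- lm(y ~ gens)
  expect_equal(unname(coef(fit)[2]), 0.3, tolerance = 1e-12)
  est <- transition_fitness(ser)
  expect_equal(est$s, 0.3, tolerance = 1e-5)
  # two-point hand computation with the 96/97 clamp
  two <- data.frame(
    generation = c(0, 10), n_wt_alleles = c(48, 96), n_total_alleles = 96
  )
  expect_equal(transition_fitness(two)$s, log(96) / 10)
  # constant frequencies give slope 0
  const <- data.frame(
    generation = c(0, 10, 20), n_wt_alleles = 48, n_total_alleles = 96
  )
  expect_equal(transition_fitness(const)$s, 0)
  expect_error(
    transition_fitness(const[c(1, 1), ]), "distinct generations"
  )
})

test_that("transition fitness pools replicate populations with one slope", {
  # frequencies kept inside the detectable range so clamping never engages
  gens <- c(0, 4, 8, 12)
  mk <- function(pop, off) {
    p <- 1 / (1 + exp(-(0.25 * gens - 2 + off)))
    data.frame(
      population_id = pop, generation = gens,
      n_wt_alleles = round(p * 96), n_total_alleles = 96
    )
  }
  ser <- rbind(mk("A", 0), mk("B", 0.5), mk("C", -0.5))
  pooled <- transition_fitness(ser)
  by_pop <- transition_fitness(ser, intercept = "by_population")
  expect_lt(abs(pooled$s - 0.25), 0.02)
  expect_lt(abs(by_pop$s - 0.25), 0.02)
  expect_equal(length(coef(by_pop$fit)), 4) # slope + 3 intercepts
})

test_that("transition fitness is nearly unbiased at assay-scale sampling", {
  # 4 time points x 96 alleles x 3 replicates with binomial noise; the time
  # points sit inside the transition window, where frequencies are interior
  # and the boundary clamp stays silent
  true_s <- 0.3
  gens <- c(0, 4, 8, 12)
  p <- 1 / (1 + exp(-(true_s * gens - 2)))
  set.seed(101)
  est <- replicate(300, {
    ser <- do.call(rbind, lapply(1:3, function(r) {
      data.frame(
        population_id = r, generation = gens,
        n_wt_alleles = rbinom(4, 96, p), n_total_alleles = 96
      )
    }))
    transition_fitness(ser)$s
  })
  expect_lt(abs(mean(est) - true_s), 0.01)
})

test_that("GFP correction is exact when male frequencies are zero", {
  # pure selfing: no heterozygotes, allele = phenotype frequencies
  out <- gfp_phenotype_to_allele_counts(500, 500, 0, 0)
  expect_equal(out$theta, 0)
  expect_equal(out$wt_alleles, 1000)
  expect_equal(out$gfp_alleles, 1000)
  # all progeny GFP-positive with no outcrossing: wt frequency 0
  out2 <- gfp_phenotype_to_allele_counts(800, 0, 0, 0)
  expect_equal(out2$wt_alleles, 0)
  expect_equal(out2$gfp_alleles, 1600)
})

test_that("GFP correction conserves allele mass and matches the enumeration oracle", {
  grid <- expand.grid(
    pos = c(100, 330, 600), neg = c(100, 400, 902),
    m_wt = c(0, 0.05, 0.2), m_gfp = c(0, 0.05, 0.3)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    out <- gfp_phenotype_to_allele_counts(g$pos, g$neg, g$m_wt, g$m_gfp)
    expect_true(out$converged)
    # exact conservation of total allele mass
    expect_equal(out$wt_alleles + out$gfp_alleles, 2 * (g$pos + g$neg))
    # the implied heterozygote share equals the mating-class enumeration at
    # the fixed-point adult frequency
    a_star <- out$gfp_alleles / (2 * (g$pos + g$neg))
    oracle <- oracle_gfp_mating_classes(a_star, g$m_wt, g$m_gfp)
    expect_equal(out$theta, unname(oracle["theta"]), tolerance = 1e-8)
  }
})

test_that("competition fitness reproduces log-ratio examples and symmetries", {
  rec <- function(pos, neg, mw = 0, mg = 0, sw = 250, sg = 250) {
    data.frame(
      block = "B1", population_id = "X", setup_wt = sw, setup_gfp = sg,
      final_gfp_pos = pos, final_gfp_neg = neg,
      male_freq_wt = mw, male_freq_gfp = mg
    )
  }
  expect_equal(competition_fitness(rec(500, 500))$w, 0)
  # 0.5 -> 0.75: w = ln 3
  expect_equal(competition_fitness(rec(250, 750))$w, log(3))
  # swapping the two roles negates w (m = 0 keeps the correction trivial)
  expect_equal(
    competition_fitness(rec(750, 250))$w,
    -competition_fitness(rec(250, 750))$w
  )
  # setup deviation flag
  est <- competition_fitness(rec(500, 500, sw = 400, sg = 100))
  expect_true(est$setup_flagged)
  expect_false(competition_fitness(rec(500, 500))$setup_flagged)
})

test_that("block centering and ancestor subtraction follow the definitions", {
  est <- data.frame(
    block = rep(c("B1", "B2"), each = 3),
    population_id = rep(c("ANC", "ANC", "EXP"), 2),
    w = c(0.1, 0.3, 0.5, -0.2, 0.0, 0.4),
    system = "trioecy"
  )
  out <- block_center_and_delta(est, "ANC",
                                ancestor_means = c(trioecy = 0.1))
  # reference w_t averages exactly zero within each block
  ref <- out[out$population_id == "ANC", ]
  expect_equal(as.numeric(tapply(ref$w_t, ref$block, mean)), c(0, 0))
  # experimental record: w - block reference mean, then ancestor-subtracted
  expect_equal(out$w_t[out$block == "B1" & out$population_id == "EXP"], 0.3)
  expect_equal(out$delta_w_t[out$block == "B1" & out$population_id == "EXP"], 0.2)
  # a block without a reference is dropped with a warning
  est2 <- rbind(est, data.frame(
    block = "B3", population_id = "EXP", w = 1, system = "trioecy"
  ))
  expect_warning(out2 <- block_center_and_delta(est2, "ANC"), "B3")
  expect_false("B3" %in% out2$block)
})

test_that("male fitness is the logit of the wild-type sired fraction", {
  rec <- function(pos, neg, fem = 15) {
    data.frame(
      plate = "p", females_transferred = fem,
      progeny_gfp_pos = pos, progeny_gfp_neg = neg
    )
  }
  expect_equal(male_fitness(rec(50, 50))$w_m, 0)
  expect_equal(male_fitness(rec(10, 30))$w_m, log(3))
  # clamped boundary: 0 wild-type sired of 40
  expect_warning(out <- male_fitness(rec(40, 0)), "clamped")
  expect_equal(out$w_m, log(1 / 40))
})

test_that("quality-control filters apply the stated thresholds and are idempotent", {
  plates <- data.frame(
    plate = paste0("p", 1:4),
    females_transferred = c(5, 10, 6, 20),
    progeny_gfp_pos = c(50, 9, 10, 30),
    progeny_gfp_neg = c(50, 10, 10, 40)
  )
  kept <- qc_filter_male_plates(plates)
  expect_equal(kept$plate, c("p3", "p4")) # p1: 5 females; p2: 19 progeny
  expect_equal(attr(kept, "rejections"), c(few_females = 1, few_progeny = 1))
  again <- qc_filter_male_plates(kept)
  expect_equal(again$plate, kept$plate)
  expect_equal(attr(again, "rejections"), c(few_females = 0, few_progeny = 0))

  ferts <- data.frame(
    progeny_total = c(4, 50, 50, 20),
    treatment = c("self", "outcross", "outcross", "self"),
    n_male_progeny = c(0, 4, 10, 0)
  )
  keptf <- qc_filter_fertility(ferts)
  # row 1: < 5 progeny; row 2: 8% male progeny in the outcross treatment
  expect_equal(nrow(keptf), 2)
  expect_equal(attr(keptf, "rejections"), c(few_progeny = 1, few_males = 1))
  expect_equal(nrow(qc_filter_fertility(keptf)), 2)
})
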