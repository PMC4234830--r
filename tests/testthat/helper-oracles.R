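# Independent oracles used to pin implementation semantics.  These are
# deliberately written from first principles (enumeration, projection
# matrices, closed forms) and share no code with the implementation paths
# they check.

# Mating-class enumeration for the GFP competition assay: two competitor
# origins, each homozygous at the marker (wt = 0 copies, gfp = 2 copies),
# adult origin frequencies a = c(wt, gfp), male frequencies m = c(wt, gfp).
# Dams reproduce in proportion to origin frequency; a fraction 2 * m[i] of
# origin i's progeny is outcrossed, with sire origin proportional to male
# supply a[j] * m[j]; the rest is selfed.  Returns the expected phenotype
# share of GFP-positive progeny and the heterozygote share among positives.
oracle_gfp_mating_classes <- function(a_gfp, m_wt, m_gfp) {
  a <- c(wt = 1 - a_gfp, gfp = a_gfp)
  m <- c(wt = m_wt, gfp = m_gfp)
  supply <- a * m
  s <- if (sum(supply) > 0) supply / sum(supply) else c(wt = 0, gfp = 0)
  # rows: dam origin x {self, sire wt, sire gfp}
  mass_pos <- 0
  mass_het <- 0
  for (dam in c("wt", "gfp")) {
    o <- 2 * m[[dam]]
    dose_dam <- if (dam == "gfp") 2 else 0
    # selfed progeny: dam genotype
    mass <- a[[dam]] * (1 - o)
    if (dose_dam > 0) mass_pos <- mass_pos + mass
    for (sire in c("wt", "gfp")) {
      dose_sire <- if (sire == "gfp") 2 else 0
      mass <- a[[dam]] * o * s[[sire]]
      dose <- (dose_dam + dose_sire) / 2
      if (dose > 0) mass_pos <- mass_pos + mass
      if (dose == 1) mass_het <- mass_het + mass
    }
  }
  c(pos = mass_pos, theta = if (mass_pos > 0) mass_het / mass_pos else 0)
}

# Sequential (Type I) ANCOVA by explicit projection matrices: covariate
# entered first, then the categorical factor; F statistics against the
# residual mean square.
oracle_ancova_projection <- function(y, x, g) {
  n <- length(y)
  g <- factor(g)
  X0 <- matrix(1, n, 1)
  X1 <- cbind(X0, x)
  X2 <- cbind(X1, stats::model.matrix(~g)[, -1, drop = FALSE])
  proj <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  fit0 <- proj(X0) %*% y
  fit1 <- proj(X1) %*% y
  fit2 <- proj(X2) %*% y
  ss_cov <- sum((fit1 - fit0)^2)
  ss_sys <- sum((fit2 - fit1)^2)
  ss_err <- sum((y - fit2)^2)
  df_cov <- 1
  df_sys <- nlevels(g) - 1
  df_err <- n - ncol(X2)
  ms_err <- ss_err / df_err
  data.frame(
    term = c("covariate", "system", "error"),
    df = c(df_cov, df_sys, df_err),
    ss = c(ss_cov, ss_sys, ss_err),
    f_value = c(ss_cov / df_cov / ms_err, ss_sys / df_sys / ms_err, NA)
  )
}

# Composite (Burrows) r^2 for one locus pair from the 3 x 3 joint genotype
# table, written out longhand from the textbook definition.
oracle_composite_r2_table <- function(xa, xb) {
  ok <- !is.na(xa) & !is.na(xb)
  xa <- xa[ok]
  xb <- xb[ok]
  n <- length(xa)
  tab <- table(factor(xa, 0:2), factor(xb, 0:2)) / n
  pa <- sum(tab * matrix(0:2, 3, 3) / 2)
  pb <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE) / 2)
  exy <- sum(tab * outer(0:2, 0:2))
  delta <- exy / 2 - 2 * pa * pb
  da <- sum(tab[3, ]) - pa^2
  db <- sum(tab[, 3]) - pb^2
  (delta / sqrt((pa * (1 - pa) + da) * (pb * (1 - pb) + db)))^2
}

# Stretch-refresh stochastic trajectory used by transition-dynamics tests:
# the quota male frequency is re-assayed every `refresh` generations, as in
# gen_trajectory_dataset().
run_refresh_trajectory <- function(alpha, p0, m0, N, n_gen, refresh, seed) {
  pars <- sim_params(alpha, N, n_gen, seed = seed)
  as.data.frame(run_trajectory(pars,
    wt_allele_freq = p0, male_freq = m0,
    quota_refresh_every = refresh
  ))
}
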