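## Individual-based Monte Carlo engine for the trioecious life cycle.
##
## The per-generation update is exact at the level of class counts: mating,
## selfing and offspring sampling are all exchangeable across individuals
## within a (sex, genotype) class, so the individual-level algorithm reduces
## to multivariate hypergeometric and multinomial draws over the six classes.
## This keeps a census of N = 1e4 as cheap as N = 100.

# Precomputed 9 x 3 matrix of offspring genotype distributions for cross
# pairs; row order = (XX genotype in c(1, 2, 0)) outer, (male genotype 0:2)
# inner, matching as.vector() of the 3 x 3 pair-count matrix produced in
# .step_counts (rows = male genotype, cols = XX class).
.cross_mendel <- local({
  gx <- c(1L, 2L, 0L)
  m <- matrix(0, 9, 3)
  k <- 0
  for (i in 1:3) {
    for (j in 0:2) {
      k <- k + 1
      m[k, ] <- .mendel_array[gx[i] + 1, j + 1, ]
    }
  }
  m
})

# One generation at the class-count level.  cnt is the numeric length-6 vector
# (male_0, male_1, male_2, herm_1, herm_2, female_0).  Returns the offspring
# counts, or NULL if no reproducing (pseudo-)pairs exist.  Uses the current
# RNG stream.
.step_counts <- function(cnt, alpha, beta = 1, delta = 0, m_quota = NULL) {
  N <- sum(cnt)
  nm <- cnt[1] + cnt[2] + cnt[3]
  nh1 <- cnt[4]
  nh2 <- cnt[5]
  nf <- cnt[6]
  nxx <- nh1 + nh2 + nf
  if (nxx == 0) return(NULL) # males cannot reproduce alone
  # mating quota alpha * m * N: m is the realized male frequency unless a
  # fixed (observed/assayed) quota frequency is imposed
  m <- if (is.null(m_quota)) nm / N else m_quota
  K <- if (nm > 0) min(round(alpha * m * N), nxx) else 0
  # mated XX: multivariate hypergeometric over (herm_1, herm_2, female_0)
  k1 <- if (K > 0) rhyper(1, nh1, nxx - nh1, K) else 0
  k2 <- if (K - k1 > 0) rhyper(1, nh2, nf, K - k1) else 0
  s1 <- nh1 - k1
  s2 <- nh2 - k2
  if (beta < 1) { # unmated hermaphrodites self with probability beta
    s1 <- rbinom(1, s1, beta)
    s2 <- rbinom(1, s2, beta)
  }
  wself <- 1 - delta
  Tw <- K + wself * (s1 + s2)
  if (Tw <= 0) return(NULL)
  pv <- numeric(6)
  if (K > 0) {
    pm <- cnt[1:3] / nm
    k3 <- K - k1 - k2
    # pair-type counts: each mated XX draws its male with replacement
    P <- cbind(rmultinom(1, k1, pm), rmultinom(1, k2, pm), rmultinom(1, k3, pm))
    cross_g <- as.vector(as.vector(P) %*% .cross_mendel)
    pv[1:3] <- 0.5 * cross_g # half of outcross offspring are male
    pv[4] <- 0.5 * cross_g[2]
    pv[5] <- 0.5 * cross_g[3]
    pv[6] <- 0.5 * cross_g[1]
  }
  if (s1 > 0) { # selfing wt/q71 hermaphrodites segregate 1:2:1
    q <- (wself * s1) * .mendel_array[2, 2, ]
    pv[4] <- pv[4] + q[2]
    pv[5] <- pv[5] + q[3]
    pv[6] <- pv[6] + q[1]
  }
  if (s2 > 0) pv[5] <- pv[5] + wself * s2
  drop(rmultinom(1, N, pv))
}

#' Initialize a population from allele and male frequencies
#'
#' Builds a [population_state()] with `round(male_freq * N)` males and the XX
#' remainder, assigning genotypes at Hardy-Weinberg proportions of
#' `wt_allele_freq` (deterministic largest-remainder rounding, applied
#' separately to the male and XX pools; male genotype frequencies are assumed
#' equal to those of hermaphrodites/females).  XX sex follows the genotype.
#'
#' @param N Census size (positive integer).
#' @param wt_allele_freq Wild-type (selfing) allele frequency.
#' @param male_freq Male frequency, `<= 0.5`.
#' @return A [population_state()] at generation 0.  If a class with positive
#'   expected frequency cannot be represented at census `N` (rounds to zero
#'   individuals) a warning reports it.
#' @examples
#' initialize_population(1000, wt_allele_freq = 0.5, male_freq = 0.2)
#' @export
initialize_population <- function(N, wt_allele_freq, male_freq) {
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer")
  check_frequency(wt_allele_freq)
  check_frequency(male_freq)
  if (male_freq > 0.5) stop("`male_freq` must be <= 0.5")
  p <- wt_allele_freq
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  n_male <- round(male_freq * N)
  male_g <- .largest_remainder(n_male, hw)
  xx_g <- .largest_remainder(N - n_male, hw)
  cnt <- c(male_g, xx_g[2], xx_g[3], xx_g[1])
  names(cnt) <- .class_names
  # report infeasible rounding: a whole category expected at positive
  # frequency that the census cannot represent
  realized_p <- sum(cnt * .class_genotype) / (2 * N)
  if (p > 0 && realized_p == 0) {
    warning("census too small to represent the wild-type allele at p = ", p)
  }
  if (p < 1 && realized_p == 1) {
    warning("census too small to represent the q71 allele at p = ", p)
  }
  if (male_freq > 0 && n_male == 0) {
    warning("census too small to represent males at frequency ", male_freq)
  }
  population_state(cnt)
}

# Apportion N into integer counts proportional to probs by the
# largest-remainder method (ties broken by class order).
.largest_remainder <- function(N, probs) {
  x <- N * probs / sum(probs)
  base <- floor(x)
  rem <- round(N - sum(base))
  if (rem > 0) {
    ord <- order(x - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Advance a population by one generation
#'
#' One cycle of the mating-pair algorithm: `K = min(round(alpha * m * N),
#' #XX)` XX individuals are drawn uniformly without replacement and each is
#' paired with a male drawn uniformly with replacement; unmated hermaphrodites
#' become selfing pseudo-pairs with probability `beta` (weighted by
#' `1 - delta` at the reproduction stage) and unmated females are discarded;
#' the N offspring are then drawn by sampling (pseudo-)pairs with
#' replacement, with genotypes from Mendelian segregation.  Offspring of true
#' pairs are male with probability 1/2, offspring of pseudo-pairs are always
#' XX, and XX sex follows the genotype.
#'
#' Randomness is taken from R's current RNG stream; use [run_trajectory()]
#' (or `set.seed()`) for reproducible runs.
#'
#' The male frequency in the mating quota `alpha * m * N` is, by default,
#' the realized frequency of the current state; passing `quota_male_freq`
#' fixes it instead at an assayed (observed) value, the convention of the
#' period-wise inference engine where `m` is known only at sampled
#' generations.
#'
#' @param state A [population_state()].
#' @param params A [sim_params()] object (`sigma` must be 0; survivorship
#'   differences are not part of the life-cycle algorithm).
#' @param quota_male_freq `NULL` (use the realized male frequency) or a
#'   fixed male frequency for the mating quota.
#' @return The next [population_state()], or `NULL` if the population has no
#'   reproducing (pseudo-)pairs (extinction).
#' @export
advance_generation <- function(state, params, quota_male_freq = NULL) {
  stopifnot(inherits(state, "population_state"), inherits(params, "sim_params"))
  if (params$sigma != 0) {
    stop("the individual-based algorithm models sigma = 0 only")
  }
  cnt <- .step_counts(
    state$counts, params$alpha, params$beta, params$delta, quota_male_freq
  )
  if (is.null(cnt)) return(NULL)
  population_state(setNames(cnt, .class_names), state$generation + 1L)
}

#' Run a stochastic trajectory
#'
#' Iterates [advance_generation()] for `params$n_generations` generations
#' under the run's seed.  The census size is exactly `N` every generation.
#'
#' @param params A [sim_params()] object.
#' @param initial Optional starting [population_state()] with total count
#'   `params$census_size`.  If omitted, supply `wt_allele_freq` and
#'   `male_freq` to build one via [initialize_population()].
#' @param wt_allele_freq,male_freq Starting frequencies used when `initial`
#'   is missing.
#' @param quota_male_freq `NULL` (mating quota follows the realized male
#'   frequency each generation) or a fixed quota frequency; see
#'   [advance_generation()].
#' @param quota_refresh_every Optional integer: refresh the quota male
#'   frequency from the realized state every this many generations and hold
#'   it fixed in between (the cadence at which male frequencies are assayed);
#'   overrides `quota_male_freq`.
#' @return An object of class `sim_result`: list with `counts` (matrix,
#'   generations x 6 classes), `params`, and `extinct_at` (`NA` or the first
#'   generation that could not be produced).  Use [as.data.frame()] for a
#'   per-generation table with derived frequencies.
#' @examples
#' p <- sim_params(alpha = 1.41, census_size = 1000, n_generations = 5, seed = 7)
#' r <- run_trajectory(p, wt_allele_freq = 0.026, male_freq = 0.45)
#' as.data.frame(r)
#' @export
run_trajectory <- function(params, initial = NULL, wt_allele_freq = NULL,
                           male_freq = NULL, quota_male_freq = NULL,
                           quota_refresh_every = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(initial)) {
    if (is.null(wt_allele_freq) || is.null(male_freq)) {
      stop("supply `initial` or both `wt_allele_freq` and `male_freq`")
    }
    initial <- initialize_population(params$census_size, wt_allele_freq, male_freq)
  }
  stopifnot(inherits(initial, "population_state"))
  if (sum(initial$counts) != params$census_size) {
    stop("`initial` census does not match params$census_size")
  }
  n_gen <- params$n_generations
  out <- matrix(NA_real_, n_gen + 1, 6, dimnames = list(NULL, .class_names))
  out[1, ] <- initial$counts
  extinct_at <- NA_integer_
  with_seed(params$seed, {
    cnt <- initial$counts
    mq <- quota_male_freq
    for (g in seq_len(n_gen)) {
      if (!is.null(quota_refresh_every) &&
          (g - 1) %% quota_refresh_every == 0) {
        mq <- min(sum(cnt[1:3]) / sum(cnt), 0.5)
      }
      cnt <- .step_counts(cnt, params$alpha, params$beta, params$delta, mq)
      if (is.null(cnt)) {
        extinct_at <- g
        out <- out[seq_len(g), , drop = FALSE]
        break
      }
      out[g + 1, ] <- cnt
    }
  })
  structure(
    list(
      counts = out,
      start_generation = initial$generation,
      params = params,
      extinct_at = extinct_at
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(
    "<sim_result>", nrow(x$counts), "generations recorded, N =",
    x$params$census_size, "\n"
  )
  if (!is.na(x$extinct_at)) {
    cat("  population lost all reproducers at generation", x$extinct_at, "\n")
  }
  fin <- x$counts[nrow(x$counts), ]
  cat("  final state:", paste(names(fin), fin, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sim_result <- function(x, ...) {
  df <- as.data.frame(x$counts)
  N <- rowSums(x$counts)
  df <- cbind(
    generation = x$start_generation + seq_len(nrow(df)) - 1L,
    df
  )
  df$n_male <- df$male_0 + df$male_1 + df$male_2
  df$n_hermaphrodite <- df$herm_1 + df$herm_2
  df$n_female <- df$female_0
  df$n_wt_alleles <- df$male_1 + df$herm_1 + 2 * (df$male_2 + df$herm_2)
  df$n_total_alleles <- 2 * N
  df$p_wt <- df$n_wt_alleles / df$n_total_alleles
  df$m <- df$n_male / N
  df
}
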