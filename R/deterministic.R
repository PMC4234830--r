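## Closed-form, infinite-population machinery: the male maintenance function,
## alpha estimation from two male frequencies, the androdioecy maintenance
## condition, and the deterministic limit of the stochastic mating algorithm.

#' One step of the male maintenance recursion
#'
#' Classical recursion for the male frequency in an androdioecious population
#' where `alpha * m` of the hermaphrodite pool is outcrossed and each selfing
#' hermaphrodite contributes a selfed brood of relative weight `brood_weight`
#' (`B = 2 * beta * (1 - delta)`; with no mixed broods and no inbreeding
#' depression `B = 2`):
#' `m' = alpha * m / (2 * alpha * m + B * (1 - alpha * m))`.
#' With `B = 2` this simplifies to `m' = alpha * m / 2`, so a rare male
#' lineage grows iff `alpha > 2`.
#'
#' @param m Male frequency in `[0, 0.5]` (vectorised).
#' @param alpha Outcross fitness (>= 0).
#' @param brood_weight Selfed brood weight `B` (> 0). Default 2.
#' @return Next-generation male frequency.
#' @examples
#' male_maintenance_step(0.1, alpha = 2)    # fixed point at the threshold
#' male_maintenance_step(0.25, alpha = 1)   # alpha * m / 2 = 0.125
#' @export
male_maintenance_step <- function(m, alpha, brood_weight = 2) {
  check_frequency(m)
  if (any(m > 0.5)) stop("`m` must be <= 0.5")
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (brood_weight <= 0) stop("`brood_weight` must be > 0")
  am <- alpha * m
  if (any(am > 1)) {
    stop("alpha * m > 1: parameters outside the model's domain")
  }
  am / (2 * am + brood_weight * (1 - am))
}

#' Outcross fitness from a two-generation male-frequency change
#'
#' Exact algebraic inverse of [male_maintenance_step()]:
#' `alpha = B * m1 / (m0 * (1 - 2 * m1 + B * m1))`.  With `B = 2` this is
#' `alpha = 2 * m1 / m0`.
#'
#' @param m0 Parental male frequency, in `(0, 0.5]`.
#' @param m1 Male frequency one generation later, in `[0, 0.5]`.
#' @param brood_weight Selfed brood weight `B` (> 0). Default 2.
#' @return The outcross-fitness estimate `alpha`.
#' @examples
#' estimate_alpha_from_male_frequencies(0.1, 0.075)   # 1.5
#' @export
estimate_alpha_from_male_frequencies <- function(m0, m1, brood_weight = 2) {
  check_frequency(m0)
  check_frequency(m1)
  if (any(m0 == 0)) stop("`m0` = 0: no parental males, alpha is unidentifiable")
  if (any(m0 > 0.5) || any(m1 > 0.5)) stop("male frequencies must be <= 0.5")
  denom <- m0 * (1 - 2 * m1 + brood_weight * m1)
  if (any(denom <= 0)) stop("inconsistent inputs: non-positive denominator")
  brood_weight * m1 / denom
}

#' Maintenance condition for androdioecy
#'
#' Males (and hence outcrossing) are maintained alongside selfing
#' hermaphrodites when the outcross fitness, discounted by the male
#' survivorship difference, exceeds the selfed brood weight:
#' `alpha * (1 - sigma) > 2 * beta * (1 - delta)` (strict inequality).  At
#' `sigma = delta = 0`, `beta = 1` this is the classical two-fold cost of
#' males, `alpha > 2`.
#'
#' @param alpha Outcross fitness (>= 0).
#' @param sigma Male-vs-hermaphrodite survivorship difference, `[0, 1)`.
#' @param beta Selfing probability of non-outcrossed hermaphrodites, `[0, 1]`.
#' @param delta Inbreeding depression, `[0, 1)`.
#' @return Logical: `TRUE` iff androdioecy is maintained.
#' @examples
#' androdioecy_maintenance_condition(2.4)  # TRUE
#' androdioecy_maintenance_condition(2)    # FALSE: the boundary is strict
#' @export
androdioecy_maintenance_condition <- function(alpha, sigma = 0, beta = 1,
                                              delta = 0) {
  if (any(alpha < 0)) stop("`alpha` must be >= 0")
  alpha * (1 - sigma) > 2 * beta * (1 - delta)
}

#' Per-generation growth factor of a rare male lineage
#'
#' Numerical derivative of [male_maintenance_step()] at `m -> 0`, i.e. the
#' factor by which a vanishingly rare male lineage is multiplied each
#' generation.  Equals `alpha / brood_weight`; males invade iff it exceeds 1.
#'
#' @inheritParams male_maintenance_step
#' @param m Small male frequency at which the ratio `m'/m` is evaluated.
#' @return The growth factor `m'/m`.
#' @export
rare_male_growth_factor <- function(alpha, brood_weight = 2, m = 1e-9) {
  male_maintenance_step(m, alpha, brood_weight) / m
}

#' Class frequencies for the deterministic model
#'
#' Validated vector of relative frequencies over the six admissible
#' sex-by-genotype classes (the infinite-population analogue of
#' [population_state()]).
#'
#' @param freq Named numeric vector (subset of `male_0`, `male_1`, `male_2`,
#'   `herm_1`, `herm_2`, `female_0`); missing classes default to 0.  Must sum
#'   to 1 within `1e-12` after the fill-in.
#' @return Named numeric vector of length 6 with class
#'   `"class_frequencies"`.
#' @examples
#' class_frequencies(c(male_0 = 0.45, female_0 = 0.5, herm_1 = 0.05))
#' @export
class_frequencies <- function(freq) {
  if (is.null(names(freq)) || !all(names(freq) %in% .class_names)) {
    stop(
      "`freq` must be named with classes among: ",
      paste(.class_names, collapse = ", ")
    )
  }
  full <- setNames(numeric(6), .class_names)
  full[names(freq)] <- freq
  if (any(full < 0)) stop("frequencies must be non-negative")
  if (abs(sum(full) - 1) > 1e-12) stop("class frequencies must sum to 1")
  structure(full, class = "class_frequencies")
}

#' Class frequencies from allele and male frequencies
#'
#' Builds the starting class frequencies used throughout the package: males
#' at frequency `male_freq`, XX genotypes at Hardy-Weinberg proportions of
#' the wild-type allele frequency `wt_allele_freq`, male genotypes at the
#' same proportions, and XX sex assigned by genotype.
#'
#' @param wt_allele_freq Wild-type (selfing) allele frequency.
#' @param male_freq Male frequency, `<= 0.5`.
#' @return A [class_frequencies()] vector.
#' @export
class_frequencies_from_freqs <- function(wt_allele_freq, male_freq) {
  check_frequency(wt_allele_freq)
  check_frequency(male_freq)
  if (male_freq > 0.5) stop("`male_freq` must be <= 0.5")
  p <- wt_allele_freq
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  f <- c(male_freq * hw, (1 - male_freq) * hw[2:3], (1 - male_freq) * hw[1])
  class_frequencies(setNames(f, .class_names))
}

# Deterministic one-generation update of class frequencies.  Returns the new
# frequency vector, or NULL on extinction (no reproducing pairs).
.deterministic_step <- function(f, alpha, beta, delta, m_quota = NULL) {
  m <- f[1] + f[2] + f[3]
  xx <- f[4] + f[5] + f[6] # actual XX mass, not 1 - m: keeps mass exact
  if (xx <= 0) return(NULL)
  mq <- if (is.null(m_quota)) m else m_quota
  M <- if (m > 0) min(alpha * mq, xx) else 0
  mated_frac <- M / xx
  herm <- f[4:5]
  self_mass <- herm * (1 - mated_frac) * beta # per herm genotype (g = 1, 2)
  self_w <- self_mass * (1 - delta)
  Tmass <- M + sum(self_w)
  if (Tmass <= 0) return(NULL)
  pv <- numeric(6)
  if (M > 0) {
    pm <- f[1:3] / m
    # mated XX mass per class, order (g=1 herm, g=2 herm, g=0 female)
    mx <- c(f[4], f[5], f[6]) * mated_frac
    cross_g <- numeric(3)
    for (i in seq_len(3)) {
      gx <- c(1L, 2L, 0L)[i]
      for (j in seq_len(3)) {
        cross_g <- cross_g + mx[i] * pm[j] * .mendel_array[gx + 1, j, ]
      }
    }
    pv[1:3] <- pv[1:3] + 0.5 * cross_g
    pv[4] <- pv[4] + 0.5 * cross_g[2]
    pv[5] <- pv[5] + 0.5 * cross_g[3]
    pv[6] <- pv[6] + 0.5 * cross_g[1]
  }
  if (self_w[1] > 0) {
    q <- self_w[1] * .mendel_array[2, 2, ]
    pv[4] <- pv[4] + q[2]
    pv[5] <- pv[5] + q[3]
    pv[6] <- pv[6] + q[1]
  }
  if (self_w[2] > 0) pv[5] <- pv[5] + self_w[2]
  setNames(pv / sum(pv), .class_names)
}

#' Deterministic trajectory of the trioecy model
#'
#' Iterates the infinite-population limit of the individual-based mating
#' algorithm: a fraction `min(alpha * m, 1 - m)` of the XX pool is mated
#' (uniformly across hermaphrodites and females), unmated hermaphrodites
#' self with probability `beta` at relative weight `1 - delta`, unmated
#' females do not reproduce, outcross offspring are male with probability
#' 1/2, and XX offspring sex follows the fog-2 genotype.
#'
#' @param initial A [class_frequencies()] vector (or anything accepted by
#'   that constructor).
#' @param params A [sim_params()] object; `alpha`, `beta`, `delta` and
#'   `n_generations` are used (`sigma` must be 0).
#' @param n_generations Number of generations; defaults to
#'   `params$n_generations`.
#' @param quota_male_freq `NULL` (mating quota follows the current male
#'   frequency) or a fixed quota frequency, mirroring the observed-male-
#'   frequency convention of the period-wise inference engine.
#' @param quota_refresh_every Optional integer: refresh the quota male
#'   frequency from the current state every this many generations and hold
#'   it fixed in between; overrides `quota_male_freq`.
#' @return A data frame with one row per generation (starting at 0): the six
#'   class frequencies plus `m` (male), `herm`, `female` and `p_wt`
#'   frequencies.  If the population loses all reproducers the trajectory is
#'   truncated and carries the attribute `extinct_at` (the first generation
#'   that could not be produced).
#' @examples
#' p <- sim_params(alpha = 1.41, census_size = 1e4, n_generations = 10)
#' f0 <- class_frequencies_from_freqs(0.026, 0.45)
#' traj <- deterministic_trioecy_trajectory(f0, p)
#' traj$p_wt
#' @export
deterministic_trioecy_trajectory <- function(initial, params,
                                             n_generations = params$n_generations,
                                             quota_male_freq = NULL,
                                             quota_refresh_every = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$sigma != 0) {
    stop("the trajectory recursion models sigma = 0 only; ",
         "sigma enters androdioecy_maintenance_condition()")
  }
  f <- unclass(class_frequencies(initial))
  out <- matrix(NA_real_, n_generations + 1, 6,
    dimnames = list(NULL, .class_names)
  )
  out[1, ] <- f
  extinct_at <- NA_integer_
  mq <- quota_male_freq
  for (g in seq_len(n_generations)) {
    if (!is.null(quota_refresh_every) && (g - 1) %% quota_refresh_every == 0) {
      mq <- min(f[1] + f[2] + f[3], 0.5)
    }
    f <- .deterministic_step(f, params$alpha, params$beta, params$delta, mq)
    if (is.null(f)) {
      extinct_at <- g
      out <- out[seq_len(g), , drop = FALSE]
      break
    }
    out[g + 1, ] <- f
  }
  df <- as.data.frame(out)
  df <- cbind(generation = seq_len(nrow(df)) - 1L, df)
  df$m <- df$male_0 + df$male_1 + df$male_2
  df$herm <- df$herm_1 + df$herm_2
  df$female <- df$female_0
  ## p_wt = mean wt allele dosage / 2 (class frequencies sum to 1)
  df$p_wt <- (df$male_1 + df$herm_1 + 2 * (df$male_2 + df$herm_2)) / 2
  attr(df, "extinct_at") <- extinct_at
  df
}
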