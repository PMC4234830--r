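## Grid-based maximum-likelihood estimation of the outcross-fitness parameter
## alpha from fog-2(wt) allele-count time series.
##
## The likelihood is simulation-based and period-wise conditional: each
## period between consecutive sampled generations is simulated independently
## from the period's own observed starting frequencies, and the observed
## end-of-period allele count is scored against the mean simulated frequency
## with a binomial log-likelihood.  Log-likelihoods are summed across periods
## and across replicate populations of the same regime.

#' Validate a trajectory observation table
#'
#' @param observations Data frame with columns `population_id`, `generation`,
#'   `n_individuals`, `n_wt_alleles` and optionally `male_count`, `n_sexed`.
#' @return The validated data frame, ordered by population and generation.
#' @export
check_trajectory_observations <- function(observations) {
  req <- c("population_id", "generation", "n_individuals", "n_wt_alleles")
  miss <- setdiff(req, names(observations))
  if (length(miss)) {
    stop("observations lack columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(observations$n_wt_alleles < 0 |
    observations$n_wt_alleles > 2 * observations$n_individuals)
  if (length(bad)) {
    stop(
      "rows with n_wt_alleles outside [0, 2 * n_individuals]: ",
      paste(bad, collapse = ", ")
    )
  }
  observations[order(observations$population_id, observations$generation), ,
    drop = FALSE
  ]
}

#' Mean simulated end-of-period allele frequency
#'
#' Initializes a population at the period's observed starting frequencies
#' (via [initialize_population()]), runs it for `n_generations` under the
#' given `alpha` in `n_reps` independent replicates, and returns the mean
#' final wild-type allele frequency, boundary-clamped away from exactly 0 or
#' 1 (see [clamp_frequency()]) so it can parameterise a binomial likelihood.
#'
#' @param start_p Starting wild-type allele frequency.
#' @param start_m Starting male frequency (`<= 0.5`).
#' @param n_generations Period length in generations (>= 0; 0 returns
#'   `start_p`).
#' @param alpha Outcross fitness.
#' @param census_size Simulated census size `N`.
#' @param n_reps Number of replicate simulations (default 20).
#' @param seed Base seed; replicate r runs under [derive_seed()]`(seed, r)`.
#' @param beta,delta Reproduction parameters, see [sim_params()].
#' @param quota `"observed"` (default): the mating quota uses the period's
#'   observed starting male frequency throughout, since `m` is assayed only
#'   at sampled generations; `"realized"`: the quota follows the simulated
#'   male frequency each generation.
#' @return Mean final allele frequency, strictly inside (0, 1).  Replicates
#'   that lose all reproducers are dropped with a warning; if all replicates
#'   do, an error is raised.
#' @export
simulate_period_mean_frequency <- function(start_p, start_m, n_generations,
                                           alpha, census_size, n_reps = 20,
                                           seed = 1, beta = 1, delta = 0,
                                           quota = c("observed", "realized")) {
  quota <- match.arg(quota)
  check_frequency(start_p)
  if (n_generations == 0) return(start_p)
  start_m <- min(start_m, 0.5)
  m_quota <- if (quota == "observed") start_m else NULL
  init <- initialize_population(census_size, start_p, start_m)
  cnt0 <- init$counts
  finals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    finals[r] <- with_seed(derive_seed(seed, r), {
      cnt <- cnt0
      for (g in seq_len(n_generations)) {
        cnt <- .step_counts(cnt, alpha, beta, delta, m_quota)
        if (is.null(cnt)) break
      }
      if (is.null(cnt)) NA_real_ else sum(cnt * .class_genotype) / (2 * sum(cnt))
    })
  }
  if (all(is.na(finals))) {
    stop("all replicate simulations went extinct during the period")
  }
  if (anyNA(finals)) {
    warning(sum(is.na(finals)), " replicate(s) went extinct; dropped")
  }
  pbar <- mean(finals, na.rm = TRUE)
  n_alleles <- 2 * census_size
  clamp_frequency(round(pbar * n_alleles), n_alleles)
}

# Decompose an observation table into per-population periods, resolving each
# period's starting male frequency: observed (male_count / n_sexed, capped at
# 0.5) when available, otherwise propagated through the deterministic
# recursion at the current alpha from the last known male frequency.
.build_periods <- function(observations, alpha, beta = 1, delta = 0,
                           initial_male_freq = NULL,
                           quota = "observed") {
  obs <- check_trajectory_observations(observations)
  out <- list()
  for (pop in unique(obs$population_id)) {
    sub <- obs[obs$population_id == pop, , drop = FALSE]
    if (nrow(sub) < 2) next
    has_m <- all(c("male_count", "n_sexed") %in% names(sub))
    m_run <- NA_real_
    for (i in seq_len(nrow(sub) - 1)) {
      a <- sub[i, ]
      b <- sub[i + 1, ]
      p_start <- clamp_frequency(a$n_wt_alleles, 2 * a$n_individuals)
      m_obs <- if (has_m && !is.na(a$male_count) && !is.na(a$n_sexed)) {
        min(a$male_count / a$n_sexed, 0.5)
      } else {
        NA_real_
      }
      if (!is.na(m_obs)) {
        m_start <- m_obs
        m_source <- "observed"
      } else if (!is.na(m_run)) {
        m_start <- m_run
        m_source <- "deterministic"
      } else if (!is.null(initial_male_freq)) {
        m_start <- initial_male_freq
        m_source <- "initial_male_freq"
      } else {
        stop(
          "population ", pop, ": no male-frequency information at the first ",
          "time point; supply male_count/n_sexed or `initial_male_freq`"
        )
      }
      len <- b$generation - a$generation
      # propagate the male frequency deterministically to the period end so
      # the next period has a fallback when its own male count is unobserved
      next_m_missing <- !(has_m && !is.na(b$male_count) && !is.na(b$n_sexed))
      if (len > 0 && next_m_missing) {
        f0 <- class_frequencies_from_freqs(p_start, min(m_start, 0.5))
        pars <- sim_params(
          alpha = alpha, census_size = 2L, n_generations = len,
          beta = beta, delta = delta
        )
        mq <- if (quota == "observed") min(m_start, 0.5) else NULL
        tr <- deterministic_trioecy_trajectory(f0, pars, quota_male_freq = mq)
        m_run <- if (is.na(attr(tr, "extinct_at"))) tr$m[nrow(tr)] else NA_real_
      } else {
        m_run <- m_start
      }
      out[[length(out) + 1]] <- list(
        population_id = pop,
        gen_start = a$generation, gen_end = b$generation,
        n_generations = len,
        p_start = p_start, m_start = min(m_start, 0.5), m_source = m_source,
        k_end = b$n_wt_alleles, n_alleles_end = 2 * b$n_individuals
      )
    }
  }
  out
}

#' Compound log-likelihood of an alpha value
#'
#' For each period of each population, simulates the period from its observed
#' starting frequencies ([simulate_period_mean_frequency()]) and scores the
#' observed end-of-period wild-type allele count with a binomial
#' log-likelihood at the mean simulated frequency.  Terms are summed across
#' periods and across populations.
#'
#' @inheritParams simulate_period_mean_frequency
#' @param observations Observation table, see
#'   [check_trajectory_observations()].
#' @param alpha Outcross fitness value to score.
#' @param census_size Simulated census size.
#' @param initial_male_freq Fallback starting male frequency for populations
#'   whose first time point carries no male counts.
#' @return The compound log-likelihood (a single number), with attribute
#'   `periods` (number of period terms).
#' @export
compound_log_likelihood <- function(observations, alpha, census_size,
                                    n_reps = 20, seed = 1, beta = 1,
                                    delta = 0, initial_male_freq = NULL,
                                    quota = c("observed", "realized")) {
  quota <- match.arg(quota)
  periods <- .build_periods(observations, alpha, beta, delta,
                            initial_male_freq, quota)
  if (!length(periods)) stop("no periods: need >= 2 generations per population")
  ll <- 0
  for (i in seq_along(periods)) {
    pd <- periods[[i]]
    # sub-seed derived from the period's content (not its position or alpha):
    # identical periods share simulations, so the compound likelihood is a
    # pure sum, and the same replicate streams are reused across grid points
    # (common random numbers, which steadies the argmax)
    p_sim <- simulate_period_mean_frequency(
      pd$p_start, pd$m_start, pd$n_generations, alpha, census_size,
      n_reps = n_reps,
      seed = derive_seed(
        seed, round(pd$p_start * 1e7), round(pd$m_start * 1e7),
        pd$n_generations
      ),
      beta = beta, delta = delta, quota = quota
    )
    ll <- ll + dbinom(pd$k_end, pd$n_alleles_end, p_sim, log = TRUE)
  }
  structure(ll, periods = length(periods))
}

#' Grid likelihood search for the outcross-fitness parameter
#'
#' Evaluates [compound_log_likelihood()] on a grid of alpha values (default:
#' 51 points on `[0, 2]`, spacing 0.04) and returns the maximum-likelihood
#' estimate with a likelihood-drop credible interval: the contiguous grid
#' range around the ML where `2 * (lnL_ML - lnL) <= ci_drop` (default 3.84,
#' the 95% chi-square quantile with 1 d.f.).
#'
#' @inheritParams compound_log_likelihood
#' @param quota Mating-quota convention passed down to the period
#'   simulations; see [simulate_period_mean_frequency()].
#' @param grid Ordered numeric vector of alpha values (>= 2 points).
#' @param ci_drop Likelihood-drop threshold defining the credible interval.
#' @return An object of class `likelihood_grid`: list with `grid` (data frame
#'   `alpha`, `loglik`), `ml_alpha`, `ci_lower`, `ci_upper`,
#'   `boundary_ml` (ML attained at a grid endpoint), `tie` (maximum attained
#'   at several grid points; the lowest alpha is reported),
#'   `n_reps`, and `m_sources` (how each period's starting male frequency was
#'   resolved).
#' @examples
#' \donttest{
#' synth <- gen_trajectory_dataset(
#'   true_alpha = 1.2, n_populations = 1,
#'   sample_generations = c(0, 10, 20), census_size = 1000, seed = 4
#' )
#' grid_likelihood_search(synth$observations,
#'   census_size = 1000,
#'   grid = seq(0.5, 2, by = 0.25), n_reps = 5, seed = 4
#' )
#' }
#' @export
grid_likelihood_search <- function(observations, census_size,
                                   grid = seq(0, 2, length.out = 51),
                                   n_reps = 20, ci_drop = 3.84, seed = 1,
                                   beta = 1, delta = 0,
                                   initial_male_freq = NULL,
                                   quota = c("observed", "realized")) {
  quota <- match.arg(quota)
  if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be an increasing vector with >= 2 points")
  }
  ll <- vapply(grid, function(a) {
    as.numeric(compound_log_likelihood(
      observations, a, census_size,
      n_reps = n_reps, seed = seed,
      beta = beta, delta = delta, initial_male_freq = initial_male_freq,
      quota = quota
    ))
  }, numeric(1))
  i_ml <- which(ll == max(ll))
  tie <- length(i_ml) > 1
  i_ml <- i_ml[1] # ties broken to the lowest alpha
  boundary <- i_ml %in% c(1L, length(grid)) || tie && all(ll == ll[1])
  inside <- 2 * (ll[i_ml] - ll) <= ci_drop
  lo <- i_ml
  while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i_ml
  while (hi < length(grid) && inside[hi + 1]) hi <- hi + 1
  periods <- .build_periods(
    observations, grid[i_ml], beta, delta, initial_male_freq, quota
  )
  structure(
    list(
      grid = data.frame(alpha = grid, loglik = ll),
      ml_alpha = grid[i_ml],
      ci_lower = grid[lo],
      ci_upper = grid[hi],
      ci_drop = ci_drop,
      boundary_ml = boundary,
      tie = tie,
      n_reps = n_reps,
      m_sources = vapply(periods, `[[`, character(1), "m_source")
    ),
    class = "likelihood_grid"
  )
}

#' @export
print.likelihood_grid <- function(x, ...) {
  cat(sprintf(
    "<likelihood_grid> ML alpha = %.3f (CI %.3f-%.3f at -2lnLk drop %.2f)\n",
    x$ml_alpha, x$ci_lower, x$ci_upper, x$ci_drop
  ))
  cat(
    "  grid:", nrow(x$grid), "points on [",
    min(x$grid$alpha), ",", max(x$grid$alpha), "],",
    x$n_reps, "replicate simulations per point\n"
  )
  if (x$boundary_ml) cat("  flag: ML attained at a grid boundary\n")
  if (x$tie) cat("  flag: likelihood tie; lowest alpha reported\n")
  invisible(x)
}
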