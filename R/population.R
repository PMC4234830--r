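## Population state and simulation parameters.
##
## A population state is a census of counts over the six admissible
## (sex, genotype) classes.  XX sex is fully determined by genotype, so the
## only classes with non-zero counts are:
##   male_0, male_1, male_2   (XO, any genotype)
##   herm_1, herm_2           (XX carrying >= 1 wild-type allele)
##   female_0                 (XX q71/q71)

.class_names <- c("male_0", "male_1", "male_2", "herm_1", "herm_2", "female_0")
.class_sex <- c("male", "male", "male", "hermaphrodite", "hermaphrodite", "female")
.class_genotype <- c(0L, 1L, 2L, 1L, 2L, 0L)

#' Population census state
#'
#' Constructs and validates the census of a simulated population at one
#' generation: non-negative integer counts over the six admissible
#' sex-by-genotype classes.  Classes that are impossible under genotypic sex
#' determination (e.g. an XX q71/q71 hermaphrodite) are not representable.
#'
#' @param counts Named numeric vector with (a subset of) the names
#'   `male_0`, `male_1`, `male_2`, `herm_1`, `herm_2`, `female_0`, where the
#'   numeric suffix is the wild-type allele count of the class.  Missing
#'   classes default to 0.
#' @param generation Non-negative integer generation index.
#' @return An object of class `population_state`: a list with elements
#'   `generation` and `counts` (full named vector of 6 counts).
#' @examples
#' population_state(c(male_0 = 50, female_0 = 45, herm_1 = 5))
#' @export
population_state <- function(counts, generation = 0L) {
  if (is.null(names(counts)) || !all(names(counts) %in% .class_names)) {
    stop(
      "`counts` must be named with classes among: ",
      paste(.class_names, collapse = ", ")
    )
  }
  full <- setNames(numeric(6), .class_names)
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full))) {
    stop("class counts must be non-negative integers")
  }
  if (generation < 0 || generation != round(generation)) {
    stop("`generation` must be a non-negative integer")
  }
  structure(
    list(generation = as.integer(generation), counts = full),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(
    "<population_state> generation", x$generation,
    "| N =", sum(x$counts), "\n"
  )
  print(x$counts)
  invisible(x)
}

#' Summary frequencies of a population state
#'
#' @param state A [population_state()].
#' @return Named numeric vector with the male, female and hermaphrodite
#'   frequencies and the wild-type allele frequency (`p_wt`).
#' @export
state_frequencies <- function(state) {
  stopifnot(inherits(state, "population_state"))
  cnt <- state$counts
  N <- sum(cnt)
  if (N == 0) stop("empty population state")
  c(
    male = sum(cnt[1:3]) / N,
    hermaphrodite = sum(cnt[4:5]) / N,
    female = cnt[6] / N,
    p_wt = sum(cnt * .class_genotype) / (2 * N)
  )
}

#' Simulation parameters
#'
#' Bundles the parameters of the trioecy model.  `alpha` is the
#' outcross-fitness parameter: the compound of all fitness components
#' expressed under outcrossing relative to selfing.  `beta` is the
#' probability that a non-outcrossed hermaphrodite self-fertilises (brood
#' level; no mixed broods), `sigma` the male-vs-hermaphrodite survivorship
#' difference and `delta` inbreeding depression, entering reproduction as a
#' `(1 - delta)` sampling weight on selfing pseudo-pairs.  The derived selfed
#' brood weight is `B = 2 * beta * (1 - delta)`; with the defaults
#' (`beta = 1`, `delta = 0`) it equals the classical two-fold cost of males,
#' `B = 2`.
#'
#' @param alpha Outcross fitness, `>= 0`.
#' @param census_size Census size `N` (positive integer).
#' @param n_generations Number of generations to simulate (>= 0).
#' @param beta Proportion of non-cross-fertilised oocytes that are
#'   self-fertilised, in `[0, 1]`.  Default 1.
#' @param sigma Survivorship difference between males and hermaphrodites, in
#'   `[0, 1)`.  Default 0; the individual-based simulator only supports
#'   `sigma = 0` (it enters the closed-form maintenance condition).
#' @param delta Inbreeding depression in `[0, 1)`.  Default 0.
#' @param seed Integer seed controlling all randomness of a run.
#' @return An object of class `sim_params` (a validated list, with derived
#'   element `brood_weight`).
#' @examples
#' sim_params(alpha = 1.41, census_size = 1e4, n_generations = 35)
#' @export
sim_params <- function(alpha, census_size, n_generations,
                       beta = 1, sigma = 0, delta = 0, seed = 1L) {
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  if (sigma < 0 || sigma >= 1) stop("`sigma` must be in [0, 1)")
  if (delta < 0 || delta >= 1) stop("`delta` must be in [0, 1)")
  if (census_size < 1 || census_size != round(census_size)) {
    stop("`census_size` must be a positive integer")
  }
  if (n_generations < 0 || n_generations != round(n_generations)) {
    stop("`n_generations` must be a non-negative integer")
  }
  structure(
    list(
      alpha = alpha, beta = beta, sigma = sigma, delta = delta,
      census_size = as.integer(census_size),
      n_generations = as.integer(n_generations),
      seed = as.integer(seed),
      brood_weight = 2 * beta * (1 - delta)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_params> alpha = %g, beta = %g, sigma = %g, delta = %g ",
      "(brood weight B = %g)\n  N = %d, generations = %d, seed = %d\n"
    ),
    x$alpha, x$beta, x$sigma, x$delta, x$brood_weight,
    x$census_size, x$n_generations, x$seed
  ))
  invisible(x)
}

## -- seeding -----------------------------------------------------------------

#' Derive a reproducible sub-seed
#'
#' Deterministically folds one or more stream indices into a base seed with a
#' linear-congruential hash (multiplier 69069, modulus 2^31 - 1), so that each
#' replicate / grid point / period of a run draws from its own reproducible
#' stream and can be re-run in isolation.
#'
#' @param seed Base integer seed.
#' @param ... Integer stream indices.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (i in idx) {
    s <- (s * 69069 + as.double(i)) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
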