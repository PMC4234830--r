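## One-cycle competition simulation against a GFP-marked tester population.
##
## The GFP transgene is carried as a second, neutral, codominant marker locus
## fixed within each competitor (wild-type competitor: 0 copies; tester: 2
## copies), so cross-origin outcross progeny are marker heterozygotes.  Only
## one generation of competition is simulated, so recombination between the
## marker and the fog-2 locus is irrelevant.

# Two-locus population: data.frame(origin, sex, fog, gfp, count, mat_weight).
# mat_weight is the pair-sampling weight applied when the row is the XX
# member of a (pseudo-)pair.
.make_competitor <- function(n, fog_p, male_freq, gfp_dose, origin,
                             herm_weight = 1) {
  st <- initialize_population(n, fog_p, male_freq)
  cnt <- st$counts
  keep <- cnt > 0
  data.frame(
    origin = origin,
    sex = .class_sex[keep],
    fog = .class_genotype[keep],
    gfp = gfp_dose,
    count = as.numeric(cnt[keep]),
    mat_weight = ifelse(.class_sex[keep] == "hermaphrodite", herm_weight, 1),
    stringsAsFactors = FALSE
  )
}

# One generation of the mating-pair algorithm on a two-locus class table.
# Returns offspring counts as a 3 x 3 x 3 array [sex, fog + 1, gfp + 1], or
# NULL on extinction.
.advance_two_locus <- function(pop, alpha, beta = 1) {
  N <- sum(pop$count)
  male_i <- which(pop$sex == "male")
  xx_i <- which(pop$sex != "male")
  nm <- sum(pop$count[male_i])
  nxx <- sum(pop$count[xx_i])
  if (nxx == 0) return(NULL)
  m <- nm / N
  K <- min(round(alpha * m * N), nxx)
  # multivariate hypergeometric draw of mated XX across the XX rows
  mated <- numeric(length(xx_i))
  left <- K
  remaining <- nxx
  for (ii in seq_along(xx_i)) {
    ni <- pop$count[xx_i[ii]]
    mated[ii] <- if (left > 0) rhyper(1, ni, remaining - ni, left) else 0
    left <- left - mated[ii]
    remaining <- remaining - ni
  }
  herm <- pop$sex[xx_i] == "hermaphrodite"
  selfed <- ifelse(herm, pop$count[xx_i] - mated, 0)
  if (beta < 1) selfed <- rbinom(length(selfed), selfed, beta)
  wxx <- pop$mat_weight[xx_i]
  pairs <- matrix(0, length(xx_i), length(male_i))
  if (K > 0) {
    pm <- pop$count[male_i] / nm
    for (ii in seq_along(xx_i)) {
      if (mated[ii] > 0) pairs[ii, ] <- drop(rmultinom(1, mated[ii], pm))
    }
  }
  TW <- sum(pairs * wxx) + sum(selfed * wxx)
  if (TW <= 0) return(NULL)
  A <- array(0, c(3, 3, 3)) # [sex(male, herm, female), fog + 1, gfp + 1]
  add_xx <- function(A, mass, qf, qh) {
    gq <- outer(qf, qh)
    A[3, 1, ] <- A[3, 1, ] + mass * gq[1, ] # fog 0 -> female
    A[2, 2:3, ] <- A[2, 2:3, ] + mass * gq[2:3, ] # fog >= 1 -> hermaphrodite
    A
  }
  for (ii in seq_along(xx_i)) {
    gx <- pop$fog[xx_i[ii]]
    hx <- pop$gfp[xx_i[ii]]
    for (jj in seq_along(male_i)) {
      if (pairs[ii, jj] == 0) next
      gm <- pop$fog[male_i[jj]]
      hm <- pop$gfp[male_i[jj]]
      mass <- pairs[ii, jj] * wxx[ii]
      qf <- .mendel_array[gx + 1, gm + 1, ]
      qh <- .mendel_array[hx + 1, hm + 1, ]
      A[1, , ] <- A[1, , ] + 0.5 * mass * outer(qf, qh)
      A <- add_xx(A, 0.5 * mass, qf, qh)
    }
    if (selfed[ii] > 0) {
      qf <- .mendel_array[gx + 1, gx + 1, ]
      qh <- .mendel_array[hx + 1, hx + 1, ]
      A <- add_xx(A, selfed[ii] * wxx[ii], qf, qh)
    }
  }
  cnt <- drop(rmultinom(1, N, as.vector(A) / TW))
  array(cnt, c(3, 3, 3))
}

#' Simulate one life cycle of competition against a GFP tester
#'
#' Mixes a trioecious wild-type competitor with a GFP-marked androdioecious
#' tester at a fixed setup allele ratio (default 50:50), runs one generation
#' of the mating-pair algorithm on the pooled population, and returns the
#' log-ratio fitness
#' `w = ln(p_wt1 / p_gfp1) - ln(p_wt0 / p_gfp0)`
#' of the wild-type marker allele, averaged over replicate cycles.  Marker
#' allele frequencies are computed directly from the simulated offspring
#' genotypes (random mating and selfing, no sex-ratio segregation
#' distortion).  Inbreeding depression `delta` enters as a `1 - delta`
#' pair-sampling weight on GFP-origin hermaphrodites.
#'
#' @param alpha Outcross fitness of the pooled population.
#' @param delta Inbreeding depression weight applied to GFP hermaphrodites,
#'   in `[0, 1]`.
#' @param setup_wt_alleles,setup_gfp_alleles Marker allele counts in the
#'   setup mix (both > 0); only their ratio matters.
#' @param male_freq_wt,male_freq_gfp Male frequencies within each competitor
#'   at setup.
#' @param wt_fog_p Wild-type competitor's fog-2 selfing-allele frequency
#'   (determines its female/hermaphrodite split); the tester is fixed for the
#'   selfing allele.
#' @param N Pooled census size per replicate cycle.
#' @param reps Number of replicate cycles.
#' @param seed Integer seed; replicate r uses [derive_seed()]`(seed, r)`.
#' @param beta Selfing probability of unmated hermaphrodites.
#' @return A list of class `competition_sim` with elements `w` (mean over
#'   replicates; `Inf`/`-Inf` if one marker allele was lost in every
#'   replicate), `w_reps`, `p_gfp_t1` (per-replicate), `male_freq_t1`,
#'   `gfp_extinct`, `wt_extinct` and `n_clamped` (replicates where a lost
#'   allele class was clamped to the boundary pseudo-frequency).
#' @examples
#' simulate_competition_cycle(alpha = 1.41, N = 2000, reps = 4, seed = 1)
#' @export
simulate_competition_cycle <- function(alpha, delta = 0,
                                       setup_wt_alleles = 50,
                                       setup_gfp_alleles = 50,
                                       male_freq_wt = 0.45,
                                       male_freq_gfp = 0.05,
                                       wt_fog_p = 0.026,
                                       N = 1e4, reps = 20, seed = 1,
                                       beta = 1) {
  if (setup_wt_alleles <= 0 || setup_gfp_alleles <= 0) {
    stop("setup allele counts must be > 0")
  }
  if (delta < 0 || delta > 1) stop("`delta` must be in [0, 1]")
  f_wt <- setup_wt_alleles / (setup_wt_alleles + setup_gfp_alleles)
  n_wt <- round(f_wt * N)
  pop <- rbind(
    .make_competitor(n_wt, wt_fog_p, male_freq_wt, gfp_dose = 0L,
                     origin = "wt"),
    .make_competitor(N - n_wt, 1, male_freq_gfp, gfp_dose = 2L,
                     origin = "gfp", herm_weight = 1 - delta)
  )
  p0_wt <- f_wt
  p0_gfp <- 1 - f_wt
  w_reps <- numeric(reps)
  p_gfp_t1 <- numeric(reps)
  male_t1 <- numeric(reps)
  gfp_lost <- logical(reps)
  wt_lost <- logical(reps)
  for (r in seq_len(reps)) {
    A <- with_seed(derive_seed(seed, r), .advance_two_locus(pop, alpha, beta))
    if (is.null(A)) stop("no reproducing pairs in the pooled population")
    Ntot <- sum(A)
    gfp_alleles <- sum(A * rep(0:2, each = 9)) # gfp is the slowest index
    male_t1[r] <- sum(A[1, , ]) / Ntot
    gfp_lost[r] <- gfp_alleles == 0
    wt_lost[r] <- gfp_alleles == 2 * Ntot
    pg <- clamp_frequency(gfp_alleles, 2 * Ntot)
    p_gfp_t1[r] <- gfp_alleles / (2 * Ntot)
    w_reps[r] <- log((1 - pg) / pg) - log(p0_wt / p0_gfp)
  }
  gfp_extinct <- all(gfp_lost)
  wt_extinct <- all(wt_lost)
  n_clamped <- sum((gfp_lost | wt_lost) & !gfp_extinct & !wt_extinct)
  if (n_clamped > 0) {
    warning(n_clamped, " replicate(s) lost a marker allele class; ",
            "boundary-clamped frequencies used")
  }
  w <- if (gfp_extinct) {
    Inf
  } else if (wt_extinct) {
    -Inf
  } else {
    mean(w_reps)
  }
  structure(
    list(
      w = w, w_reps = w_reps, p_gfp_t1 = p_gfp_t1, male_freq_t1 = male_t1,
      gfp_extinct = gfp_extinct, wt_extinct = wt_extinct,
      n_clamped = n_clamped, reps = reps, seed = seed
    ),
    class = "competition_sim"
  )
}

#' @export
print.competition_sim <- function(x, ...) {
  cat("<competition_sim>", x$reps, "replicate cycles\n")
  cat("  w =", x$w, "\n")
  if (x$gfp_extinct) cat("  flag: GFP allele lost in every replicate\n")
  if (x$wt_extinct) cat("  flag: wild-type allele lost in every replicate\n")
  invisible(x)
}
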