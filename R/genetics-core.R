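## Elementary genetic arithmetic at the fog-2 locus.
##
## Genotypes are represented throughout by the number of wild-type ("selfing")
## alleles carried: 0 = q71/q71, 1 = wt/q71, 2 = wt/wt.  Sexes are the strings
## "male", "hermaphrodite", "female".

#' Genotype and sex codes
#'
#' `fog2_genotypes()` returns the three diploid genotype codes used by the
#' package (number of wild-type alleles: 0, 1, 2, named by the conventional
#' allele notation).  `sexes()` returns the three sex labels.
#'
#' @return A named integer vector (`fog2_genotypes`) or character vector
#'   (`sexes`).
#' @examples
#' fog2_genotypes()
#' sexes()
#' @export
fog2_genotypes <- function() {
  c("q71/q71" = 0L, "wt/q71" = 1L, "wt/wt" = 2L)
}

#' @rdname fog2_genotypes
#' @export
sexes <- function() {
  c("male", "hermaphrodite", "female")
}

#' Sex determination from karyotype and fog-2 genotype
#'
#' XO animals are male regardless of genotype.  Among XX animals the recessive
#' q71 allele transforms hermaphrodites into functional females when
#' homozygous, so XX q71/q71 individuals are female and XX carriers of at
#' least one wild-type allele are self-compatible hermaphrodites.
#'
#' @param karyotype Character vector, each element `"XX"` or `"XO"`.
#' @param genotype Integer vector of wild-type allele counts (0, 1 or 2),
#'   recycled against `karyotype`.
#' @return Character vector of sexes (`"male"`, `"hermaphrodite"`,
#'   `"female"`).
#' @examples
#' sex_from_genotype("XX", 0)  # female
#' sex_from_genotype("XX", 1)  # hermaphrodite (q71 is recessive)
#' sex_from_genotype("XO", 0)  # male
#' @export
sex_from_genotype <- function(karyotype, genotype) {
  if (!all(karyotype %in% c("XX", "XO"))) {
    stop("`karyotype` must be \"XX\" or \"XO\"")
  }
  genotype <- check_genotype(genotype)
  n <- max(length(karyotype), length(genotype))
  karyotype <- rep_len(karyotype, n)
  genotype <- rep_len(genotype, n)
  out <- ifelse(karyotype == "XO", "male",
    ifelse(genotype == 0L, "female", "hermaphrodite")
  )
  out
}

#' Mendelian offspring genotype distribution
#'
#' Distribution of offspring genotypes when one allele is drawn uniformly
#' from each parent.  Selfing corresponds to `parent1 == parent2`.
#'
#' @param parent1,parent2 Single genotype codes (wild-type allele count 0, 1
#'   or 2).
#' @return Named numeric vector of length 3 (probabilities of offspring
#'   genotypes 0, 1, 2), summing to 1.
#' @examples
#' mendelian_offspring_distribution(1, 1)  # 1/4, 1/2, 1/4
#' mendelian_offspring_distribution(2, 0)  # all heterozygous
#' @export
mendelian_offspring_distribution <- function(parent1, parent2) {
  parent1 <- check_genotype(parent1, scalar = TRUE)
  parent2 <- check_genotype(parent2, scalar = TRUE)
  p1 <- parent1 / 2
  p2 <- parent2 / 2
  out <- c(
    (1 - p1) * (1 - p2),
    p1 * (1 - p2) + (1 - p1) * p2,
    p1 * p2
  )
  names(out) <- names(fog2_genotypes())
  out
}

# 3 x 3 x 3 array MEND[g1 + 1, g2 + 1, ] = offspring genotype distribution;
# precomputed once for the simulator hot path.
.mendel_array <- local({
  a <- array(0, c(3, 3, 3))
  for (g1 in 0:2) {
    for (g2 in 0:2) {
      p1 <- g1 / 2
      p2 <- g2 / 2
      a[g1 + 1, g2 + 1, ] <- c(
        (1 - p1) * (1 - p2),
        p1 * (1 - p2) + (1 - p1) * p2,
        p1 * p2
      )
    }
  }
  a
})

#' Expected homozygote frequency under random union of gametes
#'
#' Frequency `p^2` of homozygotes for an allele segregating at frequency `p`.
#' Note this is the homozygote frequency, not the carrier frequency
#' `1 - (1 - p)^2`; see [expected_carrier_frequency()].
#'
#' @param p Allele frequency in `[0, 1]` (vectorised).
#' @return `p^2`.
#' @examples
#' expected_homozygote_frequency(0.026)  # 6.76e-4
#' @export
expected_homozygote_frequency <- function(p) {
  check_frequency(p)
  p^2
}

#' @rdname expected_homozygote_frequency
#' @export
expected_carrier_frequency <- function(p) {
  check_frequency(p)
  1 - (1 - p)^2
}

#' Offspring allele frequency from parental pools
#'
#' Each offspring draws one allele from the maternal pool and one from the
#' paternal pool, so the expected offspring allele frequency is the parental
#' average.
#'
#' @param maternal_p,paternal_p Allele frequencies in `[0, 1]` (vectorised).
#' @return `(maternal_p + paternal_p) / 2`.
#' @examples
#' offspring_allele_frequency(0, 0.052)  # 0.026
#' @export
offspring_allele_frequency <- function(maternal_p, paternal_p) {
  check_frequency(maternal_p)
  check_frequency(paternal_p)
  (maternal_p + paternal_p) / 2
}

#' Selfing rate from male frequency, and its inverse
#'
#' Under random mating without sex-ratio segregation distortion, every
#' outcross event generates males and hermaphrodites/females in equal
#' proportion, so the outcrossing rate is twice the male frequency and the
#' selfing rate is `S = 1 - 2 m`.
#'
#' @param m Male frequency in `[0, 0.5]` (vectorised).
#' @param S Selfing rate in `[0, 1]` (vectorised).
#' @return `selfing_rate_from_male_frequency()` returns `1 - 2 * m`;
#'   `male_frequency_from_selfing_rate()` returns `(1 - S) / 2`.
#' @examples
#' selfing_rate_from_male_frequency(0.31)   # 0.38
#' male_frequency_from_selfing_rate(0.38)   # 0.31
#' @export
selfing_rate_from_male_frequency <- function(m) {
  check_frequency(m)
  if (any(m > 0.5)) {
    stop("male frequency > 0.5 implies an impossible sex ratio for this estimator")
  }
  1 - 2 * m
}

#' @rdname selfing_rate_from_male_frequency
#' @export
male_frequency_from_selfing_rate <- function(S) {
  check_frequency(S)
  (1 - S) / 2
}

#' Power to detect a segregating allele by exhaustive genotyping
#'
#' Probability of observing at least one copy of an allele at frequency `p`
#' among the `2 * n_individuals` alleles of a binomial sample of diploid
#' individuals: `1 - (1 - p)^(2 n)`.  Non-integer `n_individuals` is allowed
#' so that a mean realised sample size can be plugged in directly.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @param n_individuals Number of diploid individuals genotyped (>= 1; may be
#'   fractional).
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detection_power(0.02, 42.7)  # ~0.82
#' @export
detection_power <- function(p, n_individuals) {
  check_frequency(p)
  if (any(n_individuals < 1)) stop("`n_individuals` must be >= 1")
  1 - (1 - p)^(2 * n_individuals)
}

#' Boundary-clamped sample frequency
#'
#' Converts an allele count out of `n` sampled alleles into a frequency that
#' is strictly inside (0, 1), so that log-ratios computed downstream stay
#' finite.  Interior counts give the plain ratio `k / n`; a count of 0 is
#' clamped to `1 / (n + 1)` and a count of `n` to `n / (n + 1)`.  With the
#' standard sample of 48 diploid individuals (`n = 96`) the boundaries are
#' `1/97` and `96/97`.
#'
#' @param k Allele count(s), `0 <= k <= n`.
#' @param n Total number of alleles sampled (>= 1), recycled against `k`.
#' @return Frequencies strictly inside (0, 1).
#' @examples
#' clamp_frequency(0, 96)   # 1/97
#' clamp_frequency(96, 96)  # 96/97
#' clamp_frequency(48, 96)  # 0.5
#' @export
clamp_frequency <- function(k, n) {
  if (any(n < 1)) stop("`n` must be >= 1")
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  len <- max(length(k), length(n))
  k <- rep_len(k, len)
  n <- rep_len(n, len)
  out <- k / n
  out[k == 0] <- 1 / (n[k == 0] + 1)
  out[k == n] <- n[k == n] / (n[k == n] + 1)
  out
}

## -- internal argument checks ------------------------------------------------

check_genotype <- function(g, scalar = FALSE) {
  if (scalar && length(g) != 1L) stop("expected a single genotype code")
  if (any(is.na(g)) || !all(g %in% c(0, 1, 2))) {
    stop("genotypes must be coded as the number of wild-type alleles (0, 1 or 2)")
  }
  as.integer(g)
}

check_frequency <- function(x, name = deparse(substitute(x))) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a frequency in [0, 1]", name))
  }
  invisible(x)
}
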