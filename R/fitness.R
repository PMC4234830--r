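## Fitness estimators of the experimental-evolution assays: transition
## fitness s, competitive fitness w with the GFP heterozygote correction and
## block centering, male fitness w_m, and the quality-control filters.

#' Transition fitness of the selfing allele
#'
#' Per-generation selection coefficient of the invading wild-type (selfing)
#' allele, estimated as the ordinary-least-squares slope of the natural log
#' ratio of wild-type to q71 allele frequencies on generation.  Frequencies
#' are boundary-clamped ([clamp_frequency()]) so undetected or fixed alleles
#' contribute finite log ratios.  Replicate populations are pooled into a
#' single regression with one shared slope (and, by default, one shared
#' intercept).
#'
#' @param series Data frame with columns `generation`, `n_wt_alleles`,
#'   `n_total_alleles`, and optionally `population_id`.
#' @param intercept `"common"` (one intercept for all series, the default) or
#'   `"by_population"` (one intercept per replicate population).
#' @return List of class `transition_fitness`: `s` (slope), `se` (its
#'   standard error), `n_obs`, and the underlying `fit` (an `lm` object).
#' @examples
#' ser <- data.frame(
#'   generation = c(0, 10),
#'   n_wt_alleles = c(48, 96), n_total_alleles = 96
#' )
#' transition_fitness(ser)$s # log(96) / 10
#' @export
transition_fitness <- function(series, intercept = c("common", "by_population")) {
  intercept <- match.arg(intercept)
  req <- c("generation", "n_wt_alleles", "n_total_alleles")
  if (!all(req %in% names(series))) {
    stop("`series` needs columns: ", paste(req, collapse = ", "))
  }
  if (length(unique(series$generation)) < 2) {
    stop("need observations at >= 2 distinct generations to estimate a slope")
  }
  p <- clamp_frequency(series$n_wt_alleles, series$n_total_alleles)
  y <- log(p / (1 - p))
  df <- data.frame(y = y, generation = series$generation)
  if (intercept == "by_population" && !is.null(series$population_id)) {
    df$population_id <- factor(series$population_id)
    fit <- lm(y ~ generation + population_id, data = df)
  } else {
    fit <- lm(y ~ generation, data = df)
  }
  est <- summary(fit)$coefficients["generation", ]
  structure(
    list(
      s = unname(est["Estimate"]),
      se = unname(est["Std. Error"]),
      n_obs = nrow(df),
      fit = fit
    ),
    class = "transition_fitness"
  )
}

#' @export
print.transition_fitness <- function(x, ...) {
  cat(sprintf(
    "<transition_fitness> s = %.4f +/- %.4f SE (%d observations)\n",
    x$s, x$se, x$n_obs
  ))
  invisible(x)
}

#' GFP heterozygote correction: phenotype counts to allele counts
#'
#' Competition assays score larvae only for presence/absence of GFP
#' expression (the transgene is dominant for scoring), so marker
#' heterozygotes produced by cross-competitor outcrossing are invisible.
#' This correction reconstructs expected allele counts under random mating
#' and selfing with no sex-ratio segregation distortion: each competitor's
#' progeny is outcrossed in proportion `2 * m_i` (its male frequency), sire
#' origin among outcross events is proportional to each competitor's male
#' supply (adult frequency times male frequency), and cross-origin progeny
#' are marker heterozygotes.  The expected heterozygote share `theta` among
#' GFP-positive larvae is computed from these proportions, using the final
#' phenotype frequencies as the initial adult-frequency estimate and
#' iterating the implied allele frequency to a fixed point.
#'
#' @param final_gfp_pos,final_gfp_neg Scored GFP-positive / negative larval
#'   counts after one generation of competition.
#' @param male_freq_wt,male_freq_gfp Male frequencies of the wild-type and
#'   GFP competitor populations during the assay (each `<= 0.5`).
#' @param tol Fixed-point convergence tolerance (default `1e-10`).
#' @param max_iter Maximum fixed-point iterations (default 100).
#' @return List with `wt_alleles`, `gfp_alleles` (summing exactly to
#'   `2 * (final_gfp_pos + final_gfp_neg)`), the heterozygote share `theta`,
#'   `iterations` and `converged`.
#' @examples
#' # pure selfing: no heterozygotes, allele = phenotype frequencies
#' gfp_phenotype_to_allele_counts(500, 500, 0, 0)
#' @export
gfp_phenotype_to_allele_counts <- function(final_gfp_pos, final_gfp_neg,
                                           male_freq_wt, male_freq_gfp,
                                           tol = 1e-10, max_iter = 100) {
  if (final_gfp_pos < 0 || final_gfp_neg < 0 ||
    final_gfp_pos + final_gfp_neg == 0) {
    stop("need non-negative final counts with a positive total")
  }
  check_frequency(male_freq_wt)
  check_frequency(male_freq_gfp)
  if (male_freq_wt > 0.5 || male_freq_gfp > 0.5) {
    stop("male frequencies must be <= 0.5")
  }
  n_tot <- final_gfp_pos + final_gfp_neg
  a_g <- final_gfp_pos / n_tot
  o_w <- 2 * male_freq_wt
  o_g <- 2 * male_freq_gfp
  theta <- 0
  converged <- FALSE
  iterations <- 0
  for (it in seq_len(max_iter)) {
    iterations <- it
    a_w <- 1 - a_g
    supply <- c(wt = a_w * male_freq_wt, gfp = a_g * male_freq_gfp)
    if (sum(supply) > 0) {
      s_w <- supply["wt"] / sum(supply)
      s_g <- supply["gfp"] / sum(supply)
    } else {
      s_w <- s_g <- 0
    }
    pos <- a_g + a_w * o_w * s_g
    het <- a_g * o_g * s_w + a_w * o_w * s_g
    theta <- if (pos > 0) het / pos else 0
    a_g_new <- (2 - theta) * final_gfp_pos / (2 * n_tot)
    done <- abs(a_g_new - a_g) < tol
    a_g <- unname(a_g_new)
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "heterozygote-share fixed point did not converge in %d iterations (last a_gfp = %.8f)",
      max_iter, a_g
    ))
  }
  theta <- unname(theta)
  list(
    wt_alleles = 2 * final_gfp_neg + theta * final_gfp_pos,
    gfp_alleles = (2 - theta) * final_gfp_pos,
    theta = theta,
    iterations = iterations,
    converged = converged
  )
}

#' Competitive fitness from a competition record
#'
#' One-generation log-ratio fitness of the wild-type allele against the GFP
#' tester allele, `w = ln(p_wt.t1 / p_GFP.t1) - ln(p_wt.t0 / p_GFP.t0)`,
#' after applying the GFP heterozygote correction
#' ([gfp_phenotype_to_allele_counts()]) to the scored phenotype counts.
#' Setup frequencies come from the (homozygous) setup counts.  Records whose
#' setup wild-type frequency deviates from 0.5 by more than `setup_band` are
#' flagged (`setup_flagged`); exclusion is left to the caller.
#'
#' @param records Data frame with columns `block`, `population_id`,
#'   `setup_wt`, `setup_gfp`, `final_gfp_pos`, `final_gfp_neg`,
#'   `male_freq_wt`, `male_freq_gfp`.
#' @param setup_band Allowed deviation of the setup wild-type frequency from
#'   0.5 before a record is flagged (default 0.15).
#' @return `records` with added columns `theta`, `p_wt_t1`, `w` and
#'   `setup_flagged`.  Zero corrected counts are boundary-clamped with a
#'   warning.
#' @export
competition_fitness <- function(records, setup_band = 0.15) {
  req <- c(
    "setup_wt", "setup_gfp", "final_gfp_pos", "final_gfp_neg",
    "male_freq_wt", "male_freq_gfp"
  )
  if (!all(req %in% names(records))) {
    stop("`records` needs columns: ", paste(req, collapse = ", "))
  }
  usable <- records$final_gfp_pos + records$final_gfp_neg > 0
  if (!all(usable)) stop("records with no scored larvae: rows ",
                         paste(which(!usable), collapse = ", "))
  n <- nrow(records)
  theta <- p1 <- w <- numeric(n)
  clamped <- FALSE
  for (i in seq_len(n)) {
    corr <- gfp_phenotype_to_allele_counts(
      records$final_gfp_pos[i], records$final_gfp_neg[i],
      records$male_freq_wt[i], records$male_freq_gfp[i]
    )
    tot <- corr$wt_alleles + corr$gfp_alleles
    if (corr$wt_alleles == 0 || corr$gfp_alleles == 0) clamped <- TRUE
    p1[i] <- clamp_frequency(corr$wt_alleles, tot)
    theta[i] <- corr$theta
    p0 <- clamp_frequency(
      records$setup_wt[i], records$setup_wt[i] + records$setup_gfp[i]
    )
    w[i] <- log(p1[i] / (1 - p1[i])) - log(p0 / (1 - p0))
  }
  if (clamped) {
    warning("corrected allele counts of 0 boundary-clamped before log-ratios")
  }
  records$theta <- theta
  records$p_wt_t1 <- p1
  records$w <- w
  setup_p <- records$setup_wt / (records$setup_wt + records$setup_gfp)
  records$setup_flagged <- abs(setup_p - 0.5) > setup_band
  records
}

#' Block centering and ancestor subtraction of competitive fitness
#'
#' Centers raw `w` estimates on the block mean of a lab-adapted reference
#' population assayed in every block (`w_t = w - mean(w_reference | block)`),
#' then optionally subtracts ancestral-population means by reproduction
#' system (`delta_w_t = w_t - ancestor_mean[system]`).  Blocks lacking a
#' reference record are excluded with a warning.
#'
#' @param estimates Data frame with columns `block`, `population_id`, `w`,
#'   and (if `ancestor_means` is given) `system`.
#' @param reference_label `population_id` of the reference population.
#' @param ancestor_means Optional named numeric vector of ancestral `w_t`
#'   means, indexed by reproduction system.
#' @return `estimates` with added column `w_t` (and `delta_w_t` when
#'   `ancestor_means` is supplied); reference records' `w_t` average exactly
#'   0 within each block.
#' @export
block_center_and_delta <- function(estimates, reference_label,
                                   ancestor_means = NULL) {
  req <- c("block", "population_id", "w")
  if (!all(req %in% names(estimates))) {
    stop("`estimates` needs columns: ", paste(req, collapse = ", "))
  }
  is_ref <- estimates$population_id == reference_label
  ref_means <- tapply(estimates$w[is_ref], estimates$block[is_ref], mean)
  have_ref <- as.character(estimates$block) %in% names(ref_means)
  if (!all(have_ref)) {
    warning(
      "blocks without a ", reference_label, " reference excluded: ",
      paste(unique(estimates$block[!have_ref]), collapse = ", ")
    )
    estimates <- estimates[have_ref, , drop = FALSE]
  }
  estimates$w_t <- estimates$w -
    unname(ref_means[as.character(estimates$block)])
  if (!is.null(ancestor_means)) {
    if (is.null(estimates$system)) {
      stop("`ancestor_means` given but `estimates` has no `system` column")
    }
    unknown <- setdiff(unique(estimates$system), names(ancestor_means))
    if (length(unknown)) {
      stop("no ancestor mean for system(s): ", paste(unknown, collapse = ", "))
    }
    estimates$delta_w_t <- estimates$w_t -
      unname(ancestor_means[as.character(estimates$system)])
  }
  estimates
}

#' Male fitness from mating-plate progeny counts
#'
#' Competitive male fitness against GFP tester males for the fertilisation of
#' fog-2 females: wild-type sires yield non-GFP progeny and tester sires GFP
#' progeny (both competitor strains are homozygous), so the wild-type allele
#' frequency after competition is `p_t1 = gfp_neg / (gfp_neg + gfp_pos)`.
#' With the setup fixed at `p_t0 = 0.5`,
#' `w_m = logit(p_t1) - logit(0.5) = logit(p_t1)`.
#'
#' @param records Data frame with columns `plate`, `females_transferred`,
#'   `progeny_gfp_pos`, `progeny_gfp_neg`.
#' @param apply_qc Apply [qc_filter_male_plates()] first (default `TRUE`).
#' @return The (possibly filtered) records with added columns `p_t1` and
#'   `w_m`; boundary counts are clamped via [clamp_frequency()] with a
#'   warning.
#' @examples
#' male_fitness(data.frame(
#'   plate = 1, females_transferred = 15,
#'   progeny_gfp_pos = 10, progeny_gfp_neg = 30
#' ))
#' @export
male_fitness <- function(records, apply_qc = TRUE) {
  req <- c("plate", "females_transferred", "progeny_gfp_pos", "progeny_gfp_neg")
  if (!all(req %in% names(records))) {
    stop("`records` needs columns: ", paste(req, collapse = ", "))
  }
  if (apply_qc) records <- qc_filter_male_plates(records)
  tot <- records$progeny_gfp_pos + records$progeny_gfp_neg
  if (any(records$progeny_gfp_neg == 0 | records$progeny_gfp_neg == tot)) {
    warning("plates with all progeny from one sire class boundary-clamped")
  }
  p1 <- clamp_frequency(records$progeny_gfp_neg, tot)
  records$p_t1 <- p1
  records$w_m <- log(p1 / (1 - p1))
  records
}

#' Quality-control filters for male-fitness plates and fertility counts
#'
#' `qc_filter_male_plates()` keeps mating plates with at least 6 females
#' transferred and at least 20 progeny scored.  `qc_filter_fertility()`
#' keeps fertility observations with at least 5 progeny scored and, in the
#' outcross treatment, at least 10% male progeny.  Both attach a per-rule
#' rejection tally as attribute `"rejections"` and are idempotent.
#'
#' @param records Male-plate records (columns `females_transferred`,
#'   `progeny_gfp_pos`, `progeny_gfp_neg`).
#' @return The kept rows, with attribute `rejections` (named counts per
#'   rule; rows violating several rules count towards each).
#' @export
qc_filter_male_plates <- function(records) {
  tot <- records$progeny_gfp_pos + records$progeny_gfp_neg
  few_females <- records$females_transferred < 6
  few_progeny <- tot < 20
  kept <- records[!(few_females | few_progeny), , drop = FALSE]
  attr(kept, "rejections") <- c(
    few_females = sum(few_females),
    few_progeny = sum(few_progeny)
  )
  kept
}

#' @rdname qc_filter_male_plates
#' @param observations Fertility observations: columns `progeny_total`,
#'   `treatment` (`"self"` or `"outcross"`) and `n_male_progeny`.
#' @export
qc_filter_fertility <- function(observations) {
  req <- c("progeny_total", "treatment", "n_male_progeny")
  if (!all(req %in% names(observations))) {
    stop("`observations` needs columns: ", paste(req, collapse = ", "))
  }
  few_progeny <- observations$progeny_total < 5
  male_frac <- ifelse(observations$progeny_total > 0,
    observations$n_male_progeny / observations$progeny_total, 0
  )
  few_males <- observations$treatment == "outcross" & male_frac < 0.10
  kept <- observations[!(few_progeny | few_males), , drop = FALSE]
  attr(kept, "rejections") <- c(
    few_progeny = sum(few_progeny),
    few_males = sum(few_males)
  )
  kept
}
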