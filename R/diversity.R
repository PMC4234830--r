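## SNP-panel diversity statistics for unphased diploid genotypes: observed
## homozygosity (1 - Ho), Burrows' composite linkage disequilibrium r^2, the
## minor-allele-frequency filter, the staged missing-data cleaning, and the
## ANCOVA of fitness responses on diversity.

#' SNP genotype matrix
#'
#' Validated container for unphased diploid genotypes: an individuals x loci
#' integer matrix of reference-allele counts (0, 1, 2, `NA` for missing) with
#' a population label per individual.
#'
#' @param genotypes Numeric matrix (individuals x loci) with values in
#'   `{0, 1, 2, NA}`; column names identify loci (e.g. `"IV:1204556"`), row
#'   names identify individuals.
#' @param population Character vector of population labels, one per row.
#' @return Object of class `snp_matrix`: list with `genotypes` and
#'   `population`.  Loci with no non-missing calls are rejected.
#' @export
snp_matrix <- function(genotypes, population) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2, NA))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (length(population) != nrow(genotypes)) {
    stop("`population` must have one label per individual (row)")
  }
  all_missing <- colSums(!is.na(genotypes)) == 0
  if (any(all_missing)) {
    stop(
      "loci with all calls missing: ",
      paste(colnames(genotypes)[all_missing], collapse = ", ")
    )
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  structure(
    list(genotypes = genotypes, population = as.character(population)),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(
    "<snp_matrix>", nrow(x$genotypes), "individuals x", ncol(x$genotypes),
    "loci;", length(unique(x$population)), "population(s)\n"
  )
  invisible(x)
}

#' Subset a SNP matrix to one population
#'
#' @param x A [snp_matrix()].
#' @param population Population label.
#' @return A [snp_matrix()] restricted to that population's individuals.
#' @export
subset_population <- function(x, population) {
  stopifnot(inherits(x, "snp_matrix"))
  keep <- x$population == population
  if (!any(keep)) stop("no individuals in population ", population)
  g <- x$genotypes[keep, , drop = FALSE]
  g <- g[, colSums(!is.na(g)) > 0, drop = FALSE]
  snp_matrix(g, x$population[keep])
}

#' Staged missing-data cleaning
#'
#' Cleans a raw genotype matrix in three ordered stages: (1) drop SNPs with
#' more than 80% missing calls across all samples, (2) drop individuals with
#' more than 60% missing calls, (3) drop SNPs with more than 50% missing
#' calls.
#'
#' @param x A [snp_matrix()].
#' @param locus_thresholds Missingness thresholds of stages 1 and 3.
#' @param individual_threshold Missingness threshold of stage 2.
#' @return A cleaned [snp_matrix()] with attribute `dropped` (list of locus
#'   and individual names removed per stage).
#' @export
clean_snp_matrix <- function(x, locus_thresholds = c(0.8, 0.5),
                             individual_threshold = 0.6) {
  stopifnot(inherits(x, "snp_matrix"))
  g <- x$genotypes
  pop <- x$population
  miss_l <- colMeans(is.na(g))
  drop1 <- miss_l > locus_thresholds[1]
  g <- g[, !drop1, drop = FALSE]
  miss_i <- rowMeans(is.na(g))
  drop2 <- miss_i > individual_threshold
  g <- g[!drop2, , drop = FALSE]
  pop <- pop[!drop2]
  miss_l2 <- colMeans(is.na(g))
  drop3 <- miss_l2 > locus_thresholds[2]
  g <- g[, !drop3, drop = FALSE]
  out <- snp_matrix(g, pop)
  attr(out, "dropped") <- list(
    loci_stage1 = names(which(drop1)),
    individuals_stage2 = names(which(drop2)),
    loci_stage3 = names(which(drop3))
  )
  out
}

#' Observed homozygosity 1 - Ho
#'
#' One minus the mean (across loci) proportion of heterozygous genotypes
#' among non-missing calls.  Rises towards 1 under sustained selfing.
#'
#' @param x A [snp_matrix()] (restrict to one population first, e.g. with
#'   [subset_population()]).
#' @return `1 - Ho`, a number in `[0, 1]`.
#' @export
homozygosity <- function(x) {
  stopifnot(inherits(x, "snp_matrix"))
  g <- x$genotypes
  het <- colMeans(g == 1, na.rm = TRUE)
  usable <- colSums(!is.na(g)) > 0
  if (!any(usable)) stop("no locus with non-missing calls")
  1 - mean(het[usable])
}

#' Minor-allele-frequency filter
#'
#' Removes loci whose minor allele frequency, computed on non-missing calls
#' of the matrix at hand, is strictly below `threshold`.
#'
#' @param x A [snp_matrix()].
#' @param threshold MAF threshold (default 0.05; loci at exactly the
#'   threshold are retained).
#' @return Filtered [snp_matrix()] with attribute `dropped_loci`.
#' @export
maf_filter <- function(x, threshold = 0.05) {
  stopifnot(inherits(x, "snp_matrix"))
  g <- x$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- maf < threshold
  out <- x
  out$genotypes <- g[, !drop, drop = FALSE]
  attr(out, "dropped_loci") <- colnames(g)[drop]
  out
}

# Composite (Burrows) disequilibrium correlation for one locus pair on
# pairwise-complete individuals; returns NA when a normalizer is not
# positive (no usable variation).
.pair_composite_r <- function(xa, xb) {
  ok <- !is.na(xa) & !is.na(xb)
  n <- sum(ok)
  if (n < 2) return(NA_real_)
  xa <- xa[ok]
  xb <- xb[ok]
  pa <- mean(xa) / 2
  pb <- mean(xb) / 2
  delta <- mean(xa * xb) / 2 - 2 * pa * pb
  da <- mean(xa == 2) - pa^2
  db <- mean(xb == 2) - pb^2
  na_ <- pa * (1 - pa) + da
  nb_ <- pb * (1 - pb) + db
  if (na_ <= 0 || nb_ <= 0) return(NA_real_)
  delta / sqrt(na_ * nb_)
}

#' Mean composite linkage disequilibrium r-squared
#'
#' Pairwise SNP linkage disequilibrium from unphased genotypes as the
#' squared composite (Burrows) correlation, which does not assume
#' Hardy-Weinberg equilibrium: for loci A and B,
#' `Delta = mean(X * Y) / 2 - 2 * pA * pB` with X, Y the 0/1/2 codes, and
#' `r = Delta / sqrt((pA qA + DA) (pB qB + DB))` where
#' `DA = freq(X == 2) - pA^2` is the within-locus departure from
#' Hardy-Weinberg.  Pairs use pairwise-complete individuals; `r^2` is
#' clipped to `[0, 1]` and averaged over all pairs.
#'
#' @param x A [snp_matrix()] restricted to one population.
#' @param maf_threshold Minor-allele-frequency filter applied first
#'   ([maf_filter()]).
#' @return Object of class `composite_ld`: list with `mean_r2` (`NA` when
#'   fewer than 2 loci survive the MAF filter), `pairs` (per-pair data frame
#'   `locus_a`, `locus_b`, `r2`), `n_loci_used` and `n_pairs_skipped`
#'   (zero-variance pairs).
#' @export
composite_ld_mean_r2 <- function(x, maf_threshold = 0.05) {
  stopifnot(inherits(x, "snp_matrix"))
  xf <- maf_filter(x, maf_threshold)
  g <- xf$genotypes
  L <- ncol(g)
  if (L < 2) {
    out <- list(
      mean_r2 = NA_real_, pairs = NULL, n_loci_used = L, n_pairs_skipped = 0L
    )
    class(out) <- "composite_ld"
    return(out)
  }
  idx <- utils::combn(L, 2)
  r2 <- numeric(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    r <- .pair_composite_r(g[, idx[1, k]], g[, idx[2, k]])
    r2[k] <- if (is.na(r)) NA_real_ else min(r^2, 1)
  }
  pairs <- data.frame(
    locus_a = colnames(g)[idx[1, ]],
    locus_b = colnames(g)[idx[2, ]],
    r2 = r2
  )
  out <- list(
    mean_r2 = mean(r2, na.rm = TRUE),
    pairs = pairs,
    n_loci_used = L,
    n_pairs_skipped = sum(is.na(r2))
  )
  if (all(is.na(r2))) out$mean_r2 <- NA_real_
  class(out) <- "composite_ld"
  out
}

#' @export
print.composite_ld <- function(x, ...) {
  cat(
    "<composite_ld> mean r2 =", x$mean_r2, "over", x$n_loci_used,
    "loci;", x$n_pairs_skipped, "pair(s) skipped\n"
  )
  invisible(x)
}

#' Per-population diversity summary
#'
#' @param x A [snp_matrix()] with possibly several populations.
#' @param maf_threshold MAF threshold for the LD statistic.
#' @return Data frame with one row per population: `population`,
#'   `one_minus_ho`, `mean_r2` (`NA` when fewer than 2 loci survive the MAF
#'   filter) and `n_loci_used`.
#' @export
diversity_summary <- function(x, maf_threshold = 0.05) {
  stopifnot(inherits(x, "snp_matrix"))
  pops <- unique(x$population)
  do.call(rbind, lapply(pops, function(p) {
    sub <- subset_population(x, p)
    ld <- composite_ld_mean_r2(sub, maf_threshold)
    data.frame(
      population = p,
      one_minus_ho = homozygosity(sub),
      mean_r2 = ld$mean_r2,
      n_loci_used = ld$n_loci_used
    )
  }))
}

#' ANCOVA of fitness responses on a diversity covariate
#'
#' Sequential (Type I) least-squares analysis of covariance testing whether
#' per-population fitness responses (`delta_w_t`) are explained by a
#' continuous diversity covariate (homozygosity or mean LD), entered first,
#' followed by the categorical reproduction system.  F statistics use the
#' residual mean square; with three systems and one covariate the residual
#' degrees of freedom are `n - 4`.
#'
#' @param data Data frame with columns `population`, `delta_w_t`,
#'   `covariate` and `system`.
#' @return List of class `diversity_ancova`: `table` (data frame with one
#'   row per term: `term`, `df`, `ss`, `ms`, `f_value`, `p_value`) and `fit`
#'   (the underlying `lm`).
#' @export
diversity_fitness_ancova <- function(data) {
  req <- c("population", "delta_w_t", "covariate", "system")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns: ", paste(req, collapse = ", "))
  }
  data <- data[complete.cases(data[req]), , drop = FALSE]
  if (length(unique(data$system)) < 2) {
    stop("need >= 2 reproduction systems")
  }
  if (length(unique(data$covariate)) < 2) {
    stop("the covariate is constant; its term is undefined")
  }
  fit <- lm(delta_w_t ~ covariate + factor(system), data = data)
  an <- anova(fit)
  tab <- data.frame(
    term = c("covariate", "system", "error"),
    df = an$Df,
    ss = an$`Sum Sq`,
    ms = an$`Mean Sq`,
    f_value = an$`F value`,
    p_value = an$`Pr(>F)`
  )
  structure(list(table = tab, fit = fit), class = "diversity_ancova")
}

#' @export
print.diversity_ancova <- function(x, ...) {
  cat("<diversity_ancova> sequential (Type I) sums of squares\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
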