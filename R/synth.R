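## Synthetic-data generators with known ground truth, emulating the structure
## of the five assay-table kinds (fog-2 genotype counts per generation, male
## counts, competition GFP counts with block structure, male-fitness progeny
## counts, SNP genotype matrices), so every pipeline stage can be exercised
## end to end without the deposited data.  Every generator is deterministic
## given its seed and, when `out_dir` is supplied, writes its table as TSV
## with a JSON truth sidecar.

.write_synth <- function(data, truth, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(data, file.path(out_dir, paste0(name, ".tsv")))
  jsonlite::write_json(
    truth, file.path(out_dir, paste0(name, ".truth.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(NULL)
}

#' Generate a fog-2 genotype-frequency trajectory dataset
#'
#' Simulates replicate trioecious populations under a known outcross fitness
#' with the individual-based engine, then emulates the genotyping assay: at
#' each sampled generation, `n_genotyped` larvae are drawn without
#' replacement and PCR-genotyped (wild-type allele count out of
#' `2 * n_genotyped`), and `n_sexed` adults are sexed for the male count.
#'
#' Between consecutive sampled generations the mating quota is held at the
#' male frequency realized at the start of the stretch -- the same
#' observed-male-frequency convention the inference engine uses for its
#' periods (see [simulate_period_mean_frequency()]), so the generated data
#' and the likelihood share one model.
#'
#' @param true_alpha Generating outcross fitness.
#' @param n_populations Number of replicate populations (default 3).
#' @param sample_generations Generations at which samples are taken (default
#'   `c(0, 10, 20, 30)`: three 10-generation periods, the genotyping
#'   cadence of the transition assays).
#' @param n_genotyped Individuals genotyped per time point (default 48).
#' @param n_sexed Individuals sexed per time point (default 300).
#' @param census_size Simulated census size (default `1e4`).
#' @param wt_allele_freq0,male_freq0 Starting frequencies (defaults 0.1 and
#'   0.25: a trioecious population in the early-middle of a transition, the
#'   phase in which allele counts are informative about outcross fitness
#'   across its whole [0, 2] range -- while the selfing allele is rare,
#'   trajectories at different alpha > 1 are nearly indistinguishable, and
#'   once it is common every trajectory saturates).
#' @param beta,delta Reproduction parameters ([sim_params()]).
#' @param seed Integer seed; population r uses [derive_seed()]`(seed, r)`.
#' @param out_dir Optional directory to write `trajectory.tsv` plus truth
#'   sidecar.
#' @return List with `observations` (a trajectory table, see
#'   [check_trajectory_observations()]) and `truth` (generating parameters).
#' @examples
#' d <- gen_trajectory_dataset(1.2, n_populations = 1, census_size = 500, seed = 1)
#' d$observations
#' @export
gen_trajectory_dataset <- function(true_alpha, n_populations = 3,
                                   sample_generations = c(0, 10, 20, 30),
                                   n_genotyped = 48, n_sexed = 300,
                                   census_size = 1e4,
                                   wt_allele_freq0 = 0.1, male_freq0 = 0.25,
                                   beta = 1, delta = 0, seed = 1,
                                   out_dir = NULL) {
  stopifnot(length(sample_generations) >= 1, all(sample_generations >= 0))
  sample_generations <- sort(unique(sample_generations))
  rows <- list()
  for (r in seq_len(n_populations)) {
    state <- initialize_population(census_size, wt_allele_freq0, male_freq0)
    # simulate stretch by stretch, refreshing the quota male frequency at
    # each sampled generation
    bounds <- unique(c(0, sample_generations))
    segments <- Map(c, bounds[-length(bounds)], bounds[-1])
    traj_rows <- list(cbind(generation = 0L, as.data.frame(t(state$counts))))
    for (si in seq_along(segments)) {
      seg <- segments[[si]]
      len <- seg[2] - seg[1]
      if (len == 0) next
      m_now <- sum(state$counts[1:3]) / census_size
      pars <- sim_params(
        alpha = true_alpha, census_size = census_size, n_generations = len,
        beta = beta, delta = delta, seed = derive_seed(seed, r, si)
      )
      res <- run_trajectory(pars, initial = state,
                            quota_male_freq = min(m_now, 0.5))
      if (!is.na(res$extinct_at)) {
        stop("population ", r, " lost all reproducers at generation ",
             state$generation + res$extinct_at)
      }
      cm <- res$counts[-1, , drop = FALSE]
      traj_rows[[length(traj_rows) + 1]] <-
        cbind(generation = seg[1] + seq_len(len), as.data.frame(cm))
      state <- population_state(res$counts[nrow(res$counts), ],
                                generation = seg[2])
    }
    traj <- do.call(rbind, traj_rows)
    traj$n_male <- traj$male_0 + traj$male_1 + traj$male_2
    smp <- with_seed(derive_seed(seed, r, 7919), {
      lapply(sample_generations, function(g) {
        row <- traj[traj$generation == g, ]
        # genotype 48 larvae: multivariate hypergeometric over genotype totals
        gt <- c(
          row$male_0 + row$female_0,
          row$male_1 + row$herm_1,
          row$male_2 + row$herm_2
        )
        k_het <- rhyper(1, gt[2], sum(gt) - gt[2], n_genotyped)
        k_hom <- rhyper(1, gt[3], gt[1], n_genotyped - k_het)
        males <- rhyper(1, row$n_male, sum(gt) - row$n_male, n_sexed)
        data.frame(
          population_id = paste0("SP", r),
          generation = g,
          n_individuals = n_genotyped,
          n_wt_alleles = k_het + 2 * k_hom,
          male_count = males,
          n_sexed = n_sexed
        )
      })
    })
    rows <- c(rows, smp)
  }
  obs <- do.call(rbind, rows)
  truth <- list(
    true_alpha = true_alpha, beta = beta, delta = delta,
    census_size = census_size, wt_allele_freq0 = wt_allele_freq0,
    male_freq0 = male_freq0, n_populations = n_populations,
    sample_generations = sample_generations, seed = seed
  )
  .write_synth(obs, truth, out_dir, "trajectory")
  list(observations = obs, truth = truth)
}

# Forward mating-class model of the competition assay: expected GFP-positive
# phenotype share and heterozygote share among positives, given the adult
# GFP-competitor fraction and the two male frequencies.  Shared by the
# generator; the analysis-side inverse lives in
# gfp_phenotype_to_allele_counts().
.competition_phenotype_probs <- function(a_gfp, m_wt, m_gfp) {
  a_w <- 1 - a_gfp
  o_w <- 2 * m_wt
  o_g <- 2 * m_gfp
  supply <- a_w * m_wt + a_gfp * m_gfp
  s_g <- if (supply > 0) a_gfp * m_gfp / supply else 0
  s_w <- if (supply > 0) a_w * m_wt / supply else 0
  pos <- a_gfp + a_w * o_w * s_g
  het <- a_gfp * o_g * s_w + a_w * o_w * s_g
  c(pos = pos, theta = if (pos > 0) het / pos else 0)
}

#' Generate a competition-assay dataset
#'
#' Emulates the competitive fitness assay: within each block, a reference
#' population (true `w = 0`, the lab-adapted ancestor's role) and an
#' experimental population (true `w = true_w`) are each competed against the
#' GFP tester in several replicates.  A shared block effect shifts the final
#' log allele ratio of all records in a block, so block centering is
#' required to recover `true_w`.  Final phenotype counts are drawn from the
#' heterozygote-aware mating-class model at the allele frequencies implied
#' by the record's true fitness.
#'
#' @param true_w Generating competitive fitness of the experimental
#'   population.
#' @param n_blocks Number of assay blocks (default 12).
#' @param reps_range Replicates per population per block, drawn uniformly
#'   from this range (default `c(4, 6)`).
#' @param mean_scored Mean number of larvae scored per record (default 1232,
#'   the assay's typical scoring depth; actual counts are Poisson).
#' @param setup_total L1 individuals counted at setup per record (default
#'   500, split binomially around the 50:50 target).
#' @param male_freq_wt,male_freq_gfp Assay male frequencies of the two
#'   competitors (defaults 0.05 and 0.05).
#' @param block_sd Standard deviation of the Gaussian block effects on the
#'   log allele ratio (default 0.25).
#' @param seed Integer seed.
#' @param reference_label,population_id Labels of the reference and
#'   experimental populations.
#' @param out_dir Optional output directory (`competition.tsv` + sidecar).
#' @return List with `records` (competition table) and `truth`.
#' @export
gen_competition_dataset <- function(true_w, n_blocks = 12,
                                    reps_range = c(4, 6),
                                    mean_scored = 1232, setup_total = 500,
                                    male_freq_wt = 0.05, male_freq_gfp = 0.05,
                                    block_sd = 0.25, seed = 1,
                                    reference_label = "ANC",
                                    population_id = "EXP",
                                    out_dir = NULL) {
  rows <- with_seed(derive_seed(seed, 11), {
    block_eff <- rnorm(n_blocks, 0, block_sd)
    out <- list()
    for (b in seq_len(n_blocks)) {
      for (pop in c(reference_label, population_id)) {
        w_true <- if (pop == population_id) true_w else 0
        n_rep <- sample(seq(reps_range[1], reps_range[2]), 1)
        for (rep in seq_len(n_rep)) {
          lr <- w_true + block_eff[b] # log(p_wt / p_gfp) at t1; t0 ratio = 1
          a_gfp <- 1 / (1 + exp(lr))
          ph <- .competition_phenotype_probs(a_gfp, male_freq_wt, male_freq_gfp)
          n_scored <- rpois(1, mean_scored)
          n_pos <- rbinom(1, n_scored, ph["pos"])
          s_wt <- rbinom(1, setup_total, 0.5)
          out[[length(out) + 1]] <- data.frame(
            block = paste0("B", b), population_id = pop,
            setup_wt = s_wt, setup_gfp = setup_total - s_wt,
            final_gfp_pos = n_pos, final_gfp_neg = n_scored - n_pos,
            male_freq_wt = male_freq_wt, male_freq_gfp = male_freq_gfp
          )
        }
      }
    }
    out
  })
  records <- do.call(rbind, rows)
  truth <- list(
    true_w = true_w, n_blocks = n_blocks, block_sd = block_sd,
    male_freq_wt = male_freq_wt, male_freq_gfp = male_freq_gfp,
    reference_label = reference_label, population_id = population_id,
    seed = seed
  )
  .write_synth(records, truth, out_dir, "competition")
  list(records = records, truth = truth)
}

#' Generate a SNP genotype matrix under partial selfing
#'
#' Draws unphased diploid genotypes for one population at Wright's
#' partial-selfing equilibrium inbreeding coefficient `F = S / (2 - S)`:
#' each individual's first haplotype is drawn locus by locus (with a shared
#' block-level latent variable creating gametic correlation inside
#' contiguous LD blocks), and its second haplotype copies the first with
#' probability `F`.  Missing calls are injected at random, optionally with
#' extra high-missingness loci and individuals to exercise the staged
#' cleaning filter.
#'
#' @param n_individuals Individuals genotyped (default 48).
#' @param n_loci Number of SNPs (default 58, one chromosome panel).
#' @param selfing_rate Selfing rate `S` in `[0, 1]`.
#' @param block_size Loci per contiguous LD block (default 6).
#' @param block_r Probability that a locus draw follows the block's shared
#'   latent uniform rather than an independent draw (gametic correlation
#'   knob, default 0.8).
#' @param maf_range Range of simulated reference-allele frequencies.
#' @param missing_rate Per-call missingness (default 0.03).
#' @param n_bad_loci,n_bad_individuals Number of loci / individuals given
#'   `bad_rate` missingness (default 0).
#' @param bad_rate Missingness of the degraded loci/individuals.
#' @param population Population label.
#' @param seed Integer seed.
#' @param out_dir Optional output directory (`snps.tsv` + sidecar).
#' @return List with `snps` (a [snp_matrix()]) and `truth` (including the
#'   equilibrium `snp_inbreeding_F` and the per-locus allele frequencies).
#' @export
gen_snp_dataset <- function(n_individuals = 48, n_loci = 58, selfing_rate = 0.5,
                            block_size = 6, block_r = 0.8,
                            maf_range = c(0.1, 0.5), missing_rate = 0.03,
                            n_bad_loci = 0, n_bad_individuals = 0,
                            bad_rate = 0.9, population = "P1", seed = 1,
                            out_dir = NULL) {
  check_frequency(selfing_rate)
  Fis <- selfing_rate / (2 - selfing_rate)
  res <- with_seed(derive_seed(seed, 13), {
    p <- runif(n_loci, maf_range[1], maf_range[2])
    block <- rep(seq_len(ceiling(n_loci / block_size)), each = block_size)[seq_len(n_loci)]
    draw_hap <- function() {
      u_block <- runif(max(block))
      shared <- runif(n_loci) < block_r
      u <- ifelse(shared, u_block[block], runif(n_loci))
      as.integer(u < p)
    }
    g <- matrix(NA_integer_, n_individuals, n_loci)
    for (i in seq_len(n_individuals)) {
      h1 <- draw_hap()
      h2 <- if (runif(1) < Fis) h1 else draw_hap()
      g[i, ] <- h1 + h2
    }
    g[matrix(runif(length(g)) < missing_rate, nrow(g))] <- NA
    if (n_bad_loci > 0) {
      bl <- sample(n_loci, n_bad_loci)
      g[, bl][matrix(runif(n_individuals * n_bad_loci) < bad_rate, n_individuals)] <- NA
    }
    if (n_bad_individuals > 0) {
      bi <- sample(n_individuals, n_bad_individuals)
      g[bi, ][matrix(runif(n_bad_individuals * n_loci) < bad_rate, n_bad_individuals)] <- NA
    }
    list(g = g, p = p, block = block)
  })
  colnames(res$g) <- sprintf("IV:%d", seq_len(n_loci) * 100000L)
  rownames(res$g) <- sprintf("%s_i%02d", population, seq_len(n_individuals))
  # guard against all-missing columns in extreme settings
  usable <- colSums(!is.na(res$g)) > 0
  snps <- snp_matrix(res$g[, usable, drop = FALSE],
                     rep(population, n_individuals))
  truth <- list(
    selfing_rate = selfing_rate, snp_inbreeding_F = Fis,
    allele_freqs = res$p, block = res$block, block_r = block_r,
    missing_rate = missing_rate, seed = seed
  )
  if (!is.null(out_dir)) {
    tab <- data.frame(
      individual_id = rownames(snps$genotypes),
      population = snps$population,
      snps$genotypes,
      check.names = FALSE
    )
    .write_synth(tab, truth, out_dir, "snps")
  }
  list(snps = snps, truth = truth)
}

#' Generate a male-fitness mating-plate dataset
#'
#' Progeny counts are binomial with wild-type siring probability
#' `plogis(true_w_m)`; plate sizes mimic the assay (about 17 females per
#' plate, around 100 progeny scored).  Optionally a fraction of plates is
#' made to violate each quality-control rule of
#' [qc_filter_male_plates()].
#'
#' @param true_w_m Generating male fitness (log odds of a wild-type sire).
#' @param n_plates Number of mating plates (default 20).
#' @param females_mean,females_sd Female transfer counts (Gaussian, rounded,
#'   floored at 6; defaults 16.9 and 4.2).
#' @param progeny_mean Mean progeny scored per plate (Poisson, default 100).
#' @param frac_few_females,frac_few_progeny Fractions of plates forced below
#'   the QC thresholds (defaults 0).
#' @param seed Integer seed.
#' @param out_dir Optional output directory (`male_fitness.tsv` + sidecar).
#' @return List with `records` (male-fitness table) and `truth`.
#' @export
gen_male_fitness_dataset <- function(true_w_m, n_plates = 20,
                                     females_mean = 16.9, females_sd = 4.2,
                                     progeny_mean = 100,
                                     frac_few_females = 0,
                                     frac_few_progeny = 0, seed = 1,
                                     out_dir = NULL) {
  records <- with_seed(derive_seed(seed, 17), {
    females <- pmax(round(rnorm(n_plates, females_mean, females_sd)), 6)
    progeny <- pmax(rpois(n_plates, progeny_mean), 20)
    n_ff <- round(frac_few_females * n_plates)
    n_fp <- round(frac_few_progeny * n_plates)
    if (n_ff + n_fp > n_plates) stop("QC-violation fractions exceed 1")
    bad <- sample(n_plates, n_ff + n_fp) # disjoint, so tallies are exact
    if (n_ff > 0) females[bad[seq_len(n_ff)]] <- sample(1:5, n_ff, TRUE)
    if (n_fp > 0) progeny[bad[n_ff + seq_len(n_fp)]] <- sample(1:19, n_fp, TRUE)
    p_wt <- 1 / (1 + exp(-true_w_m))
    neg <- rbinom(n_plates, progeny, p_wt)
    data.frame(
      plate = paste0("plate", seq_len(n_plates)),
      females_transferred = females,
      progeny_gfp_pos = progeny - neg,
      progeny_gfp_neg = neg
    )
  })
  truth <- list(
    true_w_m = true_w_m, n_plates = n_plates,
    frac_few_females = frac_few_females, frac_few_progeny = frac_few_progeny,
    seed = seed
  )
  .write_synth(records, truth, out_dir, "male_fitness")
  list(records = records, truth = truth)
}
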