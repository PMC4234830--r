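## TSV readers/writers for the assay-table schemas, and a small pipeline
## driver chaining the analysis stages.  TSV is the canonical dialect:
## UTF-8, tab-separated, "NA" for missing values.

.schemas <- list(
  trajectory = list(
    required = c(
      population_id = "character", generation = "integer",
      n_individuals = "integer", n_wt_alleles = "integer"
    ),
    optional = c(
      regime = "character", male_count = "integer", n_sexed = "integer"
    )
  ),
  competition = list(
    required = c(
      block = "character", population_id = "character",
      setup_wt = "integer", setup_gfp = "integer",
      final_gfp_pos = "integer", final_gfp_neg = "integer",
      male_freq_wt = "numeric", male_freq_gfp = "numeric"
    ),
    optional = c(system = "character")
  ),
  male_fitness = list(
    required = c(
      plate = "character", females_transferred = "integer",
      progeny_gfp_pos = "integer", progeny_gfp_neg = "integer"
    ),
    optional = c()
  )
)

.check_rows <- function(df, cond, what) {
  bad <- which(!cond)
  if (length(bad)) {
    stop("rows ", paste(bad, collapse = ", "), ": ", what, call. = FALSE)
  }
}

#' Read a validated assay table
#'
#' Reads a TSV file against one of the package's table schemas and validates
#' column presence, types and row-level constraints, reporting offending row
#' numbers.  Unknown columns are an error (no silent coercion); optional
#' columns may be absent.
#'
#' @param path Path to a TSV file.
#' @param schema One of `"trajectory"` (fog-2 allele counts over time),
#'   `"competition"` (GFP competition records), `"male_fitness"`
#'   (mating-plate progeny counts) or `"snp"` (genotype matrix with leading
#'   `individual_id` and `population` columns, loci coded 0/1/2/NA).
#' @return A data frame, or a [snp_matrix()] for `schema = "snp"`.
#' @export
read_table <- function(path, schema = c("trajectory", "competition",
                                        "male_fitness", "snp")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (schema == "snp") return(.read_snp_table(df, path))
  sc <- .schemas[[schema]]
  missing_cols <- setdiff(names(sc$required), names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(names(sc$required), names(sc$optional)))
  if (length(unknown)) {
    stop(path, ": unknown columns: ", paste(unknown, collapse = ", "))
  }
  types <- c(sc$required, sc$optional)
  for (col in intersect(names(types), names(df))) {
    v <- df[[col]]
    ok <- switch(types[[col]],
      character = is.character(v) | is.factor(v),
      integer = is.numeric(v) && all(v[!is.na(v)] == round(v[!is.na(v)])),
      numeric = is.numeric(v)
    )
    if (!isTRUE(ok)) stop(path, ": column ", col, " is not of type ",
                          types[[col]])
  }
  if (schema == "trajectory") {
    .check_rows(df, df$generation >= 0, "generation must be >= 0")
    .check_rows(df, df$n_individuals >= 1, "n_individuals must be >= 1")
    .check_rows(
      df, df$n_wt_alleles >= 0 & df$n_wt_alleles <= 2 * df$n_individuals,
      "n_wt_alleles must lie in [0, 2 * n_individuals]"
    )
    if (!is.null(df$male_count) && !is.null(df$n_sexed)) {
      ok <- is.na(df$male_count) | df$male_count <= df$n_sexed
      .check_rows(df, ok, "male_count must not exceed n_sexed")
    }
  } else if (schema == "competition") {
    cnt <- c("setup_wt", "setup_gfp", "final_gfp_pos", "final_gfp_neg")
    for (col in cnt) .check_rows(df, df[[col]] >= 0, paste(col, "must be >= 0"))
    .check_rows(df, df$final_gfp_pos + df$final_gfp_neg > 0,
                "no scored larvae")
    for (col in c("male_freq_wt", "male_freq_gfp")) {
      .check_rows(df, df[[col]] >= 0 & df[[col]] <= 0.5,
                  paste(col, "must lie in [0, 0.5]"))
    }
  } else if (schema == "male_fitness") {
    .check_rows(df, df$females_transferred >= 0,
                "females_transferred must be >= 0")
    .check_rows(df, df$progeny_gfp_pos >= 0 & df$progeny_gfp_neg >= 0,
                "progeny counts must be >= 0")
  }
  df
}

.read_snp_table <- function(df, path) {
  lead <- c("individual_id", "population")
  if (!all(lead %in% names(df)[1:2])) {
    stop(path, ": SNP tables start with columns individual_id, population")
  }
  loci <- setdiff(names(df), lead)
  if (!length(loci)) stop(path, ": no locus columns")
  g <- as.matrix(df[loci])
  mode(g) <- "integer"
  invalid <- matrix(!(g %in% c(0L, 1L, 2L, NA)), nrow(g))
  bad <- which(invalid, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(
      path, ": invalid genotype codes at rows ",
      paste(unique(bad[, 1]), collapse = ", ")
    )
  }
  rownames(g) <- df$individual_id
  snp_matrix(g, df$population)
}

#' Write a table as canonical TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the analysis pipeline on synthetic data
#'
#' Chains the package's stages in dependency order -- generate synthetic
#' tables, infer alpha from the trajectory table, estimate competitive and
#' male fitness, summarise SNP diversity -- and writes every output plus the
#' fully resolved configuration to `out_dir`, so a run can be reproduced
#' from its artifacts alone.
#'
#' @param config Named list; recognised entries (all optional except
#'   `seed`): `seed` (integer), `true_alpha`, `census_size`,
#'   `grid` (alpha grid), `n_reps`, `ci_drop`, `trajectory`, `competition`,
#'   `male_fitness`, `snp` (lists of extra arguments passed to the
#'   respective generators), `stages` (character subset of
#'   `c("alpha", "fitness", "diversity")`).
#' @param out_dir Output directory (created if needed).
#' @return Named list of result objects, invisibly; artifacts are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed)) stop("config must contain a `seed`")
  stages <- config$stages %||% c("alpha", "fitness", "diversity")
  unknown <- setdiff(stages, c("alpha", "fitness", "diversity"))
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  if (!is.null(config$grid) && length(config$grid) < 2) {
    stop("config$grid must have >= 2 points")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  if ("alpha" %in% stages) {
    targs <- modifyList(
      list(
        true_alpha = config$true_alpha %||% 1.4,
        census_size = config$census_size %||% 2000,
        seed = derive_seed(seed, 1), out_dir = out_dir
      ),
      config$trajectory %||% list()
    )
    synth <- do.call(gen_trajectory_dataset, targs)
    fit <- grid_likelihood_search(
      synth$observations,
      census_size = targs$census_size,
      grid = config$grid %||% seq(0, 2, length.out = 51),
      n_reps = config$n_reps %||% 20,
      ci_drop = config$ci_drop %||% 3.84,
      seed = derive_seed(seed, 2)
    )
    write_table(fit$grid, file.path(out_dir, "alpha_grid.tsv"))
    jsonlite::write_json(
      fit[c("ml_alpha", "ci_lower", "ci_upper", "boundary_ml", "tie")],
      file.path(out_dir, "alpha_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    results$alpha <- fit
  }
  if ("fitness" %in% stages) {
    cargs <- modifyList(
      list(true_w = 0.5, seed = derive_seed(seed, 3), out_dir = out_dir),
      config$competition %||% list()
    )
    comp <- do.call(gen_competition_dataset, cargs)
    est <- competition_fitness(comp$records)
    est <- block_center_and_delta(est, comp$truth$reference_label)
    write_table(est, file.path(out_dir, "competition_fitness.tsv"))
    results$competition <- est
    margs <- modifyList(
      list(true_w_m = 1, seed = derive_seed(seed, 4), out_dir = out_dir),
      config$male_fitness %||% list()
    )
    mf <- do.call(gen_male_fitness_dataset, margs)
    wm <- male_fitness(mf$records)
    write_table(wm, file.path(out_dir, "male_fitness_estimates.tsv"))
    results$male_fitness <- wm
  }
  if ("diversity" %in% stages) {
    sargs <- modifyList(
      list(seed = derive_seed(seed, 5), out_dir = out_dir),
      config$snp %||% list()
    )
    snp <- do.call(gen_snp_dataset, sargs)
    div <- diversity_summary(clean_snp_matrix(snp$snps))
    write_table(div, file.path(out_dir, "diversity_summary.tsv"))
    results$diversity <- div
  }
  resolved <- config
  resolved$stages <- stages
  resolved$package_version <- as.character(utils::packageVersion("trioecy"))
  jsonlite::write_json(resolved, file.path(out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
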