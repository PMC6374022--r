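#' Simulation configuration for synthetic EHR cohorts
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The generator emulates the structure the downstream analysis assumes: a
#' sparse binary individual-by-phecode matrix arising from `n_topics` latent
#' nonnegative disease topics, a Hardy-Weinberg single-SNP genotype, and an
#' additive planted genotype effect on one topic's individual loading.
#'
#' Defaults are sized for a desk-scale analogue of a biobank EHR cohort:
#' 3000 individuals, 400 phecodes, 6 topics with disjoint 10-phecode cores,
#' minor allele frequency 0.077, an additive loading shift of 0.8 per minor
#' allele on topic 1, age centred at 70.3 (SD 12.3) years truncated at 18,
#' and 52.8% females.
#'
#' @param n_individuals Number of individuals (rows).
#' @param n_phecodes Number of phecodes (columns).
#' @param n_topics Number of latent topics.
#' @param maf Minor allele frequency in `[0, 0.5]`.
#' @param effect_beta Nonnegative additive shift of the target topic's
#'   loading per copy of the minor allele.
#' @param target_topic Index (1-based) of the topic carrying the planted
#'   effect.
#' @param core_size Number of high-weight core phecodes per topic; cores are
#'   pairwise disjoint.
#' @param core_weight,background_weight Topic-phenotype weights inside and
#'   outside a topic's core; `core_weight > background_weight >= 0`.
#' @param loading_shape Gamma shape of the baseline individual-topic
#'   loadings (scale 1).
#' @param age_mean,age_sd Age distribution in years (normal, truncated at
#'   18).
#' @param sex_prob Probability of sex code 1 (female).
#' @param confound_age_sex If `TRUE`, genotype carriers receive an age/sex
#'   shift so covariate adjustment has something to adjust for; default
#'   keeps age and sex independent of genotype.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_phecodes = 60, n_topics = 3)
#' cfg$maf
sim_config <- function(n_individuals = 3000,
                       n_phecodes = 400,
                       n_topics = 6,
                       maf = 0.077,
                       effect_beta = 0.8,
                       target_topic = 1,
                       core_size = 10,
                       core_weight = 1.0,
                       background_weight = 0.01,
                       loading_shape = 0.5,
                       age_mean = 70.3,
                       age_sd = 12.3,
                       sex_prob = 0.528,
                       confound_age_sex = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_phecodes = as.integer(n_phecodes),
    n_topics = as.integer(n_topics),
    maf = maf,
    effect_beta = effect_beta,
    target_topic = as.integer(target_topic),
    core_size = as.integer(core_size),
    core_weight = core_weight,
    background_weight = background_weight,
    loading_shape = loading_shape,
    age_mean = age_mean,
    age_sd = age_sd,
    sex_prob = sex_prob,
    confound_age_sex = isTRUE(confound_age_sex),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_individuals", "n_phecodes", "n_topics", "core_size")) {
    if (cfg[[f]] < 1L) stop_domain("`%s` must be >= 1", f)
  }
  if (cfg$maf < 0 || cfg$maf > 0.5) stop_domain("`maf` must lie in [0, 0.5]")
  if (cfg$effect_beta < 0) stop_domain("`effect_beta` must be nonnegative")
  if (cfg$target_topic < 1L || cfg$target_topic > cfg$n_topics) {
    stop_domain("`target_topic` must index one of the %d topics", cfg$n_topics)
  }
  if (!(cfg$core_weight > cfg$background_weight) || cfg$background_weight < 0) {
    stop_domain("need core_weight > background_weight >= 0")
  }
  if (cfg$n_topics * cfg$core_size > cfg$n_phecodes) {
    stop_domain(
      "disjoint cores need n_topics * core_size <= n_phecodes (%d * %d > %d)",
      cfg$n_topics, cfg$core_size, cfg$n_phecodes
    )
  }
  if (cfg$loading_shape <= 0) stop_domain("`loading_shape` must be > 0")
  if (cfg$sex_prob < 0 || cfg$sex_prob > 1) stop_domain("`sex_prob` must lie in [0, 1]")
  if (cfg$age_sd <= 0) stop_domain("`age_sd` must be > 0")
  invisible(cfg)
}

#' Simulate single-SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws minor-allele counts in `{0, 1, 2}` with genotype probabilities
#' `((1-q)^2, 2q(1-q), q^2)` for minor allele frequency `q`.
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return Integer vector of length `n` over `{0, 1, 2}`.
#' @export
#' @examples
#' g <- simulate_genotypes(1000, maf = 0.077, seed = 7)
#' compute_maf(g)
simulate_genotypes <- function(n, maf, seed = 1L) {
  if (n < 1) stop_domain("`n` must be >= 1")
  if (!is.numeric(maf) || maf < 0 || maf > 0.5) {
    stop_domain("`maf` must lie in [0, 0.5]")
  }
  # Sum of two independent allele draws == HWE genotype distribution.
  with_local_seed(seed, rbinom(n, size = 2L, prob = maf))
}

#' Simulate latent topic structure
#'
#' Builds the ground-truth factor pair: `H_true` has one disjoint block of
#' `core_size` phecodes at `core_weight` per topic and `background_weight`
#' elsewhere; `W_true` entries are i.i.d. Gamma(`loading_shape`, scale 1).
#'
#' @param config A [sim_config()].
#' @return List with nonnegative matrices `W_true` (n x k) and `H_true`
#'   (k x m), dimnames set to individual/phecode/topic labels.
#' @export
simulate_topics <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  m <- config$n_phecodes
  k <- config$n_topics
  H <- matrix(config$background_weight, nrow = k, ncol = m)
  for (t in seq_len(k)) {
    core <- ((t - 1L) * config$core_size + 1L):(t * config$core_size)
    H[t, core] <- config$core_weight
  }
  W <- with_local_seed(
    config$seed,
    matrix(rgamma(n * k, shape = config$loading_shape, scale = 1), nrow = n)
  )
  dimnames(W) <- list(individual_labels(n), topic_labels(k))
  dimnames(H) <- list(topic_labels(k), phecode_labels(m))
  list(W_true = W, H_true = H)
}

individual_labels <- function(n) sprintf("ind_%05d", seq_len(n))
phecode_labels <- function(m) sprintf("%06.1f", seq_len(m) + 99.5)
topic_labels <- function(k) sprintf("topic_%d", seq_len(k) - 1L)

#' Plant an additive genotype effect on one topic's loadings
#'
#' Shifts the target topic's column of the true loading matrix by
#' `effect_beta` per copy of the minor allele:
#' `W'[i, t] = W[i, t] + effect_beta * g[i]`. This is the linear signal the
#' Pearson correlation test downstream is designed to detect.
#'
#' @param W_true Nonnegative loading matrix (n x k).
#' @param genotype Allele counts in `{0, 1, 2}`, length n.
#' @param target_topic Column index to shift.
#' @param effect_beta Loading shift per allele. A negative value is allowed
#'   but loadings are clamped at zero (with a warning) to keep `W`
#'   nonnegative.
#' @return Modified loading matrix.
#' @export
plant_effect <- function(W_true, genotype, target_topic, effect_beta) {
  if (length(genotype) != nrow(W_true)) {
    stop_domain("genotype length (%d) != rows of W_true (%d)",
                length(genotype), nrow(W_true))
  }
  if (target_topic < 1 || target_topic > ncol(W_true)) {
    stop_domain("`target_topic` out of range")
  }
  W <- W_true
  shifted <- W[, target_topic] + effect_beta * genotype
  if (any(shifted < 0)) {
    warning("planted effect drove ", sum(shifted < 0),
            " loadings negative; clamped at 0")
    shifted <- pmax(shifted, 0)
  }
  W[, target_topic] <- shifted
  W
}

#' Sample a binary phenotype matrix from latent intensities
#'
#' Given nonnegative factors, draws independent Bernoulli phenotype labels
#' with `P(X_ij = 1) = 1 - exp(-(W H)_ij)`. The complementary-log link maps
#' any nonnegative intensity smoothly into `[0, 1)` and is monotone in the
#' intensity, so stronger topic membership means higher phecode probability
#' with no clipping artifacts.
#'
#' @param W_true,H_true Nonnegative factor matrices.
#' @param seed Integer seed.
#' @return A [phenotype_matrix] with sparse binary entries.
#' @export
sample_phenotypes <- function(W_true, H_true, seed = 1L) {
  if (ncol(W_true) != nrow(H_true)) stop_domain("factor shapes do not conform")
  if (any(W_true < 0) || any(H_true < 0)) {
    stop_domain("factors must be nonnegative")
  }
  intensity <- W_true %*% H_true
  p <- 1 - exp(-intensity)
  draws <- with_local_seed(
    seed,
    matrix(rbinom(length(p), 1L, p), nrow = nrow(p))
  )
  ids <- rownames(W_true) %||% individual_labels(nrow(W_true))
  codes <- colnames(H_true) %||% phecode_labels(ncol(H_true))
  phenotype_matrix(
    Matrix::Matrix(draws, sparse = TRUE),
    individual_ids = ids,
    phecodes = codes
  )
}

#' Simulate a complete synthetic cohort
#'
#' Composes [simulate_topics()], [plant_effect()], [simulate_genotypes()] and
#' [sample_phenotypes()] with independent age (normal, truncated at 18
#' years) and sex (Bernoulli) covariates. Deterministic given the
#' configuration, including its seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with the
#'   [phenotype_matrix] `X`, integer `genotype`, numeric `age`, integer
#'   `sex`, ground-truth `W_true` / `H_true` (post planted effect / as
#'   generated), the planted `core_sets` (list of phecode label vectors,
#'   one per topic), and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 150, n_phecodes = 60,
#'                                   n_topics = 3, core_size = 5, seed = 42))
#' dim(coh$X$X)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 5L)
  topics <- simulate_topics(config)
  g <- simulate_genotypes(config$n_individuals, config$maf, seed = seeds[1])
  W <- plant_effect(topics$W_true, g, config$target_topic, config$effect_beta)
  X <- sample_phenotypes(W, topics$H_true, seed = seeds[2])
  age <- with_local_seed(seeds[3], rtruncnorm_18(
    config$n_individuals, config$age_mean, config$age_sd
  ))
  sex <- with_local_seed(seeds[4], rbinom(config$n_individuals, 1L, config$sex_prob))
  if (config$confound_age_sex) {
    # Carriers skew older and more often sex==1: gives the logistic
    # adjustment a real confounder to absorb in tests.
    age <- age + 5 * (g >= 1)
    flip <- with_local_seed(seeds[5], rbinom(config$n_individuals, 1L, 0.25))
    sex <- ifelse(g >= 1 & flip == 1L, 1L, sex)
  }
  core_sets <- lapply(seq_len(config$n_topics), function(t) {
    colnames(topics$H_true)[((t - 1L) * config$core_size + 1L):(t * config$core_size)]
  })
  structure(
    list(
      X = X, genotype = as.integer(g), age = age, sex = as.integer(sex),
      W_true = W, H_true = topics$H_true, core_sets = core_sets,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

# Normal truncated below at 18 by rejection; at the default (70.3, 12.3) the
# truncated mass is ~1e-5 so this resamples almost never.
rtruncnorm_18 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < 18)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 18]
  }
  x
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_cohort> %d individuals x %d phecodes, %d topics (core %d)\n",
    cfg$n_individuals, cfg$n_phecodes, cfg$n_topics, cfg$core_size
  ))
  cat(sprintf("  maf %.3f, effect_beta %.2f on topic %d, seed %d\n",
              cfg$maf, cfg$effect_beta, cfg$target_topic, cfg$seed))
  cat(sprintf("  phenotype density %.3f\n", Matrix::mean(x$X$X)))
  invisible(x)
}

#' Tidy covariate table of a synthetic cohort
#'
#' @param x A `synthetic_cohort`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `individual_id`, `g`,
#'   `age`, `sex`.
#' @method tidy synthetic_cohort
#' @export
tidy.synthetic_cohort <- function(x, ...) {
  tibble(
    individual_id = x$X$individual_ids,
    g = x$genotype,
    age = x$age,
    sex = x$sex
  )
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Writes the phenotype matrix as MatrixMarket plus label TSVs (see
#' [write_phenotype_matrix()]), covariates as `covariates.tsv`
#' (`individual_id`, `g`, `age`, `sex`), ground-truth factors as TSV and the
#' configuration as `config.yaml`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write_cohort`); a `synthetic_cohort` without
#'   ground-truth factors is not supported -- `read_cohort` restores the
#'   full object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotype_matrix(cohort$X, dir)
  readr::write_tsv(tidy(cohort), file.path(dir, "covariates.tsv"))
  write_labeled_matrix(cohort$W_true, file.path(dir, "W_true.tsv"))
  write_labeled_matrix(cohort$H_true, file.path(dir, "H_true.tsv"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(sim_config, cfg_raw)
  X <- read_phenotype_matrix(dir)
  cov <- readr::read_tsv(file.path(dir, "covariates.tsv"),
                         show_col_types = FALSE)
  W <- read_labeled_matrix(file.path(dir, "W_true.tsv"))
  H <- read_labeled_matrix(file.path(dir, "H_true.tsv"))
  core_sets <- lapply(seq_len(config$n_topics), function(t) {
    colnames(H)[((t - 1L) * config$core_size + 1L):(t * config$core_size)]
  })
  structure(
    list(X = X, genotype = as.integer(cov$g), age = cov$age,
         sex = as.integer(cov$sex), W_true = W, H_true = H,
         core_sets = core_sets, config = config),
    class = "synthetic_cohort"
  )
}

write_labeled_matrix <- function(M, path) {
  df <- as.data.frame(M)
  df <- cbind(.row = rownames(M) %||% as.character(seq_len(nrow(M))), df)
  readr::write_tsv(tibble::as_tibble(df), path)
}

read_labeled_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
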