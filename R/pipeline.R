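#' Validate a run configuration file
#'
#' Reads a YAML run configuration and reports *all* schema violations at
#' once. Recognized top-level keys: `simulation` (passed to [sim_config()];
#' optional if `matrix_dir` is given), `matrix_dir`, `nmf` (`k`, `lam`,
#' `gamma`, `max_iter`, `tol`, `seed`, `init`), `descriptor_size`,
#' `association` (`joint`), `phewas` (`alpha`, `min_cases`), `scree_k_max`,
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`, or an error of class
#'   `genotopics_config_error` whose message lists every violation.
#' @export
validate_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  errors <- character()
  note <- function(msg, ...) errors <<- c(errors, sprintf(msg, ...))

  nmf <- raw$nmf %||% list()
  nmf$k <- nmf$k %||% 6L
  nmf$lam <- nmf$lam %||% 0.2
  nmf$gamma <- nmf$gamma %||% 0.5
  nmf$max_iter <- nmf$max_iter %||% 500L
  nmf$tol <- nmf$tol %||% 1e-6
  nmf$seed <- nmf$seed %||% 1L
  nmf$init <- nmf$init %||% "random"
  if (!is.numeric(nmf$k) || nmf$k < 1) note("nmf.k must be a count >= 1")
  if (!is.numeric(nmf$lam) || nmf$lam < 0) note("nmf.lam must be >= 0")
  if (!is.numeric(nmf$gamma) || nmf$gamma < 0 || nmf$gamma > 1) {
    note("nmf.gamma must lie in [0,1]")
  }
  if (!is.numeric(nmf$tol) || nmf$tol <= 0) note("nmf.tol must be > 0")
  if (!nmf$init %in% c("random", "nndsvd")) {
    note("nmf.init must be 'random' or 'nndsvd'")
  }

  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- tryCatch(do.call(sim_config, raw$simulation),
                    error = function(e) { note(conditionMessage(e)); NULL })
  } else if (is.null(raw$matrix_dir)) {
    note("need either a `simulation` block or a `matrix_dir`")
  }
  if (!is.null(raw$matrix_dir) && !dir.exists(raw$matrix_dir)) {
    note("matrix_dir does not exist: %s", raw$matrix_dir)
  }

  t <- raw$descriptor_size %||% 10L
  if (!is.numeric(t) || t < 1) note("descriptor_size must be a count >= 1")
  ph <- raw$phewas %||% list()
  ph$alpha <- ph$alpha %||% 0.05
  ph$min_cases <- ph$min_cases %||% 20L
  if (ph$alpha <= 0 || ph$alpha >= 1) note("phewas.alpha must lie in (0,1)")
  assoc <- raw$association %||% list()
  assoc$joint <- assoc$joint %||% TRUE

  if (length(errors)) {
    rlang::abort(paste0("invalid run config:\n",
                        paste("-", errors, collapse = "\n")),
                 class = "genotopics_config_error")
  }
  structure(
    list(simulation = sim, matrix_dir = raw$matrix_dir, nmf = nmf,
         descriptor_size = as.integer(t), association = assoc, phewas = ph,
         scree_k_max = raw$scree_k_max %||% 20L,
         out_dir = raw$out_dir),
    class = "run_config"
  )
}

#' Run the full synthetic reproduction pipeline
#'
#' Orchestrates simulate (or load) -> scree -> NMF fit -> descriptor /
#' dependency / coherence evaluation -> genotype-topic association ->
#' conventional PheWAS, writing every stage's output as TSV into `out_dir`
#' together with the exact configuration that produced it. Deterministic
#' given the seeds in the configuration.
#'
#' @param config A `run_config` (from [validate_run_config()]) or the path
#'   to a YAML file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list of class `run_summary` with elements `scree`,
#'   `model`, `descriptors`, `dependency`, `coherence`, `association`,
#'   `phewas`, `assignments`, and (for synthetic input) `recovery` (matched
#'   descriptor-vs-core Jaccard) -- plus `out_dir`.
#' @export
run_end_to_end <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop_domain("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                   parent = e)
    })
  }

  cohort <- NULL
  if (!is.null(config$simulation)) {
    cohort <- stage("simulate", simulate_cohort(config$simulation))
    X <- cohort$X
    g <- cohort$genotype; age <- cohort$age; sex <- cohort$sex
    stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))
  } else {
    X <- stage("load", read_phenotype_matrix(config$matrix_dir))
    cov_path <- file.path(config$matrix_dir, "covariates.tsv")
    if (file.exists(cov_path)) {
      cov <- readr::read_tsv(cov_path, show_col_types = FALSE)
      g <- cov$g; age <- cov$age; sex <- cov$sex
    } else {
      g <- NULL
    }
  }

  sc <- stage("scree", scree(X, k_max = min(config$scree_k_max, min(dim(X)))))
  readr::write_tsv(sc, file.path(out_dir, "scree.tsv"))

  nc <- config$nmf
  model <- stage("fit", fit_nmf(X, k = nc$k, lam = nc$lam, gamma = nc$gamma,
                                max_iter = nc$max_iter, tol = nc$tol,
                                seed = nc$seed, init = nc$init))
  write_topic_model(model, file.path(out_dir, "model"))

  t <- config$descriptor_size
  desc <- stage("evaluate", top_descriptors(model, t = t))
  readr::write_tsv(desc, file.path(out_dir, "descriptors.tsv"))
  dep <- stage("evaluate", topic_dependency(desc))
  coh <- stage("evaluate", suppressWarnings(topic_coherence(desc, X)))
  readr::write_tsv(coh, file.path(out_dir, "coherence.tsv"))
  assign <- stage("evaluate", assign_topics(model))
  readr::write_tsv(attr(assign, "prevalence"),
                   file.path(out_dir, "topic_prevalence.tsv"))

  assoc <- NULL; ph <- NULL
  if (!is.null(g)) {
    assoc <- stage("associate",
                   topic_association(model, g, age, sex,
                                     joint = config$association$joint))
    readr::write_tsv(assoc$pcc, file.path(out_dir, "association_pcc.tsv"))
    readr::write_tsv(assoc$lr, file.path(out_dir, "association_lr.tsv"))
    ph <- stage("phewas", phewas(X, g, age, sex,
                                 alpha = config$phewas$alpha,
                                 min_cases = config$phewas$min_cases))
    readr::write_tsv(ph, file.path(out_dir, "phewas.tsv"))
  } else {
    message("no genotype data: association and PheWAS stages skipped")
  }

  recovery <- NULL
  if (!is.null(cohort)) {
    recovery <- stage("evaluate", descriptor_core_recovery(desc, cohort))
  }

  summary <- list(
    scree = sc, model = model, descriptors = desc, dependency = dep,
    coherence = coh, association = assoc, phewas = ph,
    assignments = assign, recovery = recovery, out_dir = out_dir
  )
  writeLines(yaml::as.yaml(list(
    nmf = model$config,
    descriptor_size = t,
    dependency = dep,
    mean_coherence = attr(coh, "mean_coherence"),
    recovery_jaccard = recovery,
    n_iter = model$n_iter,
    final_objective = tail(model$objective_trace, 1)
  )), file.path(out_dir, "summary.yaml"))
  class(summary) <- "run_summary"
  invisible(summary)
}

#' Matched Jaccard between fitted descriptors and planted topic cores
#'
#' Hungarian-matched mean Jaccard similarity between a fitted model's
#' descriptor sets and the ground-truth core phecode sets of a synthetic
#' cohort -- the recovery score used to judge whether the factorization
#' found the planted structure.
#'
#' @param desc A [top_descriptors()] table (use `t = core_size`).
#' @param cohort A `synthetic_cohort`.
#' @return Scalar in `[0, 1]`.
#' @export
descriptor_core_recovery <- function(desc, cohort) {
  core_desc <- purrr::imap(cohort$core_sets, function(codes, i) {
    tibble(topic = paste0("core_", i), rank = seq_along(codes),
           phecode = codes, weight = NA_real_, degenerate = FALSE)
  }) |> purrr::list_rbind()
  topic_agreement(desc, core_desc)$agreement
}

#' Write / read a fitted topic model as TSV + YAML
#'
#' @param model A `topic_model`.
#' @param dir Output directory.
#' @return `dir` invisibly; `read_topic_model` returns the restored model.
#' @export
write_topic_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(model$W, file.path(dir, "W.tsv"))
  write_labeled_matrix(model$H, file.path(dir, "H.tsv"))
  readr::write_tsv(
    tibble(iteration = seq_along(model$objective_trace) - 1L,
           objective = model$objective_trace),
    file.path(dir, "objective_trace.tsv")
  )
  yaml::write_yaml(c(model$config,
                     list(converged = model$converged, n_iter = model$n_iter)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  trace <- readr::read_tsv(file.path(dir, "objective_trace.tsv"),
                           show_col_types = FALSE)
  structure(
    list(W = read_labeled_matrix(file.path(dir, "W.tsv")),
         H = read_labeled_matrix(file.path(dir, "H.tsv")),
         config = cfg[c("k", "lam", "gamma", "max_iter", "tol", "seed", "init")],
         objective_trace = trace$objective,
         converged = cfg$converged, n_iter = cfg$n_iter),
    class = "topic_model"
  )
}
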