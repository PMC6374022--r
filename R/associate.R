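#' Minor allele frequency of a genotype vector
#'
#' `MAF = (#heterozygotes + 2 * #homozygous minor) / (2n)` for allele
#' counts in `{0, 1, 2}`. Warns if the computed frequency exceeds 0.5,
#' i.e. the "minor" allele is actually the major one.
#'
#' @param g Integer allele counts in `{0, 1, 2}` (named or not; order
#'   irrelevant).
#' @return Frequency in `[0, 1]`.
#' @export
#' @examples
#' compute_maf(c(0, 0, 1, 2))
compute_maf <- function(g) {
  if (length(g) == 0L) stop_domain("empty genotype vector")
  if (anyNA(g) || !all(g %in% c(0, 1, 2))) {
    stop_domain("genotypes must be allele counts in {0, 1, 2}")
  }
  maf <- sum(g) / (2 * length(g))
  if (maf > 0.5) warning("allele frequency ", signif(maf, 3),
                         " > 0.5: coded allele is the major allele")
  maf
}

#' Pearson correlation test between a topic loading and allele counts
#'
#' Two-sided test of zero correlation: `r` is the sample Pearson
#' correlation and the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x Numeric vector (e.g. one column of the loading matrix `W`).
#' @param y Numeric vector of the same length (e.g. allele counts).
#' @return List with elements `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y differ in length")
  if (length(x) < 3L) stop_domain("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("zero variance: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Logistic regression with Wald tests
#'
#' Maximum-likelihood logistic fit of a binary outcome on the given
#' predictor columns (intercept prepended), with Wald z-tests per
#' coefficient. Perfect separation is reported via `converged = FALSE`
#' and a warning rather than an error.
#'
#' @param y Binary outcome in `{0, 1}`.
#' @param predictors Data frame or matrix of predictor columns (no
#'   intercept; one is added).
#' @return A tibble of class `logistic_fit`: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`; attributes `converged`,
#'   `loglik`, `n`.
#' @export
logistic_fit <- function(y, predictors) {
  if (!all(y %in% c(0, 1))) stop_domain("outcome must be binary 0/1")
  Xd <- as.data.frame(predictors)
  if (nrow(Xd) != length(y)) stop_domain("outcome/predictor length mismatch")
  qrX <- qr(cbind(1, as.matrix(Xd)))
  if (qrX$rank < ncol(Xd) + 1L) stop_domain("singular design (collinear predictors)")
  dat <- cbind(.y = y, Xd)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep) warning("possible complete separation; estimates unreliable")
  sm <- summary(fit)$coefficients
  out <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
  attr(out, "converged") <- fit$converged && !sep
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "n") <- length(y)
  class(out) <- c("logistic_fit", class(out))
  out
}

# Reorder a per-individual vector (or tibble with individual_id) to match
# the model's row order; plain unnamed vectors are taken as already aligned.
align_to <- function(v, ids, what) {
  if (is.data.frame(v)) {
    if (!"individual_id" %in% names(v)) {
      stop_domain("%s table needs an `individual_id` column", what)
    }
    val_col <- setdiff(names(v), "individual_id")[1]
    v <- setNames(v[[val_col]], v$individual_id)
  }
  if (!is.null(names(v))) {
    missing <- setdiff(ids, names(v))
    if (length(missing)) {
      stop_domain("%s lacks individual(s): %s", what,
                  paste(head(missing, 5), collapse = ", "))
    }
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stop_domain("%s length (%d) != number of individuals (%d)",
                what, length(v), length(ids))
  }
  unname(v)
}

#' Test each topic's loading against genotype
#'
#' Two complementary analyses on the individual-topic matrix `W`:
#' \itemize{
#'   \item Pearson correlation of each topic column with the allele count
#'     (one test per topic).
#'   \item One joint logistic regression of carrier status (allele count
#'     >= 1) on all topic columns together, adjusted for age and sex
#'     (set `joint = FALSE` for one marginal adjusted model per topic).
#' }
#'
#' @param model A `topic_model`.
#' @param g Allele counts in `{0, 1, 2}` (vector aligned to the model rows,
#'   named vector, or tibble with `individual_id`).
#' @param age,sex Covariates, aligned like `g`.
#' @param joint Fit all topics in one logistic model (default) or
#'   marginally.
#' @return Object of class `topic_association`: list with tibbles `pcc`
#'   (`topic`, `r`, `p`) and `lr` (`term`, `estimate`, `std_error`,
#'   `p_value`), plus `maf`, `n`, `joint`.
#' @export
topic_association <- function(model, g, age, sex, joint = TRUE) {
  ids <- rownames(model$W)
  g <- align_to(g, ids, "genotype")
  age <- align_to(age, ids, "age")
  sex <- align_to(sex, ids, "sex")
  W <- model$W
  topics <- colnames(W)
  pcc <- purrr::map(seq_along(topics), function(j) {
    ct <- pearson_test(W[, j], g)
    tibble(topic = topics[j], r = ct$r, p = ct$p)
  }) |> purrr::list_rbind()
  carrier <- as.integer(g >= 1)
  if (joint) {
    preds <- data.frame(age = age, sex = sex, W)
    lr <- logistic_fit(carrier, preds) |>
      filter(.data$term != "(Intercept)")
  } else {
    lr <- purrr::map(seq_along(topics), function(j) {
      preds <- data.frame(age = age, sex = sex, topic = W[, j])
      fit <- logistic_fit(carrier, preds)
      fit |>
        filter(.data$term == "topic") |>
        mutate(term = topics[j])
    }) |> purrr::list_rbind()
  }
  structure(
    list(pcc = pcc, lr = select(lr, "term", "estimate", "std_error", "p_value"),
         maf = compute_maf(g), n = length(g), joint = joint),
    class = "topic_association"
  )
}

#' @export
print.topic_association <- function(x, ...) {
  cat(sprintf("<topic_association> n = %d, MAF = %.3f (%s logistic model)\n",
              x$n, x$maf, if (x$joint) "joint" else "marginal"))
  cat("Pearson correlation per topic:\n")
  print(as.data.frame(x$pcc), row.names = FALSE)
  cat("Logistic regression (carrier ~ topics + age + sex):\n")
  print(as.data.frame(x$lr), row.names = FALSE)
  invisible(x)
}

#' Conventional PheWAS against a single SNP
#'
#' One logistic regression per phecode: outcome = phecode presence,
#' predictors = allele count + age + sex. Phecodes with fewer cases than
#' `min_cases` are skipped (reported with `tested = FALSE`) to avoid
#' unstable fits. The Bonferroni threshold is `alpha` divided by the number
#' of phecodes actually tested.
#'
#' @param X A [phenotype_matrix].
#' @param g,age,sex Per-individual genotype and covariates (vector, named
#'   vector or tibble with `individual_id`).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param min_cases Minimum number of cases for a phecode to be tested.
#' @return A tibble of class `phewas_result`: `phecode`, `n_cases`,
#'   `estimate`, `std_error`, `p_value`, `tested`; attributes
#'   `bonferroni` (threshold), `n_tested`, `alpha`.
#' @export
phewas <- function(X, g, age, sex, alpha = 0.05, min_cases = 20) {
  pm <- if (inherits(X, "phenotype_matrix")) X else
    phenotype_matrix(X, rownames(X), colnames(X))
  ids <- pm$individual_ids
  g <- align_to(g, ids, "genotype")
  age <- align_to(age, ids, "age")
  sex <- align_to(sex, ids, "sex")
  design <- cbind(`(Intercept)` = 1, g = g, age = age, sex = sex)
  Xs <- pm$X
  cases <- Matrix::colSums(Xs)
  rows <- purrr::map(seq_along(pm$phecodes), function(j) {
    base <- tibble(phecode = pm$phecodes[j], n_cases = as.integer(cases[j]),
                   estimate = NA_real_, std_error = NA_real_,
                   p_value = NA_real_, tested = FALSE)
    if (cases[j] < min_cases || cases[j] > length(ids) - min_cases) return(base)
    res <- tryCatch({
      y <- as.numeric(Xs[, j])
      fit <- suppressWarnings(
        glm.fit(design, y, family = binomial(), control = list(maxit = 50))
      )
      cf <- wald_from_glmfit(fit)
      base |>
        mutate(estimate = cf["g", "estimate"],
               std_error = cf["g", "std_error"],
               p_value = cf["g", "p_value"],
               tested = TRUE)
    }, error = function(e) base)
    res
  }) |> purrr::list_rbind()
  n_tested <- sum(rows$tested)
  attr(rows, "bonferroni") <- if (n_tested > 0) alpha / n_tested else NA_real_
  attr(rows, "n_tested") <- n_tested
  attr(rows, "alpha") <- alpha
  class(rows) <- c("phewas_result", class(rows))
  rows
}

#' @importFrom stats glm.fit
wald_from_glmfit <- function(fit) {
  # Wald z-tests from a glm.fit object: SEs from the inverse Fisher
  # information of the final IRLS weighted least squares.
  qr_ <- fit$qr
  cov_unscaled <- chol2inv(qr_$qr[seq_len(qr_$rank), seq_len(qr_$rank), drop = FALSE])
  se <- sqrt(diag(cov_unscaled))
  est <- fit$coefficients[qr_$pivot[seq_len(qr_$rank)]]
  z <- est / se
  out <- cbind(estimate = est, std_error = se, p_value = 2 * pnorm(-abs(z)))
  rownames(out) <- names(est)
  out
}
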