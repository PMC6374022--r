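#' Elastic-net regularized NMF objective
#'
#' The fitted criterion is
#' \deqn{\|X - WH\|_F^2 + \lambda\left[\gamma(\|W\|_1 + \|H\|_1) +
#'   \tfrac{1}{2}(1-\gamma)(\|W\|_F^2 + \|H\|_F^2)\right]}
#' with `lam` applied literally -- no rescaling by the matrix dimensions, in
#' contrast to some library conventions (scikit-learn multiplies its
#' `alpha` by `n` or `m`). `gamma` trades L1 sparsity against L2 shrinkage.
#'
#' @param X Binary data matrix (sparse or dense, or a [phenotype_matrix]).
#' @param W,H Nonnegative factor matrices (n x k and k x m).
#' @param lam Regularization weight, `>= 0`.
#' @param gamma L1 ratio in `[0, 1]`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' nmf_objective(matrix(1), matrix(1), matrix(1), lam = 0.2, gamma = 0.5)
nmf_objective <- function(X, W, H, lam = 0.2, gamma = 0.5) {
  X <- as_sparse_binary(X)
  check_factors(W, H, lam, gamma)
  resid2 <- frob2_resid(X, W, H)
  penalty <- gamma * (sum(W) + sum(H)) +
    0.5 * (1 - gamma) * (sum(W^2) + sum(H^2))
  resid2 + lam * penalty
}

# ||X - WH||_F^2 without forming the dense residual:
# ||X||^2 - 2 <W, X Ht> + <WtW, HHt>. Exact for any sparse X.
frob2_resid <- function(X, W, H) {
  XHt <- as.matrix(X %*% t(H))
  sum(X@x^2) - 2 * sum(W * XHt) + sum(crossprod(W) * tcrossprod(H))
}

check_factors <- function(W, H, lam, gamma) {
  if (ncol(W) != nrow(H)) stop_domain("W (n x k) and H (k x m) do not conform")
  if (any(W < 0) || any(H < 0)) stop_domain("W and H must be nonnegative")
  if (lam < 0) stop_domain("`lam` must be >= 0")
  if (gamma < 0 || gamma > 1) stop_domain("`gamma` must lie in [0, 1]")
  invisible(TRUE)
}

#' Analytic gradient of the NMF objective
#'
#' Gradients of [nmf_objective()] with respect to `W` and `H`; these are the
#' stationarity conditions the coordinate-descent solver's updates are
#' derived from (valid in the interior, i.e. where entries are positive).
#'
#' @inheritParams nmf_objective
#' @return List with matrices `dW` and `dH`.
#' @export
nmf_gradient <- function(X, W, H, lam = 0.2, gamma = 0.5) {
  X <- as_sparse_binary(X)
  check_factors(W, H, lam, gamma)
  XHt <- as.matrix(X %*% t(H))
  WtX <- as.matrix(Matrix::crossprod(W, X))
  HHt <- tcrossprod(H)
  WtW <- crossprod(W)
  dW <- -2 * XHt + 2 * W %*% HHt + lam * gamma + lam * (1 - gamma) * W
  dH <- -2 * WtX + 2 * WtW %*% H + lam * gamma + lam * (1 - gamma) * H
  list(dW = dW, dH = dH)
}

#' Fit the regularized NMF topic model
#'
#' Factorizes a binary individual-by-phecode matrix as `X ~ W H` with
#' `W >= 0` (n x k individual-topic loadings) and `H >= 0` (k x m
#' topic-phenotype weights), minimizing the elastic-net penalized Frobenius
#' objective of [nmf_objective()] by cyclic HALS (hierarchical alternating
#' least squares) column/row updates. The L1 penalty enters each closed-form
#' coordinate update as a constant shift `-lam * gamma` in the numerator and
#' the L2 penalty as `+lam * (1 - gamma)` in the denominator, followed by
#' projection onto `[0, Inf)`; each update solves its subproblem exactly, so
#' the objective trace is non-increasing.
#'
#' @param X A [phenotype_matrix] or 0/1 matrix.
#' @param k Number of topics.
#' @param lam Regularization weight (default 0.2).
#' @param gamma L1 ratio (default 0.5).
#' @param max_iter Maximum number of full W/H sweeps.
#' @param tol Stop when the relative objective change between sweeps falls
#'   below this.
#' @param seed Seed for the random initialization.
#' @param init `"random"` (uniform on `[0, sqrt(mean(X)/k)]`) or `"nndsvd"`
#'   (nonnegative double SVD, deterministic).
#' @return Object of class `topic_model`: nonnegative `W`, `H` (with
#'   dimnames), `objective_trace` (objective after each sweep, preceded by
#'   the initial value), `converged`, `n_iter`, and the configuration.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 120, n_phecodes = 60,
#'                                   n_topics = 3, core_size = 5, seed = 3))
#' fit <- fit_nmf(coh$X, k = 3, seed = 3)
#' glance(fit)
fit_nmf <- function(X, k = 6, lam = 0.2, gamma = 0.5, max_iter = 500,
                    tol = 1e-6, seed = 1L, init = c("random", "nndsvd")) {
  init <- match.arg(init)
  pm_ids <- if (inherits(X, "phenotype_matrix")) X$individual_ids
  pm_codes <- if (inherits(X, "phenotype_matrix")) X$phecodes
  X <- as_sparse_binary(X)
  n <- nrow(X); m <- ncol(X)
  if (k < 1) stop_domain("`k` must be >= 1")
  if (k > min(n, m)) stop_domain("`k` = %d exceeds min(n, m) = %d", k, min(n, m))
  if (lam < 0) stop_domain("`lam` must be >= 0")
  if (gamma < 0 || gamma > 1) stop_domain("`gamma` must lie in [0, 1]")
  if (tol <= 0) stop_domain("`tol` must be > 0")
  if (all(X@x == 0) || length(X@x) == 0L) {
    stop_domain("X is all zeros; factorization is degenerate")
  }

  if (init == "random") {
    hi <- sqrt(Matrix::mean(X) / k)
    Winit <- with_local_seed(seed, matrix(runif(n * k, 0, hi), n, k))
    Hinit <- with_local_seed(seed + 1L, matrix(runif(k * m, 0, hi), k, m))
  } else {
    sv <- nndsvd_init(X, k)
    Winit <- sv$W; Hinit <- sv$H
  }

  fit <- hals_fit(X, Winit, Hinit, lam, gamma, max_iter, tol)

  W <- fit$W; H <- fit$H
  tl <- topic_labels(k)
  dimnames(W) <- list(pm_ids %||% rownames(X), tl)
  dimnames(H) <- list(tl, pm_codes %||% colnames(X))
  structure(
    list(W = W, H = H,
         config = list(k = as.integer(k), lam = lam, gamma = gamma,
                       max_iter = as.integer(max_iter), tol = tol,
                       seed = as.integer(seed), init = init),
         objective_trace = fit$trace,
         converged = fit$converged, n_iter = fit$n_iter),
    class = "topic_model"
  )
}

# Cyclic HALS sweeps. Each column of W (row of H) has the exact nonnegative
# minimizer of its quadratic subproblem:
#   w_j = max(0, (2 (X Ht - W HHt + w_j HHt_jj)_j - lam*gamma) /
#                (2 HHt_jj + lam*(1-gamma)))
hals_fit <- function(X, W, H, lam, gamma, max_iter, tol) {
  l1 <- lam * gamma
  l2 <- lam * (1 - gamma)
  k <- ncol(W)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- nmf_objective(X, W, H, lam, gamma)
  converged <- FALSE
  it <- 0L
  Xt <- Matrix::t(X)
  for (it in seq_len(max_iter)) {
    # --- update W columns ---
    XHt <- as.matrix(X %*% t(H))
    HHt <- tcrossprod(H)
    for (j in seq_len(k)) {
      denom <- 2 * HHt[j, j] + l2
      if (denom <= 0) { W[, j] <- 0; next }
      num <- 2 * (XHt[, j] - W %*% HHt[, j] + W[, j] * HHt[j, j]) - l1
      W[, j] <- pmax(0, num / denom)
    }
    # --- update H rows ---
    XtW <- as.matrix(Xt %*% W)      # m x k
    WtW <- crossprod(W)
    for (j in seq_len(k)) {
      denom <- 2 * WtW[j, j] + l2
      if (denom <= 0) { H[j, ] <- 0; next }
      num <- 2 * (XtW[, j] - t(H) %*% WtW[, j] + H[j, ] * WtW[j, j]) - l1
      H[j, ] <- pmax(0, num / denom)
    }
    trace[it + 1L] <- nmf_objective(X, W, H, lam, gamma)
    rel <- abs(trace[it] - trace[it + 1L]) / max(trace[it], .Machine$double.eps)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(W = W, H = H, trace = trace[seq_len(it + 1L)],
       converged = converged, n_iter = it)
}

# Nonnegative double SVD initialization (Boutsidis & Gallopoulos): split each
# leading singular pair into its positive and negative parts and keep the
# dominant one.
nndsvd_init <- function(X, k) {
  Xd <- as.matrix(X)
  sv <- svd(Xd, nu = k, nv = k)
  n <- nrow(X); m <- ncol(X)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (n_p >= n_n && n_p > 0) {
        W[, j] <- sqrt(sv$d[j] * n_p) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * n_p) * vp / sqrt(sum(vp^2))
      } else if (n_n > 0) {
        W[, j] <- sqrt(sv$d[j] * n_n) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * n_n) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- 1e-6 * mean(abs(Xd))
  W[W <= 0] <- eps; H[H <= 0] <- eps
  list(W = W, H = H)
}

#' Normalize matrix rows to unit Euclidean norm
#'
#' Zero rows are left unchanged. Used to put individual-topic loadings on a
#' common scale before visualization or comparison.
#'
#' @param W Nonnegative matrix.
#' @return Matrix with each nonzero row scaled to L2 norm 1.
#' @export
normalize_rows_l2 <- function(W) {
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm == 0] <- 1
  W / nrm
}

#' SVD scree of the phenotype matrix
#'
#' Singular values of the column-mean-centered matrix, used to pick the
#' number of topics by looking at the decay of the spectrum (the elbow).
#'
#' @param X A [phenotype_matrix] or numeric matrix.
#' @param k_max Number of leading components to return.
#' @return A tibble of class `scree_table`: `component`, `singular_value`,
#'   `variance_explained` (share of total centered variance) and
#'   `cumulative_variance`.
#' @export
scree <- function(X, k_max = 20) {
  X <- as_sparse_binary(X)
  if (k_max < 1) stop_domain("`k_max` must be >= 1")
  if (k_max > min(dim(X))) stop_domain("`k_max` exceeds min(n, m)")
  Xc <- sweep(as.matrix(X), 2, Matrix::colMeans(X))
  d <- svd(Xc, nu = 0, nv = 0)$d
  out <- tibble(
    component = seq_len(k_max),
    singular_value = d[seq_len(k_max)],
    variance_explained = d[seq_len(k_max)]^2 / sum(d^2)
  ) |>
    mutate(cumulative_variance = cumsum(.data$variance_explained))
  class(out) <- c("scree_table", class(out))
  out
}

#' Assign each individual to their highest-loading topic
#'
#' The hard topic assignment used for prevalence summaries: the argmax of
#' each row of `W`, ties broken toward the lowest topic index; an all-zero
#' row gets `NA` (unassigned).
#'
#' @param W Nonnegative loading matrix or a `topic_model`.
#' @return A tibble: `individual_id` (row names, or row index as character),
#'   `topic` (0-based label matching column names, `NA` if unassigned).
#'   The attribute `"prevalence"` holds the per-topic count tibble
#'   (unassigned rows excluded); assigned counts plus unassigned sum to
#'   `nrow(W)`.
#' @export
assign_topics <- function(W) {
  if (inherits(W, "topic_model")) W <- W$W
  if (any(W < 0)) stop_domain("W must be nonnegative")
  k <- ncol(W)
  labels <- colnames(W) %||% topic_labels(k)
  idx <- apply(W, 1L, function(r) {
    if (all(r == 0)) NA_integer_ else which.max(r)  # which.max takes first tie
  })
  out <- tibble(
    individual_id = rownames(W) %||% as.character(seq_len(nrow(W))),
    topic = ifelse(is.na(idx), NA_character_, labels[idx])
  )
  prev <- out |>
    filter(!is.na(.data$topic)) |>
    dplyr::count(.data$topic, name = "n_individuals")
  prev <- left_join(tibble(topic = labels), prev, by = "topic") |>
    mutate(n_individuals = dplyr::coalesce(.data$n_individuals, 0L))
  attr(out, "prevalence") <- prev
  attr(out, "n_unassigned") <- sum(is.na(idx))
  out
}

#' @export
print.topic_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<topic_model> k = %d, lam = %g, gamma = %g (%s init, seed %d)\n",
    cfg$k, cfg$lam, cfg$gamma, cfg$init, cfg$seed
  ))
  cat(sprintf("  %d x %d individuals x phecodes; objective %.4g after %d sweeps%s\n",
              nrow(x$W), ncol(x$H), tail(x$objective_trace, 1), x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' @importFrom utils tail
NULL
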