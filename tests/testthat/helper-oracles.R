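# Independent oracles and small fixtures used across the suite.

# Small default cohort for fast tests.
tiny_cohort <- function(seed = 11, n = 300, m = 80, k = 3, core = 6, ...) {
  simulate_cohort(sim_config(
    n_individuals = n, n_phecodes = m, n_topics = k, core_size = core,
    seed = seed, ...
  ))
}

# Lee-Seung multiplicative-update NMF (unpenalized Frobenius objective):
# an independent reference algorithm for cross-checking the HALS solver.
mu_nmf <- function(X, k, seed, max_iter = 500) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  set.seed(seed)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  sum((X - W %*% H)^2)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force maximum-total-score assignment.
brute_assignment_max <- function(S) {
  best <- -Inf; best_p <- NULL
  for (p in all_perms(nrow(S))) {
    tot <- sum(S[cbind(seq_len(nrow(S)), p)])
    if (tot > best) { best <- tot; best_p <- p }
  }
  list(total = best, perm = best_p)
}

# Random descriptor tables for agreement tests.
random_descriptors <- function(k, t, universe, prefix = "t") {
  purrr::map(seq_len(k), function(i) {
    tibble::tibble(
      topic = paste0(prefix, i), rank = seq_len(t),
      phecode = sample(universe, t), weight = sort(runif(t), decreasing = TRUE),
      degenerate = FALSE
    )
  }) |> purrr::list_rbind()
}

# Hand-written logistic negative log-likelihood; minimized with optim as an
# MLE oracle independent of glm's IRLS.
logistic_nll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(log1p(exp(eta))) - sum(y * eta)
}

optim_logistic <- function(X, y) {
  stats::optim(rep(0, ncol(X)), logistic_nll, X = X, y = y,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))$par
}
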