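# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never leak global RNG state.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of per-stage seeds from one master seed, kept < 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "genotopics_domain_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "genotopics_format_error")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain("`%s` must be a single non-missing number", name)
  }
  invisible(x)
}

# Coerce a phenotype input (phenotype_matrix or plain matrix / Matrix) to a
# sparse dgCMatrix, keeping dimnames.
as_sparse_binary <- function(X) {
  if (inherits(X, "phenotype_matrix")) X <- X$X
  X <- Matrix::Matrix(X, sparse = TRUE)
  # force a general (non-triangular/symmetric) double CSC matrix
  X <- methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  X
}
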