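#' Tidy a fitted topic model
#'
#' @param x A `topic_model`.
#' @param matrix Which factor to tidy: `"H"` (topic-phenotype weights,
#'   long: `topic`, `phecode`, `weight`) or `"W"` (individual-topic
#'   loadings, long: `individual_id`, `topic`, `loading`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy topic_model
#' @export
tidy.topic_model <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    as_tibble(x$H, rownames = "topic") |>
      tidyr::pivot_longer(-"topic", names_to = "phecode", values_to = "weight")
  } else {
    as_tibble(x$W, rownames = "individual_id") |>
      tidyr::pivot_longer(-"individual_id", names_to = "topic",
                          values_to = "loading")
  }
}

#' One-row summary of a fitted topic model
#'
#' @param x A `topic_model`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `lam`, `gamma`, `init`, `seed`, `n_iter`,
#'   `converged`, `objective` (final value), `w_density`, `h_density`
#'   (fractions of nonzero entries -- the L1 penalty drives these down).
#' @method glance topic_model
#' @export
glance.topic_model <- function(x, ...) {
  tibble(
    k = x$config$k, lam = x$config$lam, gamma = x$config$gamma,
    init = x$config$init, seed = x$config$seed,
    n_iter = x$n_iter, converged = x$converged,
    objective = tail(x$objective_trace, 1),
    w_density = mean(x$W > 0), h_density = mean(x$H > 0)
  )
}

#' Tidy a topic-association result
#'
#' Binds the per-topic Pearson rows and the logistic-regression rows into
#' one long table.
#'
#' @param x A `topic_association`.
#' @param ... Unused.
#' @return Tibble: `method` (`"pcc"` / `"lr"`), `term`, `estimate`
#'   (correlation r or log-odds coefficient), `p_value`.
#' @method tidy topic_association
#' @export
tidy.topic_association <- function(x, ...) {
  bind_rows(
    x$pcc |> transmute(method = "pcc", term = .data$topic,
                       estimate = .data$r, p_value = .data$p),
    x$lr |> transmute(method = "lr", term = .data$term,
                      estimate = .data$estimate, p_value = .data$p_value)
  )
}

#' @method glance topic_association
#' @export
glance.topic_association <- function(x, ...) {
  tibble(n = x$n, maf = x$maf, joint = x$joint,
         min_p_pcc = min(x$pcc$p), min_p_lr = min(x$lr$p_value))
}

#' @importFrom dplyr transmute bind_rows
NULL
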