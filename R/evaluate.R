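#' Top-ranked phecode descriptors of each topic
#'
#' The `t` phecodes with the largest weight in each row of the
#' topic-phenotype matrix `H`, descending; weight ties are broken
#' lexicographically by phecode label so descriptor sets are deterministic.
#' An all-zero topic row still yields `t` (lexicographically first) labels
#' but is flagged via the `degenerate` column.
#'
#' @param model A `topic_model`, or a nonnegative `H` matrix with column
#'   names.
#' @param t Descriptor size (default 10, the size used in ranked topic
#'   tables; word-cloud style summaries typically use more).
#' @return A tibble of class `topic_descriptors`: `topic`, `rank`,
#'   `phecode`, `weight`, `degenerate`.
#' @export
top_descriptors <- function(model, t = 10) {
  H <- if (inherits(model, "topic_model")) model$H else model
  if (t < 1) stop_domain("`t` must be >= 1")
  if (t > ncol(H)) stop_domain("`t` = %d exceeds number of phecodes %d", t, ncol(H))
  codes <- colnames(H) %||% phecode_labels(ncol(H))
  topics <- rownames(H) %||% topic_labels(nrow(H))
  out <- purrr::map(seq_len(nrow(H)), function(i) {
    w <- H[i, ]
    ord <- order(-w, codes)[seq_len(t)]
    tibble(
      topic = topics[i], rank = seq_len(t),
      phecode = codes[ord], weight = unname(w[ord]),
      degenerate = all(w == 0)
    )
  }) |> purrr::list_rbind()
  attr(out, "t") <- as.integer(t)
  attr(out, "k") <- nrow(H)
  class(out) <- c("topic_descriptors", class(out))
  out
}

descriptor_sets <- function(desc) {
  split(desc$phecode, desc$topic)[unique(desc$topic)]
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Topic dependency: mean pairwise descriptor overlap
#'
#' Mean Jaccard similarity over all unordered pairs of topics' descriptor
#' sets. High dependency means redundant, overlapping topics; disjoint
#' descriptor sets give 0 and identical sets give 1.
#'
#' @param desc A [top_descriptors()] table.
#' @return Scalar in `[0, 1]`.
#' @export
topic_dependency <- function(desc) {
  sets <- descriptor_sets(desc)
  k <- length(sets)
  if (k < 2) stop_domain("topic dependency needs k >= 2 topics")
  pairs <- utils::combn(k, 2)
  mean(apply(pairs, 2, function(p) jaccard(sets[[p[1]]], sets[[p[2]]])))
}

#' Topic coherence (UMass) of descriptors against the corpus
#'
#' For each topic, the mean over ordered descriptor pairs (`w_i` ranked
#' above `w_j`) of `log((D(w_i, w_j) + 1) / D(w_j))`, where `D` counts
#' individuals (rows of `X`) carrying the phecode(s). Higher (closer to 0)
#' means the topic's descriptors genuinely co-occur in the data. Pairs whose
#' lower-ranked descriptor never occurs (`D(w_j) = 0`) are undefined and
#' dropped from the mean with a warning.
#'
#' @param desc A [top_descriptors()] table.
#' @param X The [phenotype_matrix] the model was fit to.
#' @return A tibble: `topic`, `coherence`; overall mean in attribute
#'   `"mean_coherence"`.
#' @export
topic_coherence <- function(desc, X) {
  pm <- if (inherits(X, "phenotype_matrix")) X else phenotype_matrix(
    X, individual_ids = rownames(X), phecodes = colnames(X)
  )
  sets <- descriptor_sets(desc)
  missing <- setdiff(unique(desc$phecode), pm$phecodes)
  if (length(missing)) {
    stop_domain("descriptor phecode(s) absent from matrix: %s",
                paste(head(missing, 5), collapse = ", "))
  }
  Xs <- pm$X
  dropped <- 0L
  scores <- purrr::imap(sets, function(labels, topic) {
    sub <- Xs[, labels, drop = FALSE]           # ranked order preserved
    docs <- Matrix::colSums(sub)                # D(w)
    co <- as.matrix(Matrix::crossprod(sub))     # D(w_i, w_j)
    t_len <- length(labels)
    vals <- c()
    for (i in seq_len(t_len - 1)) {
      for (j in (i + 1):t_len) {
        if (docs[j] == 0) { dropped <<- dropped + 1L; next }
        vals <- c(vals, log((co[i, j] + 1) / docs[j]))
      }
    }
    tibble(topic = topic, coherence = if (length(vals)) mean(vals) else NA_real_)
  }) |> purrr::list_rbind()
  if (dropped > 0) {
    warning(dropped, " descriptor pair(s) dropped (lower-ranked phecode absent from corpus)")
  }
  attr(scores, "mean_coherence") <- mean(scores$coherence, na.rm = TRUE)
  scores
}

#' Hungarian-matched agreement between two sets of topic descriptors
#'
#' Builds the k x k matrix of Jaccard similarities between the two models'
#' descriptor sets, finds the one-to-one topic matching maximizing total
#' similarity (Hungarian algorithm / optimal linear assignment) and returns
#' the mean matched similarity -- the agreement score used to quantify topic
#' stability. If the two sides have different numbers of topics the smaller
#' side is padded with empty topics (similarity 0) and the result flagged.
#'
#' @param desc_a,desc_b [top_descriptors()] tables.
#' @return List of class `topic_agreement`: `agreement` (mean matched
#'   Jaccard in `[0, 1]`), `matching` (tibble `topic_a`, `topic_b`,
#'   `jaccard`), `similarity` (the full matrix), `padded` flag.
#' @export
topic_agreement <- function(desc_a, desc_b) {
  sa <- descriptor_sets(desc_a)
  sb <- descriptor_sets(desc_b)
  ka <- length(sa); kb <- length(sb)
  k <- max(ka, kb)
  padded <- ka != kb
  S <- matrix(0, k, k)
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    S[i, j] <- jaccard(sa[[i]], sb[[j]])
  }
  match_cols <- solve_assignment_max(S)
  matched <- S[cbind(seq_len(k), match_cols)]
  name_a <- c(names(sa), rep(NA_character_, k - ka))
  name_b <- c(names(sb), rep(NA_character_, k - kb))
  structure(
    list(
      agreement = mean(matched),
      matching = tibble(topic_a = name_a,
                        topic_b = name_b[match_cols],
                        jaccard = matched),
      similarity = S[seq_len(ka), seq_len(kb), drop = FALSE],
      padded = padded
    ),
    class = "topic_agreement"
  )
}

#' @export
print.topic_agreement <- function(x, ...) {
  cat(sprintf("<topic_agreement> %.3f over %d matched topics%s\n",
              x$agreement, nrow(x$matching),
              if (x$padded) " (padded: unequal k)" else ""))
  invisible(x)
}

#' Solve the linear assignment problem (maximize total score)
#'
#' O(k^3) Hungarian algorithm (shortest augmenting paths with dual
#' potentials) on a square score matrix.
#'
#' @param S Square numeric matrix of scores.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`;
#'   the assignment maximizes `sum(S[cbind(seq_len(k), a)])`.
#' @export
solve_assignment_max <- function(S) {
  if (nrow(S) != ncol(S)) stop_domain("score matrix must be square")
  solve_assignment_min(max(S) - S)
}

solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  vc <- n + 1L                    # virtual column
  u <- numeric(n)                 # row potentials
  v <- numeric(n + 1L)            # column potentials (incl. virtual)
  p <- integer(n + 1L)            # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[vc] <- i
    j0 <- vc
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == vc) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

#' Stability scan over regularization settings and seeds
#'
#' Refits the topic model over a grid of `lam`, `gamma`, `k` and seeds and
#' scores each fit's Hungarian-matched agreement against a reference
#' (base-setting) model's descriptors. High agreement across the grid means
#' the learned topics are robust to the tuning parameters.
#'
#' @param X A [phenotype_matrix].
#' @param base_model Reference `topic_model`; if `NULL`, fit at the base
#'   setting (`k`, `lam = 0.2`, `gamma = 0.5`, first seed).
#' @param lam Values of the regularization weight to scan.
#' @param gamma Values of the L1 ratio to scan.
#' @param k Topic counts to scan.
#' @param seeds Random initialization seeds; each grid point is fit once per
#'   seed.
#' @param t Descriptor size used for agreement (default 10).
#' @param ... Passed to [fit_nmf()] (e.g. `max_iter`, `tol`).
#' @return A tibble of class `stability_report`: one row per grid point and
#'   seed with `lam`, `gamma`, `k`, `seed`, `agreement`, `converged`,
#'   `error` (NA unless that fit failed). Reference settings in attributes.
#' @export
stability_scan <- function(X, base_model = NULL, lam = 0.2, gamma = 0.5,
                           k = 6, seeds = 1L, t = 10, ...) {
  grid <- tidyr::expand_grid(lam = lam, gamma = gamma, k = k, seed = seeds)
  if (nrow(grid) == 0L) stop_domain("empty stability grid")
  if (is.null(base_model)) {
    base_model <- fit_nmf(X, k = k[1], lam = 0.2, gamma = 0.5,
                          seed = seeds[1], ...)
  }
  base_desc <- top_descriptors(base_model, t = t)
  rows <- purrr::pmap(grid, function(lam, gamma, k, seed) {
    res <- tryCatch({
      fit <- fit_nmf(X, k = k, lam = lam, gamma = gamma, seed = seed, ...)
      agr <- topic_agreement(base_desc, top_descriptors(fit, t = t))
      tibble(lam = lam, gamma = gamma, k = k, seed = seed,
             agreement = agr$agreement, converged = fit$converged,
             error = NA_character_)
    }, error = function(e) {
      tibble(lam = lam, gamma = gamma, k = k, seed = seed,
             agreement = NA_real_, converged = NA, error = conditionMessage(e))
    })
    res
  }) |> purrr::list_rbind()
  attr(rows, "base_config") <- base_model$config
  attr(rows, "t") <- as.integer(t)
  class(rows) <- c("stability_report", class(rows))
  rows
}
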