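test_that("MAF counts alleles and is order-invariant", {
  expect_equal(compute_maf(rep(0L, 10)), 0)
  expect_warning(m <- compute_maf(rep(2L, 5)), "major")
  expect_equal(m, 1)
  g <- c(0L, 0L, 1L, 2L, 0L, 1L)
  expect_equal(compute_maf(g), sum(g) / (2 * length(g)))
  expect_equal(compute_maf(g), compute_maf(rev(g)))
  expect_error(compute_maf(integer(0)), class = "genotopics_domain_error")
  expect_error(compute_maf(c(0, 3)), class = "genotopics_domain_error")
})

test_that("Pearson test matches the closed form and a high-precision oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)

  sym <- pearson_test(c(1, 2, 3, 4), c(1, 0, 0, 1))
  expect_equal(sym$r, 0)
  expect_equal(sym$p, 1)

  # reference: direct formula, r to 1e-12 and p to 1e-10
  set.seed(12)
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50) + 0.3 * a
    got <- pearson_test(a, b)
    r_ref <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    t_ref <- r_ref * sqrt((50 - 2) / (1 - r_ref^2))
    p_ref <- 2 * pt(-abs(t_ref), df = 48)
    expect_lt(abs(got$r - r_ref), 1e-12)
    expect_lt(abs(got$p - p_ref), 1e-10)
  }

  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)),
               class = "genotopics_domain_error")
  expect_error(pearson_test(1:2, 1:2), class = "genotopics_domain_error")
})

test_that("Pearson p-values are uniform under the null", {
  set.seed(77)
  p <- replicate(2000, {
    pearson_test(rnorm(50), rnorm(50))$p
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  # KS critical value at alpha = 0.01 for n = 2000
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))
})

test_that("logistic fit recovers closed forms and the brute-force MLE", {
  # intercept-only truth
  set.seed(3)
  y <- rbinom(500, 1, 0.3)
  x <- rnorm(500)
  fit <- logistic_fit(y, data.frame(x = x))
  phat <- mean(y)
  expect_equal(unname(fit$estimate[fit$term == "(Intercept)"]),
               log(phat / (1 - phat)), tolerance = 0.15)
  expect_lt(abs(fit$estimate[fit$term == "x"]), 0.25)
  expect_gt(fit$p_value[fit$term == "x"], 0.01)

  # 2x2 table (a, b, c, d) = (30, 10, 20, 40): slope = log(ad/bc) = log(6)
  exposed <- c(rep(1, 40), rep(0, 60))
  outcome <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  f22 <- logistic_fit(outcome, data.frame(exposed = exposed))
  expect_equal(unname(f22$estimate[f22$term == "exposed"]), log(6),
               tolerance = 1e-6)

  # oracle equivalence: optim on the hand-written likelihood, n = 200
  set.seed(14)
  xo <- rnorm(200)
  yo <- rbinom(200, 1, plogis(-0.5 + 0.8 * xo))
  fo <- logistic_fit(yo, data.frame(x = xo))
  ref <- optim_logistic(cbind(1, xo), yo)
  expect_equal(unname(fo$estimate), unname(ref), tolerance = 1e-4)

  # the returned optimum beats every point of a surrounding coarse grid
  ll_at <- function(b) -logistic_nll(b, cbind(1, xo), yo)
  ll_hat <- ll_at(fo$estimate)
  grid <- expand.grid(b0 = fo$estimate[1] + seq(-1, 1, 0.25),
                      b1 = fo$estimate[2] + seq(-1, 1, 0.25))
  expect_true(all(apply(grid, 1, function(b) ll_at(b)) <= ll_hat + 1e-8))

  # Wald p agrees with glm's summary by construction; sanity vs z formula
  z <- fo$estimate / fo$std_error
  expect_equal(fo$p_value, 2 * pnorm(-abs(z)))
})

test_that("logistic fit flags separation and rejects singular designs", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -5), rnorm(20, 5))  # perfectly separable
  expect_warning(fit <- logistic_fit(y, data.frame(x = x)), "separation")
  expect_false(attr(fit, "converged"))

  expect_error(logistic_fit(y, data.frame(a = x, b = 2 * x)),
               class = "genotopics_domain_error")
  expect_error(logistic_fit(c(0, 1, 2), data.frame(x = 1:3)),
               class = "genotopics_domain_error")
})

test_that("topic association detects the planted signal and aligns by id", {
  coh <- tiny_cohort(seed = 31, n = 1200, m = 80, k = 3, core = 6,
                     effect_beta = 0.8)
  fit <- fit_nmf(coh$X, k = 3, seed = 2, max_iter = 200)
  assoc <- topic_association(fit, coh$genotype, coh$age, coh$sex)
  best <- assoc$pcc$topic[which.max(abs(assoc$pcc$r))]
  expect_lt(assoc$pcc$p[assoc$pcc$topic == best], 0.001)
  # the LR coefficient for the same topic is positive and significant
  expect_gt(assoc$lr$estimate[assoc$lr$term == best], 0)
  expect_lt(assoc$lr$p_value[assoc$lr$term == best], 0.01)
  expect_true(all(c("age", "sex") %in% assoc$lr$term))

  # named inputs in scrambled order give identical results
  ids <- rownames(fit$W)
  perm <- sample(length(ids))
  assoc2 <- topic_association(
    fit,
    tibble::tibble(individual_id = ids[perm], g = coh$genotype[perm]),
    stats::setNames(coh$age, ids)[perm],
    stats::setNames(coh$sex, ids)[perm]
  )
  expect_equal(assoc2$pcc, assoc$pcc)

  # misalignment errors name the offender
  bad <- tibble::tibble(individual_id = c(ids[-1], "ghost"),
                        g = coh$genotype)
  expect_error(topic_association(fit, bad, coh$age, coh$sex),
               regexp = ids[1], class = "genotopics_domain_error")

  # marginal mode returns one row per topic
  assoc_m <- topic_association(fit, coh$genotype, coh$age, coh$sex,
                               joint = FALSE)
  expect_equal(sort(assoc_m$lr$term), sort(colnames(fit$W)))

  # permuting the genotype destroys the association
  set.seed(55)
  p_perm <- replicate(20, {
    gp <- sample(coh$genotype)
    topic_association(fit, gp, coh$age, coh$sex)$pcc$p[
      assoc$pcc$topic == best]
  })
  expect_gt(mean(p_perm > 0.05), 0.8)
})

test_that("phewas tests eligible phecodes and sets the Bonferroni threshold", {
  coh <- tiny_cohort(seed = 41, n = 800, m = 60, k = 3, core = 6,
                     effect_beta = 1.2, maf = 0.2)
  ph <- phewas(coh$X, coh$genotype, coh$age, coh$sex, min_cases = 20)
  expect_equal(nrow(ph), 60)
  expect_equal(attr(ph, "bonferroni"), 0.05 / attr(ph, "n_tested"))
  expect_true(all(is.na(ph$p_value[!ph$tested])))
  expect_true(all(ph$n_cases[!ph$tested] < 20 |
                    ph$n_cases[!ph$tested] > 800 - 20))

  # the planted topic's core phecodes rank ahead of the rest
  core <- coh$core_sets[[coh$config$target_topic]]
  tested <- dplyr::filter(ph, tested)
  ranks <- rank(tested$p_value)
  expect_lt(median(ranks[tested$phecode %in% core]),
            median(ranks[!tested$phecode %in% core]))

  # direction agrees with the topic-level analysis: core effects positive
  expect_gt(median(tested$estimate[tested$phecode %in% core]), 0)
})

test_that("phewas controls family-wise error under a permuted genotype", {
  coh <- tiny_cohort(seed = 43, n = 500, m = 100, k = 4, core = 6,
                     effect_beta = 0, maf = 0.15)
  set.seed(99)
  crossings <- replicate(40, {
    gp <- sample(coh$genotype)
    ph <- phewas(coh$X, gp, coh$age, coh$sex, min_cases = 20)
    min(ph$p_value, na.rm = TRUE) < attr(ph, "bonferroni")
  })
  expect_lt(mean(crossings), 0.15)
})
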