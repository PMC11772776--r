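test_that("model log-likelihood matches direct log-pmf summation", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    counts <- rnbinom(n, mu = 100, size = 10)
    c_ <- sample(c(1, 2), n, replace = TRUE)
    d_ <- c_ - 1
    sm <- runif(n, 0.5, 2) * 100
    beta1 <- c(t1 = runif(1, 0.5, 2))
    beta2 <- runif(1, -0.4, 0.4)
    shape <- runif(1, 2, 50)
    ll <- nb_model_loglik(counts, c_, d_, sm, rep("t1", n),
                          beta1, beta2, shape)
    mu <- sm * (beta1 * c_ + beta2 * d_)
    expect_equal(ll, nb_loglik_oracle(counts, mu, shape), tolerance = 1e-8)
  }
})

test_that("tumor likelihood at purity 1 reduces to the cell-line likelihood", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 15
    counts <- rnbinom(n, mu = 80, size = 8)
    c_ <- sample(c(1, 2), n, replace = TRUE)
    sm <- runif(n, 50, 150)
    tissue <- sample(c("a", "b"), n, replace = TRUE)
    beta1 <- c(a = runif(1, 0.5, 2), b = runif(1, 0.5, 2))
    beta3 <- c(a = runif(1, 0.1, 3), b = runif(1, 0.1, 3))
    beta2 <- runif(1, -0.3, 0.3)
    shape <- runif(1, 5, 30)
    ll_tumor <- nb_model_loglik(counts, c_, c_ - 1, sm, tissue, beta1, beta2,
                                shape, beta3 = beta3,
                                purity = rep(1, n), tumor = TRUE)
    ll_cell <- nb_model_loglik(counts, c_, c_ - 1, sm, tissue, beta1, beta2,
                               shape)
    expect_equal(ll_tumor, ll_cell, tolerance = 1e-12)
  }
})

test_that("normalization and shrinkage follow their closed forms", {
  fit <- structure(list(beta1 = c(a = 1.0, b = 1.5), tissues = c("a", "b"),
                        beta2 = -0.5, beta2_sd = 0.1),
                   class = "compensation_fit")
  expect_equal(normalize_deviation(fit), -0.4)
  fit$beta1 <- c(a = 2); fit$tissues <- "a"; fit$beta2 <- 1
  expect_equal(normalize_deviation(fit), 0.5)
  fit$beta2 <- 0
  expect_equal(normalize_deviation(fit), 0)

  # weighted normalizer option
  fit2 <- structure(list(beta1 = c(a = 1, b = 3), tissues = c("a", "b"),
                         beta2 = 1, beta2_sd = 1),
                    class = "compensation_fit")
  expect_equal(normalize_deviation(fit2, weights = c(a = 3, b = 1)), 1 / 1.5)

  # z = 0 gives pseudo_p = 1 and a fully shrunk score
  fit$beta2 <- 0; fit$beta2_sd <- 0.2
  sc <- shrink_score(fit)
  expect_equal(sc$pseudo_p, 1)
  expect_equal(sc$score, 0)

  # z = 1.96 gives pseudo_p ~ 0.05 and score ~ 0.95 * beta2_star
  fit3 <- structure(list(beta1 = c(a = 1), tissues = "a",
                         beta2 = -0.4 * 1.96 / 1.96, beta2_sd = NA),
                    class = "compensation_fit")
  fit3$beta2 <- -0.4; fit3$beta2_sd <- -0.4 / -1.96
  sc <- shrink_score(fit3)
  expect_equal(sc$z, -1.96)
  expect_equal(sc$pseudo_p, 2 * pnorm(-1.96))
  expect_equal(sc$score, (1 - 2 * pnorm(-1.96)) * -0.4, tolerance = 1e-12)
  expect_equal(sc$score, -0.38, tolerance = 0.01)
})

test_that("shrinkage never exceeds beta2_star and is monotone in |z|", {
  b2s <- -0.6
  prev <- 0
  for (z in seq(0, 6, by = 0.25)) {
    fit <- structure(list(beta1 = c(a = 1), tissues = "a", beta2 = b2s,
                          beta2_sd = if (z == 0) 1e9 else abs(b2s) / z),
                     class = "compensation_fit")
    s <- shrink_score(fit, beta2_star = b2s)$score
    expect_lte(abs(s), abs(b2s))
    expect_true(sign(s) == sign(b2s) || s == 0)
    expect_gte(abs(s), abs(prev) - 1e-12)   # monotone in |z|
    prev <- s
  }
})

test_that("synthetic genes recover their generative compensation score", {
  # full compensation, pure scaling, and full hyperactivation at n = 200
  for (ts in c(-1, 0, 1)) {
    fit <- fit_one_synthetic_gene(ts, seed = 100 + ts, chains = 2,
                                  iter = 500, warmup = 400)
    expect_true(fit$diagnostics$converged)
    sc <- shrink_score(fit)
    expect_equal(sc$score, ts, tolerance = 0.15)
  }
})

test_that("the tumor model recovers compensation under Beta purity", {
  fit <- fit_one_synthetic_gene(-1, cohort_kind = "tumor", seed = 31,
                                chains = 2, iter = 500, warmup = 400)
  expect_true(fit$diagnostics$converged)
  expect_equal(shrink_score(fit)$score, -1, tolerance = 0.2)
})

test_that("with purity near zero the deviation posterior returns its prior", {
  set.seed(33)
  n <- 60
  counts <- rnbinom(n, mu = 100, size = 20)
  c_ <- c(rep(1, 40), rep(2, 20))
  fit <- fit_gene_tumor(counts, c_, c_ - 1, rep(1, n), 100, rep("t", n),
                        purity = rep(1e-3, n), chains = 4, iter = 2000,
                        warmup = 800, seed = 1)
  # beta2 prior for tumors is N(0, 0.2)
  expect_equal(fit$beta2, 0, tolerance = 0.05)
  expect_equal(fit$beta2_sd, 0.2, tolerance = 0.05)
  expect_error(fit_gene_tumor(counts, c_, c_ - 1, rep(1, n), 100,
                              rep("t", n), purity = rep(0, n)))
})

test_that("independent seeded runs agree within Monte-Carlo error", {
  fit1 <- fit_one_synthetic_gene(-0.5, seed = 51, fit_seed = 1)
  fit2 <- fit_one_synthetic_gene(-0.5, seed = 51, fit_seed = 2)
  mcse <- fit1$beta2_sd / sqrt(min(fit1$diagnostics$ess["beta2"], 1e6))
  expect_lt(abs(fit1$beta2 - fit2$beta2), 3 * (mcse + fit2$beta2_sd /
    sqrt(fit2$diagnostics$ess["beta2"])))
  # identical seed: identical draws
  fit3 <- fit_one_synthetic_gene(-0.5, seed = 51, fit_seed = 1)
  expect_identical(fit1$draws, fit3$draws)
})

test_that("classification requires the score boundary in both cohorts", {
  sa <- data.frame(gene = c("a", "b", "c", "d"),
                   score = c(-0.5, -0.5, 0.4, -0.31))
  sb <- data.frame(gene = c("a", "b", "c", "e"),
                   score = c(-0.4, -0.2, 0.35, -0.9))
  cl <- classify_compensation(sa, sb)
  expect_equal(cl$status[cl$gene == "a"], "compensated")
  expect_equal(cl$status[cl$gene == "b"], "neither")   # must hold in both
  expect_equal(cl$status[cl$gene == "c"], "hyperactivated")
  expect_equal(cl$status[cl$gene == "d"], "single-cohort")
  expect_equal(cl$status[cl$gene == "e"], "single-cohort")
  # boundary is strict
  cl2 <- classify_compensation(data.frame(gene = "x", score = -0.3),
                               data.frame(gene = "x", score = -0.3))
  expect_equal(cl2$status, "neither")
})

test_that("gene-set contrast equals the two-group pooled-variance statistic", {
  set.seed(41)
  scores <- c(rnorm(30, 0, 0.1), rnorm(10, -0.5, 0.1))
  in_set <- c(rep(FALSE, 30), rep(TRUE, 10))
  res <- gene_set_difference(scores, in_set)
  tt <- t.test(scores[in_set], scores[!in_set], var.equal = TRUE)
  expect_equal(res$estimate, mean(scores[in_set]) - mean(scores[!in_set]),
               tolerance = 1e-12)
  expect_equal(res$wald, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # noiseless shift is recovered exactly (summary.lm warns on the
  # zero-residual fit; the estimate itself is what matters here)
  res0 <- suppressWarnings(
    gene_set_difference(c(rep(0, 5), rep(-0.5, 5)),
                        c(rep(FALSE, 5), rep(TRUE, 5))))
  expect_equal(res0$estimate, -0.5)
  expect_error(gene_set_difference(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})
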