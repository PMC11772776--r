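test_that("argos calls are the conjunction of compensated and toxic", {
  comp <- data.frame(gene = c("a", "b", "c", "d"),
                     compensated = c(TRUE, TRUE, FALSE, FALSE),
                     hyperactivated = c(FALSE, FALSE, FALSE, TRUE))
  tox <- data.frame(gene = c("a", "b", "c", "d", "z"),
                    toxic = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  amp <- data.frame(gene = c("a", "b"), frequently_amplified = c(TRUE, FALSE))
  res <- call_argos(comp, tox, amp)
  expect_equal(res$argos, c(TRUE, FALSE, FALSE, FALSE))
  # frequent amplification is annotated, not required
  expect_true(res$frequently_amplified[res$gene == "a"])
  expect_true(res$argos[res$gene == "a"])
  # universe is the intersection; attrition recorded
  expect_false("z" %in% res$gene)
  expect_equal(unname(attr(res, "attrition")["n_universe"]), 4)
  expect_error(call_argos(comp, data.frame(gene = "q", toxic = TRUE)),
               "no genes")
})

test_that("complex enrichment matches hypergeometric enumeration", {
  universe <- paste0("g", 1:1000)
  compensated <- paste0("g", 1:10)
  members <- c("g1", "g2", "g3", "g500")
  res <- complex_enrichment(members, compensated, universe)
  expect_equal(res$n_member_compensated, 3)
  oracle <- fisher_oracle(3, 4, 10, 1000)
  expect_equal(res$fisher_p, oracle, tolerance = 1e-10)
  expect_equal(res$fisher_p, 2.87e-6, tolerance = 0.01)

  # small-universe agreement with exhaustive enumeration
  set.seed(71)
  for (i in 1:10) {
    u <- paste0("u", 1:sample(10:30, 1))
    comp <- sample(u, sample(1:5, 1))
    mem <- sample(u, sample(2:6, 1))
    res <- complex_enrichment(mem, comp, u)
    expect_equal(res$fisher_p,
                 fisher_oracle(res$n_member_compensated, length(mem),
                               length(comp), length(u)),
                 tolerance = 1e-10)
  }

  # degenerate margins
  none <- complex_enrichment(c("g900", "g901"), compensated, universe)
  expect_gte(none$fisher_p, 0.99)
  all_comp <- complex_enrichment(c("g1", "g2"), universe, universe)
  expect_equal(all_comp$fisher_p, 1)

  # members outside the universe are dropped with a warning
  expect_warning(complex_enrichment(c("g1", "not_tested"), compensated,
                                    universe), "dropped")
  expect_null(suppressWarnings(
    complex_enrichment("not_tested", compensated, universe)))
})

test_that("complex toxicity contrast is the signed two-group Wald statistic", {
  est <- setNames(c(rep(0, 20), rep(-1, 3)) + rep(c(0.001, -0.001), len = 23),
                  paste0("g", 1:23))
  members <- paste0("g", 21:23)
  w <- complex_toxicity(members, est)
  tt <- t.test(est[members], est[setdiff(names(est), members)],
               var.equal = TRUE)
  expect_equal(w, unname(tt$statistic), tolerance = 1e-10)
  expect_lt(w, -100)   # members drop out far more

  # identical distributions give a near-zero statistic
  est2 <- setNames(rep(c(-0.2, 0.2), 10), paste0("g", 1:20))
  expect_equal(complex_toxicity(paste0("g", 1:4), est2), 0, tolerance = 1e-9)

  # single-member complex is still defined
  expect_true(is.finite(complex_toxicity("g1", est)))
})

test_that("complex ranking applies BH correction and the toxicity tie-break", {
  universe <- paste0("g", 1:40)
  compensated <- paste0("g", 1:8)
  membership <- data.frame(
    complex_id = rep(c("cpxA", "cpxB", "cpxC"), each = 4),
    gene = c(paste0("g", 1:4),        # enriched
             paste0("g", c(5, 6, 20, 21)),
             paste0("g", 30:33))      # not enriched
  )
  tox <- setNames(rep(0, 40), universe)
  tox[paste0("g", 1:4)] <- -1
  tox <- tox + rep(c(0.01, -0.01), 20)
  ranked <- rank_complexes(membership, compensated, universe, tox)
  expect_equal(ranked$complex_id[1], "cpxA")
  # hand step-up on this instance, plus the canonical 3-complex example
  expect_equal(ranked$fdr_q, bh_oracle(ranked$fisher_p), tolerance = 1e-12)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # q-values are monotone in sorted-p order and bounded by 1
  ord <- order(ranked$fisher_p)
  expect_true(all(diff(ranked$fdr_q[ord]) >= -1e-12))
  expect_true(all(ranked$fdr_q <= 1))

  # a single complex keeps q = p
  one <- rank_complexes(membership[membership$complex_id == "cpxA", ],
                        compensated, universe, tox)
  expect_equal(one$fdr_q, one$fisher_p)

  # ties in q are broken by more negative toxicity first
  m2 <- data.frame(complex_id = rep(c("x", "y"), each = 3),
                   gene = c(paste0("g", 1:3), paste0("g", c(1, 2, 4))))
  tox2 <- setNames(rep(c(0.01, -0.01), 20), universe)
  tox2[paste0("g", c(1, 2, 4))] <- -2
  r2 <- rank_complexes(m2, compensated, universe, tox2)
  expect_equal(r2$fisher_p[1], r2$fisher_p[2])
  expect_equal(r2$complex_id[1], "y")
})

test_that("ranked q-values reproduce the manual step-up on random complexes", {
  set.seed(72)
  universe <- paste0("g", 1:60)
  for (i in 1:5) {
    comp <- sample(universe, 12)
    n_cpx <- sample(3:8, 1)
    membership <- do.call(rbind, lapply(seq_len(n_cpx), function(k) {
      data.frame(complex_id = paste0("c", k),
                 gene = sample(universe, sample(3:6, 1)))
    }))
    ranked <- rank_complexes(membership, comp, universe)
    expect_equal(ranked$fdr_q, bh_oracle(ranked$fisher_p), tolerance = 1e-12)
  }
})
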