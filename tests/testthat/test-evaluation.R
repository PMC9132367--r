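test_that("Cronbach alpha matches a hand computation and its limits", {
  # two perfectly correlated equal-variance items
  x <- cbind(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1))
  expect_equal(cronbach_alpha(x), 1)
  # written-out 4 x 3 binary matrix against the covariance formula
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  k <- 3
  alpha_hand <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), alpha_hand)
  # independent items: alpha near zero at large n
  set.seed(19)
  xi <- matrix(rbinom(50000 * 5, 1, 0.5), 50000)
  expect_lt(abs(cronbach_alpha(xi)), 0.05)
  expect_error(cronbach_alpha(cbind(c(1, 1), c(0, 0))), "variance")
})

test_that("the reliability-retention rule reproduces the published cases", {
  expect_true(reliability_criterion(0.62, 0.64))   # 9-item row: 0.969 ratio
  expect_false(reliability_criterion(0.59, 0.64))  # 8-item row: 0.922 ratio
  expect_true(reliability_criterion(0.5, 0.5, ratio = 1))
  expect_error(reliability_criterion(0.5, 0), "positive")
})

test_that("Pearson correlation and its Fisher interval behave correctly", {
  s <- c(2, 4, 5, 7, 9)
  expect_equal(concurrent_validity(s, s)$r, 1)
  expect_equal(concurrent_validity(s, -s)$r, -1)
  a <- c(1, 3, 2, 5, 4); b <- c(2, 3, 4, 4, 6)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cv <- concurrent_validity(a, b)
  expect_equal(cv$r, hand)
  expect_true(cv$ci[1] < hand && hand < cv$ci[2])
  expect_error(concurrent_validity(a, rep(1, 5)), "variance")
})

test_that("TOST equivalence has the right interior and boundary behavior", {
  # identical correlations, huge n, tight dependence: decisive equivalence
  res <- dependent_corr_equivalence(0.5, 0.5, 0.95, n = 2552)
  expect_lt(res$p, 0.001)
  # difference exactly at the margin: one-sided p near 1/2 at large n
  res2 <- dependent_corr_equivalence(0.55, 0.50, 0.90, n = 100000, margin = 0.05)
  expect_equal(res2$p, 0.5, tolerance = 0.05)
  # symmetric in swapping the two correlations
  r12a <- dependent_corr_equivalence(0.52, 0.48, 0.9, 500)
  r12b <- dependent_corr_equivalence(0.48, 0.52, 0.9, 500)
  expect_equal(r12a$p, r12b$p, tolerance = 1e-12)
  expect_error(dependent_corr_equivalence(0.9, -0.9, 0.99, 100), "positive semidefinite")
  expect_error(dependent_corr_equivalence(0.5, 0.5, 0.9, 5), "at least 10")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:25, 1))
    expect_equal(bh_adjust(p), bh_stepup(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the criteria table has coherent structure on synthetic data", {
  d <- generate_population(generator_config(n_respondents = 800, seed = 31))
  fit <- gpcm(d$responses_main)
  lad <- candidate_ladder(fit)
  ext <- list(kq = summed_scores(d$responses_kq),
              who = summed_scores(d$responses_who))
  tab <- build_criteria_table(d$responses_main, fit, lad, ext)
  expect_equal(nrow(tab), 20)  # 10 lengths x 2 external measures
  full <- tab[tab$length == 12, ]
  expect_equal(full$r_sum_full, c(1, 1))
  expect_equal(full$r_eap_full, c(1, 1))
  expect_true(all(tab$p_sum_adj >= tab$p_sum - 1e-12))
  expect_true(all(tab$p_eap_adj >= tab$p_eap - 1e-12))
  expect_true(all(tab$p_sum_adj <= 1 & tab$p_eap_adj <= 1))
  expect_true(all(abs(c(tab$r_sum_full, tab$r_eap_full,
                        tab$r_sum_ext, tab$r_eap_ext)) <= 1))
})

test_that("the five-criterion rule returns the shortest admissible form", {
  tab <- published_criteria_table()
  sel_kq <- select_final_form(tab, external_measure = "kq")
  expect_identical(sel_kq$length, 9L)
  expect_true(sel_kq$admissible)
  sel_who <- select_final_form(tab, external_measure = "who")
  expect_identical(sel_who$length, 10L)
  expect_true(sel_who$admissible)
  # per-criterion bookkeeping: the 8-item form fails only reliability vs kq
  chk8 <- sel_kq$checks[sel_kq$checks$length == 8, ]
  expect_false(chk8$reliability)
  expect_true(chk8$equivalence_sum && chk8$equivalence_eap)
})

test_that("when every row fails, the full form is returned flagged", {
  tab <- published_criteria_table()
  tab$alpha[tab$length < 12] <- 0.1
  sel <- select_final_form(tab, external_measure = "kq")
  expect_identical(sel$length, 12L)
  expect_false(sel$admissible)
})
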