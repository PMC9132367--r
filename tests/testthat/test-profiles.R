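test_that("group means and intervals match a hand computation", {
  scores <- c(4, 6, 8, 1, 2, 3)
  grp <- c("a", "a", "a", "b", "b", "b")
  gs <- group_means(scores, grp)
  expect_equal(gs$mean, c(6, 2))
  se_a <- sd(c(4, 6, 8)) / sqrt(3)
  expect_equal(gs$lower[1], 6 - qnorm(0.975) * se_a)
  expect_equal(gs$upper[1], 6 + qnorm(0.975) * se_a)
  # pooled mean equals the n-weighted mean of level means
  expect_equal(sum(gs$n * gs$mean) / sum(gs$n), mean(scores))
  # constant scores give a zero-width interval
  gc <- group_means(rep(5, 4), rep("x", 4))
  expect_equal(gc$lower, gc$upper)
  # singleton level: no interval
  g1 <- group_means(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(g1$lower[g1$level == "b"]))
  expect_error(group_means(numeric(0), character(0)), "no non-missing")
})

test_that("interval width shrinks like 1/sqrt(n)", {
  set.seed(23)
  widths <- vapply(c(100, 400, 1600), function(n) {
    g <- group_means(rnorm(n), rep("g", n))
    g$upper - g$lower
  }, 0)
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("perceived-accuracy dichotomization keeps only the top level", {
  expect_equal(as.character(dichotomize_uu("4")), "completely_accurate")
  expect_equal(as.character(dichotomize_uu("dont_know")),
               "not_completely_accurate")
  expect_equal(as.character(dichotomize_uu("1")), "not_completely_accurate")
  expect_equal(as.character(dichotomize_uu(c("4", "2", NA))),
               c("completely_accurate", "not_completely_accurate", NA))
  expect_error(dichotomize_uu("5"), "unknown")
})

test_that("descriptive tables reproduce percentages from counts", {
  df <- data.frame(status = factor(rep(c("never", "negative", "positive"),
                                       times = c(250, 1510, 792))),
                   age = c(rep(30, 2000), rep(40, 552)))
  tab <- descriptive_table(df)
  pos <- tab$categorical[tab$categorical$level == "positive", ]
  expect_equal(round(pos$pct, 1), 31.0)
  expect_equal(sum(tab$categorical$pct), 100, tolerance = 0.1)
  expect_equal(tab$continuous$mean, mean(df$age))
  one <- descriptive_table(data.frame(v = rep("only", 7)))
  expect_equal(one$categorical$pct, 100)
})

test_that("known-groups hypotheses evaluate orderings on point estimates", {
  gs <- data.frame(level = c("never", "negative", "positive"),
                   n = c(50, 100, 80), mean = c(7.2, 8.1, 8.5),
                   lower = NA, upper = NA)
  expect_true(known_groups_check(gs, c("never", "negative", "positive"))$pass)
  expect_false(known_groups_check(gs, c("positive", "negative", "never"))$pass)
  expect_error(known_groups_check(gs, c("never", "unknown")), "absent")
})

test_that("generated education gradients pass the known-groups check", {
  hits <- 0
  for (s in 1:10) {
    d <- generate_population(generator_config(n_respondents = 2552, seed = s))
    sc <- summed_scores(d$responses_main)
    gs <- group_means(sc, d$covariates$education)
    hits <- hits + known_groups_check(
      gs, c("middle_school", "high_school", "college"))$pass
  }
  expect_gte(hits, 9)
})
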