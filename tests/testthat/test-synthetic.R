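test_that("item banks honor degenerate ranges and are seed-deterministic", {
  spec <- default_bank_spec(disc_range = c(1, 1))
  banks <- generate_item_bank(spec, seed = 3)
  expect_true(all(banks$main$a == 1))
  b2 <- generate_item_bank(spec, seed = 3)
  expect_identical(banks, b2)
  expect_error(default_bank_spec(disc_range = c(0, 1)), "positive")
  expect_error(default_bank_spec(n_items = c(main = 2L)), "at least 3")
})

test_that("drawn discriminations are uniform over the configured range", {
  set.seed(77)
  draws <- unlist(lapply(1:1000, function(i)
    generate_item_bank(default_bank_spec())$main$a))
  ks <- ks.test(draws, "punif", 0.9, 2.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated responses follow the GPCM category distribution", {
  # flat item: correct rate 1/2 at any trait level
  bank0 <- item_bank(a = 0, b = 0)
  x <- simulate_responses(bank0, rep(3.7, 10000), seed = 1)
  expect_equal(mean(x), 0.5, tolerance = 0.02)
  # saturation for an easy item at extreme trait
  bank1 <- item_bank(a = 1.5, b = -1)
  x <- simulate_responses(bank1, rep(10, 10000), seed = 2)
  expect_gte(mean(x), 0.99)
  # marginal correctness within a binomial 99% CI at several trait points
  a <- 1.3; b <- -0.6
  bank <- item_bank(a = a, b = b)
  for (th in c(-2, 0, 1.5)) {
    p <- gpcm_prob(th, a, b)[1, 2]
    x <- simulate_responses(bank, rep(th, 10000), seed = round(10 * th) + 100)
    expect_lt(abs(mean(x) - p), 2.576 * sqrt(p * (1 - p) / 10000))
  }
  expect_error(simulate_responses(bank, numeric(0)), "nonempty")
})

test_that("refitting recovers the generating discriminations", {
  bank <- random_bank(9)
  set.seed(9)
  x <- simulate_responses(bank, rnorm(2000))
  fit <- gpcm(x)
  expect_gte(cor(bank$a, fit$bank$a), 0.9)
})

test_that("the default population emulates the study profile", {
  d <- generate_population(generator_config(seed = 42))
  s_main <- summed_scores(d$responses_main)
  expect_gte(mean(s_main), 10.5)
  expect_lte(mean(s_main), 11.5)
  r <- cor(s_main, summed_scores(d$responses_kq))
  expect_gte(r, 0.45)
  expect_lte(r, 0.65)
  expect_identical(dim(d$true_theta), c(2552L, 3L))
  expect_true(all(d$responses_main %in% 0:1))
  expect_false(anyNA(d$responses_main))
  # identical config + seed gives an identical dataset
  d2 <- generate_population(generator_config(seed = 42))
  expect_identical(d, d2)
})

test_that("Cronbach alpha of the generated 12-item measure sits in the moderate band", {
  alphas <- vapply(42:61, function(s)
    cronbach_alpha(generate_population(generator_config(seed = s))$responses_main),
    0)
  expect_gte(sum(alphas >= 0.55 & alphas <= 0.75), 18)
})

test_that("missing responses appear at the configured rate and only then", {
  d0 <- generate_population(generator_config(n_respondents = 500, seed = 5))
  expect_false(anyNA(d0$responses_main))
  dm <- generate_population(generator_config(n_respondents = 2000, seed = 5,
                                             missing_rate = 0.1))
  rate <- mean(is.na(cbind(dm$responses_main, dm$responses_kq,
                           dm$responses_who)))
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("null covariate effects leave group means flat", {
  eff <- lapply(default_covariate_effects(), function(e) e * 0)
  d <- generate_population(generator_config(n_respondents = 20000,
                                            covariate_effects = eff, seed = 8))
  s <- summed_scores(d$responses_main)
  gm <- tapply(s, d$covariates$education, mean)
  expect_lt(max(gm) - min(gm), 0.15)
})

test_that("configured covariate effects order the group means", {
  ok_edu <- ok_hiv <- logical(10)
  for (s in 1:10) {
    d <- generate_population(generator_config(seed = s))
    th <- d$true_theta[, 1]
    edu <- tapply(th, d$covariates$education, mean)
    hiv <- tapply(th, d$covariates$hiv_test, mean)
    ok_edu[s] <- all(diff(edu[c("middle_school", "high_school", "college")]) > 0)
    ok_hiv[s] <- all(diff(hiv[c("never", "negative", "positive")]) > 0)
  }
  expect_gte(sum(ok_edu), 9)
  expect_gte(sum(ok_hiv), 9)
})

test_that("invalid generator configurations are rejected", {
  R <- matrix(c(1, 0.99, -0.9, 0.99, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(generator_config(trait_cor = R), "positive definite")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
})

test_that("datasets round-trip through CSV plus JSON sidecar", {
  d <- generate_population(generator_config(n_respondents = 120, seed = 13))
  tmp <- file.path(tempdir(), "synth.csv")
  paths <- write_dataset(d, tmp)
  back <- read_responses(tmp)
  expect_identical(unname(back$item), unname(d$responses_main))
  expect_identical(unname(back$kq), unname(d$responses_kq))
  expect_equal(back$n_complete, 120L)
  truth <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(truth$banks$main$a, d$banks$main$a, tolerance = 1e-12)
  expect_equal(truth$config$seed, 13L)
})

test_that("generator configs load from YAML and JSON", {
  yml <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("n_respondents: 200", "seed: 4", "trait_cor: 0.7",
               "missing_rate: 0.05"), yml)
  cfg <- read_generator_config(yml)
  expect_identical(cfg$n_respondents, 200L)
  expect_equal(cfg$trait_cor[1, 2], 0.7)
  expect_equal(cfg$missing_rate, 0.05)
  js <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(n_respondents = 300, seed = 2), js,
                       auto_unbox = TRUE)
  expect_identical(read_generator_config(js)$n_respondents, 300L)
})
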