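test_that("dominant items are always selected under the sum objective", {
  bank <- item_bank(a = c(2, 2, 2, rep(0.2, 9)), b = rep(-1, 12))
  expect_equal(enumerate_optimal(bank, 3)$items, 1:3)
  expect_equal(assemble_short_form(bank, 3)$items, 1:3)
  # maximin guards the information floor at the outer anchors, where weakly
  # discriminating items are flatter and can dominate; the two formulations
  # legitimately disagree here but must each match their own oracle
  em <- enumerate_optimal(bank, 3, formulation = "maximin")
  mm <- assemble_short_form(bank, 3, formulation = "maximin")
  expect_identical(mm$items, em$items)
})

test_that("dropping one item removes the smallest information contributor", {
  bank <- random_bank(17)
  anchors <- anchor_set()
  I <- shortform:::information_matrix(bank, anchors$anchors)
  contrib <- drop(I %*% anchors$weights)
  f <- enumerate_optimal(bank, 11, anchors)
  expect_equal(setdiff(1:12, f$items), which.min(contrib))
})

test_that("equal-information ties resolve to the smallest index set", {
  bank <- item_bank(a = rep(1.3, 8), b = rep(-1, 8))
  for (f in c("sum", "maximin")) {
    expect_equal(assemble_short_form(bank, 4, formulation = f)$items, 1:4)
    expect_equal(enumerate_optimal(bank, 4, formulation = f)$items, 1:4)
  }
})

test_that("branch and bound equals exhaustive enumeration across banks", {
  for (s in 1:5) {
    bank <- random_bank(200 + s, arange = c(0.3, 2.5), brange = c(-3.5, 1.5))
    for (L in c(3, 6, 9, 11)) for (f in c("sum", "maximin")) {
      e <- enumerate_optimal(bank, L, formulation = f)
      m <- assemble_short_form(bank, L, formulation = f)
      expect_identical(m$items, e$items)
      expect_equal(m$objective, e$objective, tolerance = 1e-10)
    }
  }
})

test_that("objective value is nondecreasing in form length", {
  bank <- random_bank(33)
  for (f in c("sum", "maximin")) {
    obj <- vapply(3:11, function(L)
      enumerate_optimal(bank, L, formulation = f)$objective, 0)
    expect_true(all(diff(obj) >= -1e-12))
  }
})

test_that("anchor-weight scaling leaves the selection unchanged", {
  bank <- random_bank(44)
  a1 <- anchor_set()
  a2 <- anchor_set(weights = rep(7.3, 5))
  expect_identical(assemble_short_form(bank, 5, a1)$items,
                   assemble_short_form(bank, 5, a2)$items)
})

test_that("the candidate ladder covers lengths 3 through p-1", {
  bank <- random_bank(55)
  lad <- candidate_ladder(bank)
  expect_length(lad, 9)
  expect_equal(vapply(lad, function(x) x$length, 1L), 3:11,
               ignore_attr = TRUE)
  # stored TIF never exceeds the full form
  full <- test_information(bank, attr(lad, "theta_grid"))
  for (fm in lad) expect_true(all(fm$tif <= full + 1e-12))
  # high-discrimination, well-placed items enter before weak ones
  ranks <- rank(-bank$a)
  first_in <- vapply(1:12, function(j)
    min(c(Inf, which(vapply(lad, function(fm) j %in% fm$items, TRUE)))), 0)
  expect_gt(cor(ranks, first_in, method = "spearman", use = "complete.obs"), 0.4)
})

test_that("invalid lengths and oversized enumerations are rejected", {
  bank <- random_bank(2)
  expect_error(enumerate_optimal(bank, 2), "between 3")
  expect_error(enumerate_optimal(bank, 12), "between 3")
  expect_error(assemble_short_form(bank, 13), "between 3")
})
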