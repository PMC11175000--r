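test_that("matrix extrema match independent per-rule branch enumeration", {
  m <- medoc_matrix()
  expect_length(m$rules, 22)
  # oracle: enumerate each rule's attainable point values via probe inputs,
  # sum per-rule maxima/minima
  per_rule <- lapply(m$rules, rule_point_values)
  expect_true(all(vapply(per_rule, function(p) {
    all(p %in% c(-1.5, -1, 1, 1.5))
  }, logical(1))))
  oracle_max <- sum(vapply(per_rule, max, numeric(1)))
  oracle_min <- sum(vapply(per_rule, min, numeric(1)))
  ext <- matrix_extrema(m)
  expect_equal(unname(ext["raw_max"]), oracle_max)
  expect_equal(unname(ext["raw_min"]), oracle_min)
  expect_equal(oracle_max, 25.5)
  expect_equal(oracle_min, -oracle_max)
})

test_that("toy and empty matrices have hand-computed extrema", {
  toy <- list(rules = list(
    a = list(row_id = "a", kind = "frequency_range", fav_lo = 0, fav_hi = 1,
             lo_open = FALSE, hi_open = FALSE,
             modifier = list(behavior = "x", favorable_answer = "y",
                             delta = 0.5)),
    b = list(row_id = "b", kind = "frequency_range", fav_lo = 0, fav_hi = 1,
             lo_open = FALSE, hi_open = FALSE, modifier = NULL)
  ))
  expect_equal(unname(matrix_extrema(toy)), c(-2.5, 2.5))
  expect_equal(unname(matrix_extrema(list(rules = list()))), c(0, 0))
})

test_that("branch cut-offs follow the printed inequalities", {
  m <- medoc_matrix()$rules
  branch <- function(rule, s) score_item(rule, servings = s)$branch
  # fruits/vegetables: favourable at >= 5/day (35/week)
  expect_equal(branch(m$fruits_vegetables, 35), "favorable")
  expect_equal(branch(m$fruits_vegetables, 34.9), "unfavorable")
  # cereals: closed interval [21, 42] servings/week
  expect_equal(branch(m$cereals, 21), "favorable")
  expect_equal(branch(m$cereals, 42), "favorable")
  expect_equal(branch(m$cereals, 20.5), "unfavorable")
  expect_equal(branch(m$cereals, 42.5), "unfavorable")
  # dairy: exactly 2/day
  expect_equal(branch(m$dairy, 14), "favorable")
  expect_equal(branch(m$dairy, 13.5), "unfavorable")
  expect_equal(branch(m$dairy, 14.5), "unfavorable")
  # eggs: 2-4/week inclusive
  expect_equal(vapply(c(2, 3, 4), branch, character(1), rule = m$eggs),
               rep("favorable", 3))
  expect_equal(vapply(c(1.5, 4.5, 0), branch, character(1), rule = m$eggs),
               rep("unfavorable", 3))
  # red meat: complementarity repair, favourable iff < 2
  expect_equal(branch(m$red_meat, 1.5), "favorable")
  expect_equal(branch(m$red_meat, 2), "unfavorable")
  # zero-tolerance rows
  expect_equal(branch(m$fast_food, 0), "favorable")
  expect_equal(branch(m$fast_food, 0.5), "unfavorable")
})

test_that("branch complementarity holds on a dense frequency grid", {
  m <- medoc_matrix()$rules
  freq_rules <- Filter(function(r) r$kind == "frequency_range", m)
  grid <- seq(0, 100, by = 0.25)
  for (rule in freq_rules) {
    branches <- vapply(grid, function(s) {
      score_item(rule, servings = s)$branch
    }, character(1))
    expect_true(all(branches %in% c("favorable", "unfavorable")))
    # an independent interval-membership oracle
    inside <- (if (rule$lo_open) grid > rule$fav_lo else grid >= rule$fav_lo) &
      (if (rule$hi_open) grid < rule$fav_hi else grid <= rule$fav_hi)
    expect_identical(branches == "favorable", inside)
  }
})

test_that("the matrix survives a JSON round trip", {
  m <- medoc_matrix()
  f <- tempfile(fileext = ".json")
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_equal(m2$raw_max, m$raw_max)
  expect_length(m2$rules, length(m$rules))
  card1 <- score_profile(medoc_extremal_profile("favorable"), m)
  card2 <- score_profile(medoc_extremal_profile("favorable"), m2)
  expect_equal(card2$raw_total, card1$raw_total)
})
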