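test_that("potato and alcohol components follow the published bins", {
  r <- mds_rules()
  expect_identical(mds_component(r$potatoes, 3), 5L)
  expect_identical(mds_component(r$potatoes, 4), 5L)
  expect_identical(mds_component(r$potatoes, 2), 4L)
  expect_identical(mds_component(r$potatoes, 1), 4L)
  expect_identical(mds_component(r$potatoes, 0), 3L)  # rare/no consumption
  expect_identical(mds_component(r$potatoes, 5), 2L)
  expect_identical(mds_component(r$potatoes, 6.5), 1L)
  expect_identical(mds_component(r$potatoes, 7), 0L)
  expect_identical(mds_component(r$alcohol, 2), 5L)
  expect_identical(mds_component(r$alcohol, 3), 4L)
  expect_identical(mds_component(r$alcohol, 4.5), 3L)
  expect_identical(mds_component(r$alcohol, 6), 2L)
  expect_identical(mds_component(r$alcohol, 7), 1L)
  expect_identical(mds_component(r$alcohol, 8), 0L)
})

test_that("ordinary components match an independent bin lookup", {
  r <- mds_rules()
  # oracle: literal monthly bin table evaluated by hand
  bin_oracle <- function(monthly) {
    if (monthly == 0) 0L
    else if (monthly <= 4) 1L
    else if (monthly <= 8) 2L
    else if (monthly <= 12) 3L
    else if (monthly <= 18) 4L
    else 5L
  }
  weekly <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 4.5, 5, 7, 10)
  for (w in weekly) {
    expect_identical(mds_component(r$fruit, w), bin_oracle(w * 4))
    expect_identical(mds_component(r$poultry, w), 5L - bin_oracle(w * 4))
  }
})

test_that("pro components are monotone increasing, anti decreasing", {
  r <- mds_rules()
  grid <- seq(0, 12, by = 0.25)
  pro <- vapply(grid, function(w) mds_component(r$vegetables, w), integer(1))
  anti <- vapply(grid, function(w) mds_component(r$meat_products, w), integer(1))
  expect_false(is.unsorted(pro))
  expect_false(is.unsorted(rev(anti)))
})

test_that("the fully adherent profile scores the printed maximum of 55", {
  res <- mds_total(mds_extremal_profile())
  expect_identical(res$total, 55L)
  expect_true(all(res$component_scores == 5L))
})

test_that("zero intake with heavy drinking scores the hand-summed floor", {
  sch <- medoc_schema()
  p <- response_profile(
    "floor",
    frequencies = stats::setNames(rep(0, nrow(sch$items)), sch$items$id),
    behaviors = list(),
    age_years = 40)
  p$frequencies[["spirits"]] <- 8 * 7  # 8 glasses/day
  res <- mds_total(p)
  # hand sum: pro components 0 each; anti (meat, poultry, dairy) 5 each;
  # potatoes at zero fall in the rare bin (3); olive oil unanswered (0);
  # alcohol above 7 glasses/day (0)
  expect_identical(unname(res$component_scores["potatoes"]), 3L)
  expect_identical(res$total, 0L + 15L + 3L + 0L + 0L)
})

test_that("moving potatoes from 3 to 0 drops the total by 5 - score(0)", {
  p <- mds_extremal_profile()
  before <- mds_total(p)$total
  p$frequencies[["potatoes"]] <- 0
  after <- mds_total(p)$total
  r <- mds_rules()
  expect_identical(before - after, 5L - mds_component(r$potatoes, 0))
})

test_that("totals stay within 0..55 on random profiles", {
  set.seed(99)
  for (arch in c("md", "wd", "mixed")) {
    params <- archetype_params(arch)
    totals <- vapply(1:40, function(i) {
      mds_total(generate_profile(params))$total
    }, integer(1))
    expect_true(all(totals >= 0 & totals <= 55))
  }
})

test_that("behaviour gates decide which intake counts", {
  p <- mds_extremal_profile()
  # refined cereals: the non-refined component loses its intake
  p$behaviors$cereal_refinement <- "refined"
  expect_identical(
    unname(mds_total(p)$component_scores["nonrefined_cereals"]), 0L)
  # full-fat dairy with high dairy intake is penalized
  p2 <- mds_extremal_profile()
  p2$frequencies[["cow_milk"]] <- 14
  p2$behaviors$dairy_fat <- "full_fat"
  expect_lt(unname(mds_total(p2)$component_scores["full_fat_dairy"]), 5L)
})
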