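test_that("servings merge frequency and portion multiplier", {
  expect_equal(servings_per_week(7, 1.0), 7)
  expect_equal(servings_per_week(7, 0.5), 3.5)
  expect_equal(servings_per_week(0, 1.5), 0)
  expect_error(servings_per_week(-1, 1), "non-negative")
  expect_error(servings_per_week(1, 0), "positive")
})

test_that("item scoring reproduces the published point values", {
  rules <- medoc_matrix()$rules
  fv <- rules$fruits_vegetables
  expect_equal(score_item(fv, 36, modifier_answer = "seasonal")$points, 1.5)
  expect_equal(score_item(fv, 36, modifier_answer = "not_seasonal")$points, 1)
  expect_equal(score_item(fv, 20, modifier_answer = "seasonal")$points, -1)
  expect_equal(score_item(fv, 20, modifier_answer = "not_seasonal")$points, -1.5)
  eggs <- rules$eggs
  expect_equal(score_item(eggs, 3)$points, 1)
  expect_equal(score_item(eggs, 0)$points, -1)
  expect_equal(score_item(eggs, 5)$points, -1)
})

test_that("the seasonal behaviour bonus is worth exactly 0.5", {
  fv <- medoc_matrix()$rules$fruits_vegetables
  for (s in c(35, 36, 50, 100)) {
    expect_equal(score_item(fv, s, modifier_answer = "seasonal")$points -
                   score_item(fv, s, modifier_answer = "not_seasonal")$points,
                 0.5)
  }
})

test_that("extremal profiles attain the raw extrema and normalized +/-20", {
  m <- medoc_matrix()
  fav <- score_profile(medoc_extremal_profile("favorable"), m)
  unf <- score_profile(medoc_extremal_profile("unfavorable"), m)
  expect_equal(fav$raw_total, m$raw_max)
  expect_equal(unf$raw_total, m$raw_min)
  expect_equal(fav$normalized_total, 20)
  expect_equal(unf$normalized_total, -20)
  expect_true(all(fav$item_scores$branch == "favorable"))
  expect_true(all(unf$item_scores$branch == "unfavorable"))
})

test_that("a single favourable row lifts the base-branch total by 2", {
  # all 22 rows on the unfavourable base branch (no modifier answers):
  # raw = -22; flipping only the eggs row to favourable gives 1 + (-21)
  all_unfav <- score_profile(base_branch_profile())
  expect_equal(all_unfav$raw_total, -22)
  expect_true(all(all_unfav$item_scores$modifier_delta == 0))
  eggs_fav <- score_profile(base_branch_profile("eggs"))
  expect_equal(eggs_fav$raw_total, 1 + (-22 + 1))
})

test_that("flipping every branch and modifier negates the raw total", {
  fav <- score_profile(medoc_extremal_profile("favorable"))
  unf <- score_profile(medoc_extremal_profile("unfavorable"))
  expect_equal(unf$raw_total, -fav$raw_total)
  # same antisymmetry without modifiers
  p_fav <- medoc_extremal_profile("favorable")
  p_unf <- medoc_extremal_profile("unfavorable")
  mods <- c("seasonality", "cereal_refinement", "dairy_fat", "fish_source",
            "white_meat_source", "red_meat_source", "sweets_type")
  p_fav$behaviors[mods] <- NULL
  p_unf$behaviors[mods] <- NULL
  expect_equal(score_profile(p_unf)$raw_total,
               -score_profile(p_fav)$raw_total)
})

test_that("subscores decompose the raw total on random profiles", {
  set.seed(42)
  m <- medoc_matrix()
  for (arch in c("md", "wd", "mixed")) {
    params <- archetype_params(arch)
    for (i in 1:40) {
      card <- score_profile(generate_profile(params), m)
      expect_equal(card$md_subscore + card$wd_subscore, card$raw_total)
      expect_gte(card$md_subscore, 0)
      expect_lte(card$wd_subscore, 0)
      expect_gte(card$raw_total, m$raw_min)
      expect_lte(card$raw_total, m$raw_max)
      expect_true(all(card$item_scores$points %in% c(-1.5, -1, 1, 1.5)))
    }
  }
})

test_that("normalization is linear, order-preserving and bounded", {
  m <- medoc_matrix()
  expect_equal(normalize_score(m$raw_max, m), 20)
  expect_equal(normalize_score(m$raw_min, m), -20)
  expect_equal(normalize_score(0, m), 0)
  raws <- sort(stats::runif(50, m$raw_min, m$raw_max))
  expect_false(is.unsorted(normalize_score(raws, m)))
  expect_error(normalize_score(m$raw_max + 1, m), "outside")
})

test_that("portion sizes scale the aggregated servings", {
  p <- medoc_extremal_profile("favorable")
  base <- score_profile(p)
  # halving every fruit/vegetable portion drops the row below 5/day
  fv_items <- medoc_schema()$aggregation_map$fruits_vegetables
  p$portions[fv_items] <- "small"
  small <- score_profile(p)
  row <- function(card) {
    card$item_scores[card$item_scores$row_id == "fruits_vegetables", ]
  }
  expect_equal(row(base)$points, 1.5)
  expect_equal(row(small)$points, -1)  # seasonal, below recommendation
  expect_equal(row(small)$servings, row(base)$servings / 2)
})

test_that("score_cohort returns one row per profile with per-row points", {
  set.seed(7)
  profs <- list(medoc_extremal_profile("favorable"), compliant_profile())
  df <- score_cohort(profs)
  expect_identical(nrow(df), 2L)
  expect_true(all(c("md_subscore", "wd_subscore", "raw_total",
                    "normalized_total", "points.eggs") %in% names(df)))
  expect_equal(df$normalized_total[1], 20)
})
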