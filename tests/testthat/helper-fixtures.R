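# Shared fixtures: profiles built in code, no stored data.

# A compliant mid-range profile touching every schema element.
compliant_profile <- function(id = "P1", age = 25) {
  sch <- medoc_schema()
  freqs <- stats::setNames(rep(1, nrow(sch$items)), sch$items$id)
  portion_items <- sch$items$id[sch$items$has_portion_question]
  response_profile(
    respondent_id = id,
    frequencies = freqs,
    portions = stats::setNames(rep("standard", length(portion_items)),
                               portion_items),
    behaviors = list(
      seasonality = "seasonal", cereal_refinement = "refined",
      olive_oil = "frequent", dairy_fat = "full_fat",
      fish_source = "supermarket", white_meat_source = "supermarket",
      red_meat_source = "local_producer", sweets_type = "homemade",
      no_breakfast = "no", nibbling = "no", spices_instead_of_salt = "yes",
      meal_time_minutes = 25, dining_out_per_week = 2
    ),
    age_years = age, sex = "F", height_cm = 170, weight_kg = 65
  )
}

# Profile sitting on the unfavourable base branch of every matrix row, with
# no modifier-behaviour answers, except chosen rows forced favourable.
base_branch_profile <- function(favorable_rows = character(0)) {
  freqs <- c(
    fruit_medium_large = 2, fruit_small = 1, cooked_vegetables = 2,
    raw_vegetables = 1, salad = 1, breakfast_cereals = 1, fresh_bread = 4,
    rice_other_cereals = 2, pasta = 3, cow_milk = 2, milk_products = 1,
    fresh_cheese = 1, seasoned_cheese = 1, eggs = 1, legumes = 1,
    fresh_fish = 0.5, tinned_fish = 0.5, white_meat = 3, red_meat = 3,
    ultra_processed_food = 2, cookies = 2, sweets_cakes_pastries = 1,
    breakfast_croissant_cappuccino = 3, loaf_bread = 5, bread_substitutes = 2,
    fast_food = 1, salted_snack = 1, soda = 2, ready_to_eat_meals = 1,
    frozen_foods = 1, dried_fruit = 0, potatoes = 0, french_fries = 0,
    focaccia_bread = 0, pizza = 0, wine = 0, beer = 0, cocktail = 0,
    spirits = 0
  )
  behaviors <- list(olive_oil = "occasional", no_breakfast = "yes",
                    nibbling = "yes", spices_instead_of_salt = "no",
                    meal_time_minutes = 15, dining_out_per_week = 5)
  if ("eggs" %in% favorable_rows) freqs[["eggs"]] <- 3
  if ("legumes" %in% favorable_rows) freqs[["legumes"]] <- 3
  if ("olive_oil" %in% favorable_rows) behaviors$olive_oil <- "regular"
  response_profile("base", frequencies = freqs, behaviors = behaviors,
                   age_years = 40)
}

# Independent per-rule branch enumeration: probe inputs driving each rule
# into both branches and, where a modifier exists, both modifier answers;
# returns the set of attainable point values for a rule.
rule_point_values <- function(rule) {
  probes <- list()
  if (rule$kind == "frequency_range") {
    inside <- if (is.finite(rule$fav_hi)) {
      (max(rule$fav_lo, 0) + rule$fav_hi) / 2
    } else {
      rule$fav_lo + 1
    }
    outside <- c(rule$fav_hi + 1, max(0, rule$fav_lo - 1),
                 rule$fav_lo + 1e-6, if (is.finite(rule$fav_hi)) {
                   rule$fav_hi - 1e-6
                 })
    for (s in c(inside, outside)) probes <- c(probes, list(list(servings = s)))
  } else if (rule$kind == "comparison") {
    probes <- list(list(servings = c(1, 2)), list(servings = c(2, 1)))
  } else if (rule$kind == "categorical") {
    for (a in c(rule$favorable_answers, "occasional", "yes", "no")) {
      probes <- c(probes, list(list(behavior = a)))
    }
  } else if (rule$kind == "behavior_threshold") {
    for (v in c(rule$threshold - 1, rule$threshold, rule$threshold + 1)) {
      probes <- c(probes, list(list(behavior = v)))
    }
  } else if (rule$kind == "breakfast") {
    probes <- list(list(servings = 0.5, behavior = "no"),
                   list(servings = 3, behavior = "no"),
                   list(servings = 0.5, behavior = "yes"))
  }
  mods <- if (is.null(rule$modifier)) {
    list(NULL)
  } else {
    list(rule$modifier$favorable_answer,
         paste0("not_", rule$modifier$favorable_answer))
  }
  pts <- c()
  for (pr in probes) {
    for (m in mods) {
      res <- tryCatch(
        score_item(rule, servings = pr$servings %||% NA_real_,
                   behavior_answer = pr$behavior, modifier_answer = m),
        error = function(e) NULL)
      if (!is.null(res)) pts <- c(pts, res$points)
    }
  }
  sort(unique(pts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
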