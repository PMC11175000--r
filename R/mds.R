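#' MedDietScore component rules
#'
#' The MedDietScore (MDS) is an 11-component a-priori Mediterranean-diet
#' adherence score; each component contributes 0-5 points and the total
#' spans 0-55. Components recommended for frequent consumption (non-refined
#' cereals, fruit, vegetables, legumes, fish) score increasingly with
#' intake; meat and products, poultry and full-fat dairy score inversely;
#' potatoes and alcohol have their own bin tables; olive oil is scored from
#' the consumption-pattern answer.
#'
#' Intake bins for the ordinary components are expressed in servings per
#' month (weekly intakes are converted with a factor 4): 0 -> 0, (0,4] -> 1,
#' (4,8] -> 2, (8,12] -> 3, (12,18] -> 4, >18 -> 5 points for pro-MD
#' components, reversed for anti-MD ones. Potatoes (servings/week):
#' 3-4 -> 5, 1-2 -> 4, <1 -> 3, then 2, 1, 0 for increasingly frequent
#' consumption up to daily. Alcohol (wine glasses/day): <3 -> 5, 3 -> 4,
#' 4-5 -> 3, 6 -> 2, 7 -> 1, >7 -> 0.
#'
#' @param monthly_bins Upper bin edges (servings/month) for the ordinary
#'   components; scores are `0:5` across the six bins.
#' @return Named list of component rules, each with `component_id`,
#'   `direction` (`"pro"`, `"anti"`, `"potato"`, `"alcohol"`,
#'   `"olive_oil"`), the MEDOC `items` (or `behavior`) it reads, and an
#'   optional `gate` behaviour restricting which intake counts (e.g. dairy
#'   counts as full-fat only when the respondent reports full-fat dairy).
#' @export
mds_rules <- function(monthly_bins = c(0, 4, 8, 12, 18)) {
  rule <- function(id, direction, items = NULL, behavior = NULL, gate = NULL) {
    list(component_id = id, direction = direction, items = items,
         behavior = behavior, gate = gate, monthly_bins = monthly_bins)
  }
  r <- list(
    rule("nonrefined_cereals", "pro",
         items = c("breakfast_cereals", "fresh_bread", "rice_other_cereals",
                   "pasta"),
         gate = list(behavior = "cereal_refinement", answer = "non_refined")),
    rule("fruit", "pro",
         items = c("fruit_medium_large", "fruit_small", "dried_fruit")),
    rule("vegetables", "pro",
         items = c("cooked_vegetables", "raw_vegetables", "salad")),
    rule("legumes", "pro", items = "legumes"),
    rule("potatoes", "potato", items = "potatoes"),
    rule("fish", "pro", items = c("fresh_fish", "tinned_fish")),
    rule("meat_products", "anti",
         items = c("red_meat", "ultra_processed_food")),
    rule("poultry", "anti", items = "white_meat"),
    rule("full_fat_dairy", "anti",
         items = c("cow_milk", "milk_products", "fresh_cheese",
                   "seasoned_cheese"),
         gate = list(behavior = "dairy_fat", answer = "full_fat")),
    rule("olive_oil", "olive_oil", behavior = "olive_oil"),
    rule("alcohol", "alcohol",
         items = c("wine", "beer", "cocktail", "spirits"))
  )
  names(r) <- vapply(r, `[[`, character(1), "component_id")
  r
}

#' Score one MDS component
#'
#' @param rule A component rule from [mds_rules()].
#' @param intake Servings/week for food components, wine glasses/day for the
#'   alcohol component, or the olive-oil pattern answer (`"regular"`,
#'   `"frequent"`, `"occasional"`) for the olive-oil component.
#' @return Integer score 0-5.
#' @export
#' @examples
#' rules <- mds_rules()
#' mds_component(rules$potatoes, 3) # 5
#' mds_component(rules$alcohol, 2)  # 5
mds_component <- function(rule, intake) {
  if (rule$direction == "olive_oil") {
    return(switch(as.character(intake),
                  regular = 5L, frequent = 4L, occasional = 1L, 0L))
  }
  stopifnot(is.numeric(intake), intake >= 0)
  switch(
    rule$direction,
    pro = {
      monthly <- intake * 4
      as.integer(findInterval(monthly, rule$monthly_bins, left.open = TRUE))
    },
    anti = {
      monthly <- intake * 4
      5L - as.integer(findInterval(monthly, rule$monthly_bins,
                                   left.open = TRUE))
    },
    potato = {
      if (intake < 1) 3L
      else if (intake < 3) 4L
      else if (intake <= 4) 5L
      else if (intake <= 6) 2L
      else if (intake < 7) 1L
      else 0L
    },
    alcohol = {
      if (intake < 3) 5L
      else if (intake < 4) 4L
      else if (intake < 6) 3L
      else if (intake < 7) 2L
      else if (intake <= 7) 1L
      else 0L
    },
    stop("unknown MDS component direction: ", rule$direction)
  )
}

#' Total MedDietScore for a profile
#'
#' Aggregates the profile's item servings (frequencies merged with portion
#' multipliers) into the 11 MDS components and sums the component scores.
#' Weekly drink frequencies are bridged to the alcohol component's wine
#' glasses/day by dividing the weekly drink total by 7. Gated components
#' (non-refined cereals, full-fat dairy) count their intake only when the
#' gating behaviour answer matches, since the questionnaire asks refinement
#' and fat content once per category.
#'
#' @param profile An `ffq_profile`.
#' @param rules Component rules, default [mds_rules()].
#' @param schema The questionnaire schema.
#' @return Object of class `mds_result`: list with `respondent_id`,
#'   `component_scores` (named integer vector) and `total` (0-55).
#' @export
mds_total <- function(profile, rules = mds_rules(), schema = medoc_schema()) {
  freqs <- profile$frequencies
  comp <- vapply(rules, function(rule) {
    if (rule$direction == "olive_oil") {
      ans <- profile$behaviors[[rule$behavior]]
      return(mds_component(rule, if (is.null(ans)) NA else ans))
    }
    present <- intersect(rule$items, names(freqs))
    if (!length(present)) {
      stop("MDS component '", rule$component_id, "' has no frequency data")
    }
    intake <- sum(vapply(present, function(it) {
      mult <- 1
      if (it %in% names(profile$portions)) {
        lbl <- profile$portions[[it]]
        if (!is.na(lbl)) mult <- schema$portion_levels[[lbl]]
      }
      servings_per_week(freqs[[it]], mult)
    }, numeric(1)))
    if (!is.null(rule$gate)) {
      ans <- profile$behaviors[[rule$gate$behavior]]
      if (is.null(ans) || is.na(ans) || !identical(ans, rule$gate$answer)) {
        intake <- 0
      }
    }
    if (rule$direction == "alcohol") intake <- intake / 7
    mds_component(rule, intake)
  }, integer(1))
  structure(
    list(respondent_id = profile$respondent_id,
         component_scores = comp, total = sum(comp)),
    class = "mds_result"
  )
}

#' @export
print.mds_result <- function(x, ...) {
  cat("MedDietScore for", x$respondent_id, ":", x$total, "/ 55\n")
  invisible(x)
}

#' The fully Mediterranean-adherent MDS profile
#'
#' Constructs a profile sitting in the top-scoring bin of all 11 MDS
#' components: daily pro-MD foods, no meat, poultry or full-fat dairy,
#' 3 potato servings/week, regular olive-oil use and under 3 wine
#' glasses/day. Its MDS total is the score's printed maximum, 55.
#'
#' @param schema The questionnaire schema.
#' @return An `ffq_profile`.
#' @export
mds_extremal_profile <- function(schema = medoc_schema()) {
  response_profile(
    respondent_id = "mds_extremal",
    frequencies = c(
      breakfast_cereals = 7, fresh_bread = 7, rice_other_cereals = 7,
      pasta = 7,                              # > 18 servings/month
      fruit_medium_large = 14, fruit_small = 7, dried_fruit = 0,
      cooked_vegetables = 7, raw_vegetables = 7, salad = 7,
      legumes = 5, potatoes = 3,
      fresh_fish = 5, tinned_fish = 0,
      red_meat = 0, ultra_processed_food = 0, white_meat = 0,
      cow_milk = 0, milk_products = 0, fresh_cheese = 0, seasoned_cheese = 0,
      wine = 7, beer = 0, cocktail = 0, spirits = 0,  # 1 glass/day
      loaf_bread = 0, bread_substitutes = 0, focaccia_bread = 0, pizza = 0,
      cookies = 0, sweets_cakes_pastries = 0, eggs = 2, soda = 0,
      fast_food = 0, salted_snack = 0, frozen_foods = 0,
      ready_to_eat_meals = 0, breakfast_croissant_cappuccino = 0,
      french_fries = 0
    ),
    behaviors = list(cereal_refinement = "non_refined", dairy_fat = "skimmed",
                     olive_oil = "regular", no_breakfast = "no"),
    age_years = 40, sex = "F"
  )
}
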