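#' Weekly servings from frequency and portion size
#'
#' Merges a weekly consumption frequency with a portion-size multiplier to
#' give standard servings per week.
#'
#' @param frequency Weekly count, non-negative.
#' @param portion_multiplier Dimensionless serving multiplier (> 0);
#'   1 is a standard portion.
#' @return `frequency * portion_multiplier`, in servings/week.
#' @export
#' @examples
#' servings_per_week(7, 0.5) # 3.5
servings_per_week <- function(frequency, portion_multiplier = 1) {
  if (any(frequency < 0, na.rm = TRUE)) {
    stop("frequency must be non-negative")
  }
  if (any(portion_multiplier <= 0, na.rm = TRUE)) {
    stop("portion multiplier must be positive")
  }
  frequency * portion_multiplier
}

#' Score a single matrix row
#'
#' Applies one scoring rule to the relevant input: aggregated weekly
#' servings for frequency rules, a behaviour answer for categorical and
#' threshold rules, a pair of weekly frequencies for the bread comparison,
#' and frequency plus the skips-breakfast answer for the breakfast row.
#' Exactly one branch fires; the behaviour modifier (when the rule has one)
#' adds +0.5 on the favourable branch if the modifier answer is
#' Mediterranean, and -0.5 on the unfavourable branch if it is not.
#' Missing behaviour answers fall on the unfavourable branch (categorical
#' rules) or leave the modifier at 0.
#'
#' @param rule A rule from [medoc_matrix()].
#' @param servings Aggregated servings/week (frequency rules), length-2
#'   numeric `c(lhs, rhs)` (comparison rule), or ignored.
#' @param behavior_answer The driving behaviour answer, where the rule uses
#'   one.
#' @param modifier_answer Answer to the rule's modifier behaviour, if any.
#' @return List: `row_id`, `branch` (`"favorable"`/`"unfavorable"`), `base`
#'   (+1/-1), `modifier_delta` (-0.5/0/+0.5), `points`, `servings`.
#' @export
score_item <- function(rule, servings = NA_real_, behavior_answer = NULL,
                       modifier_answer = NULL) {
  ans <- behavior_answer
  favorable <- switch(
    rule$kind,
    frequency_range = {
      if (is.na(servings)) stop("rule '", rule$row_id, "': servings required")
      if (servings < 0) stop("rule '", rule$row_id, "': negative servings")
      in_favorable_interval(rule, servings)
    },
    comparison = {
      if (length(servings) != 2 || anyNA(servings)) {
        stop("rule '", rule$row_id, "': two frequencies required")
      }
      servings[1] <= servings[2]
    },
    categorical = {
      if (!is.null(ans) && !is.na(ans) && rule$row_id == "olive_oil" &&
          !(ans %in% c("regular", "frequent", "occasional"))) {
        stop("rule '", rule$row_id, "': answer '", ans, "' outside domain")
      }
      !is.null(ans) && !is.na(ans) && ans %in% rule$favorable_answers
    },
    behavior_threshold = {
      v <- suppressWarnings(as.numeric(ans))
      if (length(v) != 1 || is.na(v)) {
        stop("rule '", rule$row_id, "': numeric behaviour answer required")
      }
      if (rule$favorable == "below") v < rule$threshold else v >= rule$threshold
    },
    breakfast = {
      skips <- !is.null(ans) && !is.na(ans) && identical(ans, "yes")
      if (is.na(servings)) stop("rule '", rule$row_id, "': servings required")
      !skips && servings >= rule$fav_lo && servings <= rule$fav_hi
    },
    stop("unknown rule kind: ", rule$kind)
  )
  base <- if (favorable) 1 else -1
  delta <- 0
  if (!is.null(rule$modifier)) {
    m_ans <- modifier_answer
    if (!is.null(m_ans) && !is.na(m_ans)) {
      md_behavior <- m_ans == rule$modifier$favorable_answer
      if (favorable && md_behavior) delta <- rule$modifier$delta
      if (!favorable && !md_behavior) delta <- -rule$modifier$delta
    }
  }
  list(row_id = rule$row_id,
       branch = if (favorable) "favorable" else "unfavorable",
       base = base, modifier_delta = delta, points = base + delta,
       servings = if (rule$kind %in% c("frequency_range", "breakfast")) {
         servings
       } else NA_real_)
}

in_favorable_interval <- function(rule, servings) {
  above_lo <- if (rule$lo_open) servings > rule$fav_lo else servings >= rule$fav_lo
  below_hi <- if (rule$hi_open) servings < rule$fav_hi else servings <= rule$fav_hi
  above_lo && below_hi
}

#' Score one respondent on the MEDOC matrix
#'
#' Aggregates the profile's item frequencies (merged with portion
#' multipliers; a missing portion answer counts as a standard portion) into
#' the matrix's score rows, applies every rule, and assembles the score
#' card: per-row points, the Mediterranean-diet subscore (sum of positive
#' points), the Western-diet subscore (sum of negative points), the raw
#' total, and the raw total rescaled to the published -20..+20 range.
#'
#' @param profile An `ffq_profile`.
#' @param matrix A `medoc_matrix`, default the built-in one.
#' @param schema The questionnaire schema providing the item aggregation map
#'   and portion multipliers.
#' @return Object of class `medoc_scorecard`.
#' @export
score_profile <- function(profile, matrix = medoc_matrix(),
                          schema = medoc_schema()) {
  freqs <- profile$frequencies
  serv_of <- function(items, row_id) {
    present <- intersect(items, names(freqs))
    if (!length(present)) {
      stop("score row '", row_id, "' has no frequency data (items: ",
           paste(items, collapse = ", "), ")")
    }
    sum(vapply(present, function(it) {
      mult <- 1
      if (it %in% names(profile$portions)) {
        lbl <- profile$portions[[it]]
        if (!is.na(lbl)) mult <- schema$portion_levels[[lbl]]
      }
      servings_per_week(freqs[[it]], mult)
    }, numeric(1)))
  }
  scores <- lapply(matrix$rules, function(rule) {
    servings <- NA_real_
    behavior <- NULL
    if (rule$kind %in% c("frequency_range", "breakfast")) {
      servings <- serv_of(schema$aggregation_map[[rule$row_id]], rule$row_id)
    }
    if (rule$kind == "comparison") {
      servings <- c(serv_of(rule$lhs_item, rule$row_id),
                    serv_of(rule$rhs_item, rule$row_id))
    }
    if (!is.null(rule$behavior)) behavior <- profile$behaviors[[rule$behavior]]
    modifier <- if (!is.null(rule$modifier)) {
      profile$behaviors[[rule$modifier$behavior]]
    }
    score_item(rule, servings = servings, behavior_answer = behavior,
               modifier_answer = modifier)
  })
  item_scores <- data.frame(
    row_id = vapply(scores, `[[`, character(1), "row_id"),
    branch = vapply(scores, `[[`, character(1), "branch"),
    base = vapply(scores, `[[`, numeric(1), "base"),
    modifier_delta = vapply(scores, `[[`, numeric(1), "modifier_delta"),
    points = vapply(scores, `[[`, numeric(1), "points"),
    servings = vapply(scores, function(s) s$servings[1], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pts <- item_scores$points
  raw <- sum(pts)
  structure(
    list(respondent_id = profile$respondent_id,
         administration = profile$administration,
         item_scores = item_scores,
         md_subscore = sum(pts[pts > 0]),
         wd_subscore = sum(pts[pts < 0]),
         raw_total = raw,
         normalized_total = normalize_score(raw, matrix),
         raw_min = matrix$raw_min, raw_max = matrix$raw_max),
    class = "medoc_scorecard"
  )
}

#' @export
print.medoc_scorecard <- function(x, ...) {
  cat("MEDOC score card for", x$respondent_id, "\n",
      " MD subscore:", x$md_subscore, " WD subscore:", x$wd_subscore, "\n",
      " raw total:", x$raw_total, "-> normalized:",
      round(x$normalized_total, 2), "(scale -20..+20)\n")
  invisible(x)
}

#' Rescale a raw MEDOC total to the published -20..+20 range
#'
#' The matrix's raw extrema (+/-25.5 for the default matrix) are mapped
#' linearly onto +/-20: `raw * 20 / raw_max`. The map is order-preserving
#' and fixes 0 (a respondent equally pulled by both diets).
#'
#' @param raw Raw total, inside `[raw_min, raw_max]`.
#' @param matrix The scoring matrix defining the extrema.
#' @return The normalized score.
#' @export
normalize_score <- function(raw, matrix = medoc_matrix()) {
  if (any(raw < matrix$raw_min - 1e-9) || any(raw > matrix$raw_max + 1e-9)) {
    stop("raw score outside the matrix range [", matrix$raw_min, ", ",
         matrix$raw_max, "]")
  }
  if (matrix$raw_max == 0) return(raw * 0)
  raw * 20 / matrix$raw_max
}

#' Score a cohort of profiles
#'
#' @param profiles List of `ffq_profile` objects.
#' @param matrix,schema As in [score_profile()].
#' @return data.frame with one row per profile: demographics, the MD and WD
#'   subscores, raw and normalized totals, and one `points.<row>` column per
#'   matrix row.
#' @export
score_cohort <- function(profiles, matrix = medoc_matrix(),
                         schema = medoc_schema()) {
  rows <- lapply(profiles, function(p) {
    card <- score_profile(p, matrix, schema)
    pts <- stats::setNames(as.list(card$item_scores$points),
                           paste0("points.", card$item_scores$row_id))
    as.data.frame(c(list(respondent_id = p$respondent_id,
                         administration = p$administration,
                         age_years = p$age_years, sex = p$sex,
                         md_subscore = card$md_subscore,
                         wd_subscore = card$wd_subscore,
                         raw_total = card$raw_total,
                         normalized_total = card$normalized_total),
                    pts),
                  check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extremal MEDOC profiles
#'
#' Constructs the profile that satisfies every favourable (or every
#' unfavourable) branch of the default scoring matrix together with every
#' favourable (unfavourable) behaviour modifier. These profiles attain the
#' matrix's raw extrema and hence the normalized scores +20 and -20.
#'
#' @param direction `"favorable"` (full Mediterranean adherence) or
#'   `"unfavorable"` (full Western adherence).
#' @param schema The questionnaire schema (all portions are set to the
#'   standard level so frequencies equal servings).
#' @return An `ffq_profile`.
#' @export
medoc_extremal_profile <- function(direction = c("favorable", "unfavorable"),
                                   schema = medoc_schema()) {
  direction <- match.arg(direction)
  if (direction == "favorable") {
    freqs <- c(
      fruit_medium_large = 14, fruit_small = 7, cooked_vegetables = 7,
      raw_vegetables = 4, salad = 4,                      # 36 >= 35
      breakfast_cereals = 7, fresh_bread = 7, rice_other_cereals = 7,
      pasta = 7,                                          # 28 in [21, 42]
      cow_milk = 7, milk_products = 3.5, fresh_cheese = 2,
      seasoned_cheese = 1.5,                              # exactly 14
      eggs = 3, legumes = 3, fresh_fish = 1.5, tinned_fish = 1,
      white_meat = 2, red_meat = 1, ultra_processed_food = 1,
      cookies = 1, sweets_cakes_pastries = 1,
      breakfast_croissant_cappuccino = 1, loaf_bread = 0,
      bread_substitutes = 1, fast_food = 0, salted_snack = 0, soda = 0,
      ready_to_eat_meals = 0, frozen_foods = 0,
      dried_fruit = 2, potatoes = 2, french_fries = 0, focaccia_bread = 1,
      pizza = 1, wine = 3, beer = 0, cocktail = 0, spirits = 0
    )
    behaviors <- list(
      seasonality = "seasonal", cereal_refinement = "non_refined",
      olive_oil = "regular", dairy_fat = "skimmed",
      fish_source = "local_producer", white_meat_source = "local_producer",
      red_meat_source = "local_producer", sweets_type = "homemade",
      no_breakfast = "no", nibbling = "no", spices_instead_of_salt = "yes",
      meal_time_minutes = 45, dining_out_per_week = 1
    )
  } else {
    freqs <- c(
      fruit_medium_large = 2, fruit_small = 1, cooked_vegetables = 2,
      raw_vegetables = 1, salad = 1,                      # 7 < 35
      breakfast_cereals = 1, fresh_bread = 4, rice_other_cereals = 2,
      pasta = 3,                                          # 10 < 21
      cow_milk = 2, milk_products = 1, fresh_cheese = 1,
      seasoned_cheese = 1,                                # 5 != 14
      eggs = 1, legumes = 1, fresh_fish = 0.5, tinned_fish = 0.5,
      white_meat = 3, red_meat = 3, ultra_processed_food = 2,
      cookies = 2, sweets_cakes_pastries = 1,
      breakfast_croissant_cappuccino = 3, loaf_bread = 5,
      bread_substitutes = 2, fast_food = 1, salted_snack = 1, soda = 2,
      ready_to_eat_meals = 1, frozen_foods = 1,
      dried_fruit = 0.5, potatoes = 1, french_fries = 2, focaccia_bread = 2,
      pizza = 2, wine = 0.5, beer = 2, cocktail = 1.5, spirits = 1
    )
    behaviors <- list(
      seasonality = "not_seasonal", cereal_refinement = "refined",
      olive_oil = "occasional", dairy_fat = "full_fat",
      fish_source = "supermarket", white_meat_source = "supermarket",
      red_meat_source = "supermarket", sweets_type = "packed",
      no_breakfast = "yes", nibbling = "yes", spices_instead_of_salt = "no",
      meal_time_minutes = 15, dining_out_per_week = 5
    )
  }
  portion_items <- schema$items$id[schema$items$has_portion_question]
  response_profile(
    respondent_id = paste0("extremal_", direction),
    frequencies = freqs,
    portions = stats::setNames(rep("standard", length(portion_items)),
                               portion_items),
    behaviors = behaviors,
    age_years = 40, sex = "F"
  )
}
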