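#' The built-in MEDOC questionnaire schema
#'
#' Constructs the default schema of the MEDOC food frequency questionnaire:
#' 39 weekly-frequency food items organised in six sections, the qualitative
#' behaviour questions that feed the scoring modifiers, the ordered portion
#' categories with their serving multipliers, and the aggregation map that
#' assigns frequency items to scoring-matrix rows.
#'
#' Sections and item counts: vegetables and fruits (8), cereals (10), dairy
#' products (4), meat and fish (7), drinks (5), unhealthy foods (5).
#' Items with no scoring-matrix row (e.g. dried fruit, potatoes, the alcohol
#' drinks) are retained as informative-only: they are collected, validated
#' and usable by the reference scorers, but contribute no MEDOC points.
#'
#' @return An object of class `ffq_schema`: a list with elements `items`
#'   (data.frame: `id`, `label`, `category`, `has_portion_question`),
#'   `behaviors` (list of behaviour definitions), `aggregation_map`
#'   (named list: score-row id -> character vector of item ids),
#'   `portion_levels` (named numeric vector of serving multipliers, in
#'   ascending order).
#' @seealso [load_schema()], [validate_profile()]
#' @export
#' @examples
#' sch <- medoc_schema()
#' nrow(sch$items) # 39
medoc_schema <- function() {
  items <- rbind(
    item_row("fruit_medium_large", "Medium/large sized fruit", "vegetables_fruits", TRUE),
    item_row("fruit_small", "Small sized fruit", "vegetables_fruits", TRUE),
    item_row("dried_fruit", "Dried fruit", "vegetables_fruits", FALSE),
    item_row("cooked_vegetables", "Cooked vegetables", "vegetables_fruits", TRUE),
    item_row("raw_vegetables", "Raw vegetables", "vegetables_fruits", TRUE),
    item_row("salad", "Salad", "vegetables_fruits", TRUE),
    item_row("potatoes", "Potatoes", "vegetables_fruits", TRUE),
    item_row("french_fries", "French fries", "vegetables_fruits", TRUE),
    item_row("breakfast_cereals", "Breakfast cereals", "cereals", TRUE),
    item_row("loaf_bread", "Loaf bread", "cereals", TRUE),
    item_row("fresh_bread", "Fresh bread", "cereals", TRUE),
    item_row("bread_substitutes", "Bread substitutes", "cereals", TRUE),
    item_row("focaccia_bread", "Focaccia bread", "cereals", TRUE),
    item_row("pizza", "Pizza", "cereals", TRUE),
    item_row("rice_other_cereals", "Rice and other cereals", "cereals", TRUE),
    item_row("pasta", "Pasta", "cereals", TRUE),
    item_row("cookies", "Cookies", "cereals", TRUE),
    item_row("sweets_cakes_pastries", "Sweets/cakes/pastries", "cereals", TRUE),
    item_row("cow_milk", "Cow milk", "dairy", TRUE),
    item_row("milk_products", "Milk products", "dairy", TRUE),
    item_row("fresh_cheese", "Fresh cheese", "dairy", TRUE),
    item_row("seasoned_cheese", "Seasoned cheese", "dairy", TRUE),
    item_row("white_meat", "White meat", "meat_fish", TRUE),
    item_row("red_meat", "Red meat", "meat_fish", TRUE),
    item_row("ultra_processed_food", "Ultra-processed food", "meat_fish", TRUE),
    item_row("fresh_fish", "Fresh fish", "meat_fish", TRUE),
    item_row("tinned_fish", "Tinned fish", "meat_fish", TRUE),
    item_row("eggs", "Eggs", "meat_fish", TRUE),
    item_row("legumes", "Legumes", "meat_fish", TRUE),
    item_row("soda", "Soda", "drinks", TRUE),
    item_row("wine", "Wine", "drinks", TRUE),
    item_row("beer", "Beer", "drinks", TRUE),
    item_row("cocktail", "Cocktail", "drinks", TRUE),
    item_row("spirits", "Spirits", "drinks", FALSE),
    item_row("fast_food", "Fast food", "unhealthy", TRUE),
    item_row("salted_snack", "Salted snack", "unhealthy", TRUE),
    item_row("frozen_foods", "Frozen foods", "unhealthy", FALSE),
    item_row("ready_to_eat_meals", "Ready-to-eat meals", "unhealthy", FALSE),
    item_row("breakfast_croissant_cappuccino",
             "Breakfast with croissant and cappuccino", "unhealthy", FALSE)
  )

  behaviors <- list(
    behavior_def("seasonality", "Fruit/vegetables bought in season",
                 c("seasonal", "not_seasonal"), favorable = "seasonal"),
    behavior_def("cereal_refinement", "Cereals mostly refined or non-refined",
                 c("non_refined", "refined"), favorable = "non_refined"),
    behavior_def("olive_oil", "Olive oil consumption",
                 c("regular", "frequent", "occasional"), favorable = "regular"),
    behavior_def("dairy_fat", "Dairy mostly skimmed or full fat",
                 c("skimmed", "full_fat"), favorable = "skimmed"),
    behavior_def("fish_source", "Fish bought from",
                 c("local_producer", "supermarket"), favorable = "local_producer"),
    behavior_def("white_meat_source", "White meat bought from",
                 c("local_producer", "supermarket"), favorable = "local_producer"),
    behavior_def("red_meat_source", "Red meat bought from",
                 c("local_producer", "supermarket"), favorable = "local_producer"),
    behavior_def("sweets_type", "Sweets homemade or packed",
                 c("homemade", "packed"), favorable = "homemade"),
    behavior_def("no_breakfast", "Skips breakfast",
                 c("yes", "no"), favorable = "no"),
    behavior_def("nibbling", "Nibbles between meals",
                 c("yes", "no"), favorable = "no"),
    behavior_def("spices_instead_of_salt", "Adds spices instead of salt",
                 c("yes", "no"), favorable = "yes"),
    behavior_def("meal_time_minutes", "Time dedicated to meals (minutes)",
                 numeric_domain = c(0, Inf)),
    behavior_def("dining_out_per_week", "Dining out or takeaway (times/week)",
                 numeric_domain = c(0, Inf))
  )
  names(behaviors) <- vapply(behaviors, `[[`, character(1), "id")

  aggregation_map <- list(
    fruits_vegetables = c("fruit_medium_large", "fruit_small",
                          "cooked_vegetables", "raw_vegetables", "salad"),
    cereals = c("breakfast_cereals", "fresh_bread", "rice_other_cereals", "pasta"),
    dairy = c("cow_milk", "milk_products", "fresh_cheese", "seasoned_cheese"),
    fish = c("fresh_fish", "tinned_fish"),
    white_meat = "white_meat",
    red_meat = "red_meat",
    processed_meat = "ultra_processed_food",
    eggs = "eggs",
    legumes = "legumes",
    sweets = c("cookies", "sweets_cakes_pastries"),
    breakfast = "breakfast_croissant_cappuccino",
    bread_substitutes = "bread_substitutes",
    fast_food = "fast_food",
    salted_snacks = "salted_snack",
    sodas = "soda",
    ready_to_eat = c("ready_to_eat_meals", "frozen_foods")
  )

  schema <- structure(
    list(
      items = items,
      behaviors = behaviors,
      aggregation_map = aggregation_map,
      portion_levels = c(small = 0.5, standard = 1.0, large = 1.5)
    ),
    class = "ffq_schema"
  )
  check_schema(schema)
  schema
}

item_row <- function(id, label, category, has_portion) {
  data.frame(id = id, label = label, category = category,
             has_portion_question = has_portion, stringsAsFactors = FALSE)
}

behavior_def <- function(id, label, answers = NULL, favorable = NULL,
                         numeric_domain = NULL) {
  stopifnot(!is.null(answers) || !is.null(numeric_domain))
  list(id = id, label = label, answers = answers, favorable = favorable,
       numeric_domain = numeric_domain,
       type = if (is.null(numeric_domain)) "categorical" else "numeric")
}

#' Load a questionnaire schema
#'
#' Reads a questionnaire schema from a JSON file, or returns the built-in
#' MEDOC schema when `path = "builtin"`. The JSON layout mirrors the schema
#' object: `items` (array of objects with `id`, `label`, `category`,
#' `has_portion_question`), `behaviors`, `aggregation_map`, `portion_levels`.
#'
#' @param path Path to a JSON schema file, or the token `"builtin"`.
#' @return An `ffq_schema` object; all structural invariants (unique item
#'   ids, valid categories, positive ordered portion multipliers, aggregation
#'   map referencing known items) are checked and violations raise errors.
#' @export
load_schema <- function(path = "builtin") {
  if (identical(path, "builtin")) return(medoc_schema())
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("items", "portion_levels")) {
    if (is.null(raw[[key]])) stop("malformed schema file: missing key '", key, "'")
  }
  items <- do.call(rbind, lapply(raw$items, function(it) {
    for (key in c("id", "label", "category")) {
      if (is.null(it[[key]])) {
        stop("malformed schema file: item missing key '", key, "'")
      }
    }
    item_row(it$id, it$label, it$category, isTRUE(it$has_portion_question))
  }))
  behaviors <- lapply(raw$behaviors, function(b) {
    behavior_def(b$id, b$label %||% b$id,
                 answers = unlist(b$answers),
                 favorable = b$favorable,
                 numeric_domain = unlist(b$numeric_domain))
  })
  names(behaviors) <- vapply(behaviors, `[[`, character(1), "id")
  schema <- structure(
    list(
      items = items,
      behaviors = behaviors,
      aggregation_map = lapply(raw$aggregation_map, unlist),
      portion_levels = unlist(raw$portion_levels)
    ),
    class = "ffq_schema"
  )
  check_schema(schema, require_full = FALSE)
  schema
}

# Structural invariants; require_full additionally pins the builtin shape
# (39 items) so a corrupted builtin cannot pass silently.
check_schema <- function(schema, require_full = TRUE) {
  items <- schema$items
  if (anyDuplicated(items$id)) {
    stop("duplicate item id(s): ",
         paste(unique(items$id[duplicated(items$id)]), collapse = ", "))
  }
  valid_cat <- c("vegetables_fruits", "cereals", "dairy", "meat_fish",
                 "drinks", "unhealthy")
  bad <- setdiff(items$category, valid_cat)
  if (length(bad)) stop("unknown item category: ", paste(bad, collapse = ", "))
  pl <- schema$portion_levels
  if (any(pl <= 0) || is.unsorted(pl, strictly = TRUE)) {
    stop("portion multipliers must be strictly positive and increasing")
  }
  unknown <- setdiff(unlist(schema$aggregation_map), items$id)
  if (length(unknown)) {
    stop("aggregation map references unknown item(s): ",
         paste(unknown, collapse = ", "))
  }
  multi <- table(unlist(schema$aggregation_map))
  if (any(multi > 1)) {
    stop("item(s) mapped to more than one score row: ",
         paste(names(multi)[multi > 1], collapse = ", "))
  }
  if (require_full && nrow(items) != 39L) {
    stop("builtin schema must contain exactly 39 items, found ", nrow(items))
  }
  invisible(schema)
}

#' Write a questionnaire schema to JSON
#'
#' @param schema An `ffq_schema` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  out <- list(
    items = lapply(seq_len(nrow(schema$items)), function(i) {
      as.list(schema$items[i, , drop = FALSE])
    }),
    behaviors = unname(schema$behaviors),
    aggregation_map = schema$aggregation_map,
    portion_levels = as.list(schema$portion_levels)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat("FFQ schema:", nrow(x$items), "frequency items,",
      length(x$behaviors), "behaviour questions,",
      length(x$aggregation_map), "score rows mapped\n")
  print(table(x$items$category))
  invisible(x)
}

#' Age stratum of a respondent
#'
#' The validation design splits respondents at 30 years: young adults
#' (age <= 30) versus adults/elderly (age > 30).
#'
#' @param age_years Numeric vector of ages.
#' @return Factor with levels `"young_adults"` and `"adults_elderly"`.
#' @export
age_stratum <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years >= 0, na.rm = TRUE))
  factor(ifelse(age_years <= 30, "young_adults", "adults_elderly"),
         levels = c("young_adults", "adults_elderly"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
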