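#' The built-in MEDOC scoring matrix
#'
#' Builds the 22-row scoring matrix of the MEDOC adherence score. Each row
#' awards +1 when the respondent's intake (or behaviour) falls in the
#' Mediterranean-diet recommended branch and -1 otherwise; seven rows carry a
#' behaviour modifier worth an extra +0.5 on the favourable branch when the
#' matching behaviour is Mediterranean (e.g. seasonal produce) and an extra
#' -0.5 on the unfavourable branch when it is not, so item points lie in
#' \{-1.5, -1, +1, +1.5\}.
#'
#' Frequency cut-offs printed per day are stored as weekly servings
#' (multiplied by 7), since all frequency questions are asked per week.
#' Two rows need a reading decision: the red-meat row's branches overlap as
#' printed ("<2" favourable, ">1" unfavourable) and are resolved as
#' favourable iff servings < 2; the white-meat row's modifier column is
#' uninformative as printed and follows the fish/red-meat local-producer
#' pattern.
#'
#' @return Object of class `medoc_matrix`: list with `rules` (named list of
#'   scoring rules) and `raw_min`, `raw_max` (the extreme attainable raw
#'   totals, here -25.5 and +25.5).
#' @seealso [score_profile()], [matrix_extrema()]
#' @export
medoc_matrix <- function() {
  r <- list(
    freq_rule("fruits_vegetables", "Fruits/Vegetables",
              fav_lo = 5 * 7, fav_hi = Inf,
              modifier = mod("seasonality", "seasonal")),
    freq_rule("cereals", "Cereals", fav_lo = 3 * 7, fav_hi = 6 * 7,
              modifier = mod("cereal_refinement", "non_refined")),
    categorical_rule("olive_oil", "Olive oil", behavior = "olive_oil",
                     favorable_answers = c("regular", "frequent")),
    freq_rule("dairy", "Dairy", fav_lo = 2 * 7, fav_hi = 2 * 7,
              modifier = mod("dairy_fat", "skimmed")),
    freq_rule("eggs", "Eggs", fav_lo = 2, fav_hi = 4),
    freq_rule("legumes", "Legumes", fav_lo = 2, fav_hi = Inf),
    freq_rule("fish", "Fish", fav_lo = 2, fav_hi = Inf,
              modifier = mod("fish_source", "local_producer")),
    freq_rule("white_meat", "White meat", fav_lo = 2, fav_hi = 2,
              modifier = mod("white_meat_source", "local_producer")),
    freq_rule("red_meat", "Red meat", fav_lo = 0, fav_hi = 2, hi_open = TRUE,
              modifier = mod("red_meat_source", "local_producer")),
    freq_rule("processed_meat", "Processed meat", fav_lo = 0, fav_hi = 1),
    freq_rule("sweets", "Sweets/cakes/pastries", fav_lo = 0, fav_hi = 2,
              modifier = mod("sweets_type", "homemade")),
    breakfast_rule(),
    threshold_rule("meal_time", "Time dedicated to meals",
                   behavior = "meal_time_minutes", threshold = 30,
                   favorable = "at_or_above"),
    categorical_rule("nibbling", "Nibbling", behavior = "nibbling",
                     favorable_answers = "no"),
    categorical_rule("spices", "Adding spices instead of salt",
                     behavior = "spices_instead_of_salt",
                     favorable_answers = "yes"),
    threshold_rule("dining_out", "Dining out/takeaway",
                   behavior = "dining_out_per_week", threshold = 4,
                   favorable = "below"),
    comparison_rule("bread", "Bread (loaf vs fresh)",
                    lhs_item = "loaf_bread", rhs_item = "fresh_bread"),
    freq_rule("bread_substitutes", "Bread substitutes", fav_lo = 0, fav_hi = 1),
    freq_rule("fast_food", "Fast food", fav_lo = 0, fav_hi = 0),
    freq_rule("salted_snacks", "Salted snacks", fav_lo = 0, fav_hi = 0),
    freq_rule("sodas", "Sodas", fav_lo = 0, fav_hi = 0),
    freq_rule("ready_to_eat", "Ready-to-eat meals/Frozen food",
              fav_lo = 0, fav_hi = 1)
  )
  names(r) <- vapply(r, `[[`, character(1), "row_id")
  build_matrix(r)
}

build_matrix <- function(rules) {
  m <- structure(list(rules = rules), class = "medoc_matrix")
  ext <- matrix_extrema(m)
  m$raw_min <- ext[["raw_min"]]
  m$raw_max <- ext[["raw_max"]]
  m
}

freq_rule <- function(row_id, label, fav_lo, fav_hi,
                      lo_open = FALSE, hi_open = FALSE, modifier = NULL) {
  list(row_id = row_id, label = label, kind = "frequency_range",
       fav_lo = fav_lo, fav_hi = fav_hi,
       lo_open = lo_open, hi_open = hi_open, modifier = modifier)
}

categorical_rule <- function(row_id, label, behavior, favorable_answers) {
  list(row_id = row_id, label = label, kind = "categorical",
       behavior = behavior, favorable_answers = favorable_answers,
       modifier = NULL)
}

threshold_rule <- function(row_id, label, behavior, threshold, favorable) {
  list(row_id = row_id, label = label, kind = "behavior_threshold",
       behavior = behavior, threshold = threshold,
       favorable = match.arg(favorable, c("below", "at_or_above")),
       modifier = NULL)
}

comparison_rule <- function(row_id, label, lhs_item, rhs_item) {
  # favourable iff weekly frequency of lhs_item <= rhs_item
  list(row_id = row_id, label = label, kind = "comparison",
       lhs_item = lhs_item, rhs_item = rhs_item, modifier = NULL)
}

breakfast_rule <- function() {
  # favourable iff the respondent has breakfast and the croissant-and-
  # cappuccino frequency is 0-1 per week; skipping breakfast entirely is
  # the unfavourable branch regardless of frequency
  list(row_id = "breakfast", label = "Breakfast with croissant and cappuccino",
       kind = "breakfast", fav_lo = 0, fav_hi = 1,
       behavior = "no_breakfast", modifier = NULL)
}

mod <- function(behavior, favorable_answer) {
  list(behavior = behavior, favorable_answer = favorable_answer, delta = 0.5)
}

#' Raw score extrema of a scoring matrix
#'
#' Computes the most negative and most positive attainable raw totals by
#' enumerating, for every rule, its branch/modifier point values and summing
#' the per-rule minima and maxima (rules score independently, so the sum of
#' per-rule extrema is the matrix extremum).
#'
#' @param matrix A `medoc_matrix` (or a bare list with a `rules` element).
#' @return Named numeric vector `c(raw_min = ..., raw_max = ...)`; by the
#'   symmetry of the matrix (every branch has a mirrored negative branch)
#'   `raw_min == -raw_max`.
#' @export
matrix_extrema <- function(matrix) {
  maxima <- vapply(matrix$rules, function(rule) {
    1 + if (is.null(rule$modifier)) 0 else rule$modifier$delta
  }, numeric(1))
  if (!length(maxima)) maxima <- 0
  c(raw_min = -sum(maxima), raw_max = sum(maxima))
}

#' @export
print.medoc_matrix <- function(x, ...) {
  cat("MEDOC scoring matrix:", length(x$rules), "rows; raw range [",
      x$raw_min, ",", x$raw_max, "]\n")
  invisible(x)
}

#' Read / write a scoring matrix as JSON
#'
#' The JSON layout mirrors the rule fields, so alternative cut-offs can be
#' evaluated without code changes.
#'
#' @param path File path.
#' @return `read_matrix()` returns a `medoc_matrix`; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw$rules, function(r) {
    r$favorable_answers <- unlist(r$favorable_answers)
    for (f in c("fav_lo", "fav_hi")) {
      if (!is.null(r[[f]]) && is.character(r[[f]])) {
        r[[f]] <- as.numeric(r[[f]]) # "Inf" round-trips as string
      }
    }
    r
  })
  names(rules) <- vapply(rules, `[[`, character(1), "row_id")
  build_matrix(rules)
}

#' @rdname read_matrix
#' @param matrix A `medoc_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  out <- list(rules = unname(lapply(matrix$rules, function(r) {
    for (f in c("fav_lo", "fav_hi")) {
      if (!is.null(r[[f]]) && is.infinite(r[[f]])) r[[f]] <- as.character(r[[f]])
    }
    r
  })))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
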