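#' MEDILITE group rules
#'
#' The MEDILITE score is a literature-based Mediterranean-diet adherence
#' score over nine food groups, each scored 0-2 for a total of 0-18. Five
#' groups typical of the Mediterranean diet award 2 points to the highest
#' consumption level, 1 to the middle and 0 to the lowest; non-Mediterranean
#' groups reverse the pattern (2 for the lowest level); alcohol awards 2 to
#' the middle level, 1 to the lowest and 0 to the highest (moderation
#' scores best).
#'
#' Group membership and the two cut points separating the lowest/middle/
#' highest consumption levels are configuration, not code: the defaults
#' ship in `extdata/medilite_rules.json` and an alternative file can be
#' supplied. Olive oil is carried by the questionnaire as a consumption-
#' pattern answer and treated as a Mediterranean-typical group with levels
#' regular > frequent > occasional.
#'
#' @param path Path to a rules JSON file; `NULL` loads the packaged default.
#' @return Named list of group rules.
#' @export
medilite_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "medilite_rules.json", package = "medocr",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw$groups, function(g) {
    list(group_id = g$group_id, group_class = g$group_class,
         items = unlist(g$items), behavior = g$behavior,
         cuts = unlist(g$cuts), unit = g$unit %||% "servings_per_week")
  })
  names(rules) <- vapply(rules, `[[`, character(1), "group_id")
  rules
}

#' Consumption level of a group intake
#'
#' @param intake Aggregated intake in the rule's unit.
#' @param rule A group rule with two ordered `cuts`.
#' @return `"lowest"` (below the first cut), `"middle"` (between the cuts,
#'   inclusive) or `"highest"` (above the second cut).
#' @export
medilite_level <- function(intake, rule) {
  stopifnot(length(rule$cuts) == 2, rule$cuts[1] <= rule$cuts[2])
  if (intake < rule$cuts[1]) "lowest"
  else if (intake <= rule$cuts[2]) "middle"
  else "highest"
}

#' Points for one MEDILITE group
#'
#' @param rule A group rule (only `group_class` is used).
#' @param level `"lowest"`, `"middle"` or `"highest"`.
#' @return Integer points 0-2.
#' @export
#' @examples
#' medilite_component(list(group_class = "alcohol"), "middle") # 2
medilite_component <- function(rule, level) {
  level <- match.arg(level, c("lowest", "middle", "highest"))
  idx <- match(level, c("lowest", "middle", "highest"))
  pts <- switch(rule$group_class,
                md_typical = c(0L, 1L, 2L),
                non_md = c(2L, 1L, 0L),
                alcohol = c(1L, 2L, 0L),
                stop("unknown MEDILITE group class: ", rule$group_class))
  pts[idx]
}

#' Total MEDILITE score for a profile
#'
#' Aggregates item servings into the nine groups (weekly drink frequencies
#' divided by 7 for the alcohol group), assigns each group's consumption
#' level from its cut points, and sums the group points.
#'
#' @param profile An `ffq_profile`.
#' @param rules Group rules, default [medilite_rules()].
#' @param schema The questionnaire schema.
#' @return Object of class `medilite_result`: `respondent_id`,
#'   `group_points` (named integer vector), `total` (0-18).
#' @export
medilite_total <- function(profile, rules = medilite_rules(),
                           schema = medoc_schema()) {
  freqs <- profile$frequencies
  pts <- vapply(rules, function(rule) {
    if (!is.null(rule$behavior)) {
      ans <- profile$behaviors[[rule$behavior]]
      level <- switch(as.character(ans %||% "missing"),
                      regular = "highest", frequent = "middle", "lowest")
      return(medilite_component(rule, level))
    }
    present <- intersect(rule$items, names(freqs))
    if (!length(present)) {
      stop("MEDILITE group '", rule$group_id, "' has no frequency data")
    }
    intake <- sum(vapply(present, function(it) {
      mult <- 1
      if (it %in% names(profile$portions)) {
        lbl <- profile$portions[[it]]
        if (!is.na(lbl)) mult <- schema$portion_levels[[lbl]]
      }
      servings_per_week(freqs[[it]], mult)
    }, numeric(1)))
    if (identical(rule$unit, "glasses_per_day")) intake <- intake / 7
    medilite_component(rule, medilite_level(intake, rule))
  }, integer(1))
  structure(
    list(respondent_id = profile$respondent_id,
         group_points = pts, total = sum(pts)),
    class = "medilite_result"
  )
}

#' @export
print.medilite_result <- function(x, ...) {
  cat("MEDILITE score for", x$respondent_id, ":", x$total, "/ 18\n")
  invisible(x)
}
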