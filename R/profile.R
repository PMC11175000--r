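#' Construct a respondent profile
#'
#' A profile holds one respondent's answers to one administration of the
#' questionnaire: weekly consumption frequencies, optional portion-size
#' categories, behaviour answers, and demographics.
#'
#' @param respondent_id Character scalar.
#' @param frequencies Named numeric vector, item id -> weekly count
#'   (non-negative reals; half servings allowed).
#' @param portions Named character vector, item id -> portion label
#'   (optional per item).
#' @param behaviors Named list, behaviour id -> answer (character for
#'   categorical behaviours, numeric for numeric ones).
#' @param age_years,sex,height_cm,weight_kg Demographics; height and weight
#'   are optional.
#' @param administration `"T0"` (first) or `"T1"` (retest).
#' @return Object of class `ffq_profile`.
#' @export
response_profile <- function(respondent_id, frequencies,
                             portions = character(0), behaviors = list(),
                             age_years = NA_real_, sex = NA_character_,
                             height_cm = NA_real_, weight_kg = NA_real_,
                             administration = "T0") {
  structure(
    list(respondent_id = as.character(respondent_id),
         age_years = as.numeric(age_years), sex = as.character(sex),
         height_cm = as.numeric(height_cm), weight_kg = as.numeric(weight_kg),
         frequencies = frequencies, portions = portions,
         behaviors = behaviors, administration = administration),
    class = "ffq_profile"
  )
}

#' @export
print.ffq_profile <- function(x, ...) {
  cat("FFQ profile", x$respondent_id, paste0("(", x$administration, ")"),
      "- age", x$age_years, "-", length(x$frequencies), "frequencies,",
      length(x$portions), "portions,", length(x$behaviors), "behaviours\n")
  invisible(x)
}

#' Validate respondent profiles against a schema
#'
#' Checks each profile for structural problems: negative or non-numeric
#' frequencies, unknown item or behaviour ids, portion labels outside the
#' schema's levels, behaviour answers outside their domains, missing or
#' negative age. Problems are returned as data, not raised as conditions.
#'
#' @param profiles A single `ffq_profile` or a list of them.
#' @param schema An `ffq_schema`, default the built-in MEDOC schema.
#' @return Object of class `ffq_validation`: list with `errors` and
#'   `warnings` (data.frames with columns `respondent_id`, `field`,
#'   `message`) and `n_valid`, the number of profiles with no errors.
#' @export
validate_profile <- function(profiles, schema = medoc_schema()) {
  if (inherits(profiles, "ffq_profile")) profiles <- list(profiles)
  errors <- list()
  warnings <- list()
  note <- function(store, id, field, msg) {
    c(store, list(data.frame(respondent_id = id, field = field,
                             message = msg, stringsAsFactors = FALSE)))
  }
  n_valid <- 0L
  for (p in profiles) {
    n_err <- length(errors)
    id <- p$respondent_id
    if (!is.na(p$age_years) && p$age_years < 0) {
      errors <- note(errors, id, "age_years", "age must be non-negative")
    }
    f <- p$frequencies
    unknown <- setdiff(names(f), schema$items$id)
    if (length(unknown)) {
      errors <- note(errors, id, paste(unknown, collapse = ","),
                     "unknown frequency item id")
    }
    bad <- names(f)[!is.na(f) & f < 0]
    for (b in bad) {
      errors <- note(errors, id, b, "negative weekly frequency")
    }
    po <- p$portions
    unknown <- setdiff(names(po), schema$items$id)
    if (length(unknown)) {
      errors <- note(errors, id, paste(unknown, collapse = ","),
                     "unknown portion item id")
    }
    bad <- names(po)[!is.na(po) & !(po %in% names(schema$portion_levels))]
    for (b in bad) {
      errors <- note(errors, id, b, paste0("portion label '", po[[b]],
                                           "' not a schema portion level"))
    }
    for (bid in names(p$behaviors)) {
      bdef <- schema$behaviors[[bid]]
      ans <- p$behaviors[[bid]]
      if (is.null(bdef)) {
        errors <- note(errors, id, bid, "unknown behavior id")
      } else if (bdef$type == "categorical") {
        if (!is.na(ans) && !(ans %in% bdef$answers)) {
          errors <- note(errors, id, bid,
                         paste0("answer '", ans, "' outside domain"))
        }
      } else if (!is.na(ans) &&
                 (!is.numeric(ans) || ans < bdef$numeric_domain[1] ||
                  ans > bdef$numeric_domain[2])) {
        errors <- note(errors, id, bid, "numeric answer outside domain")
      }
    }
    missing_portion <- setdiff(
      intersect(names(f), schema$items$id[schema$items$has_portion_question]),
      names(po))
    if (length(missing_portion)) {
      warnings <- note(warnings, id, paste(missing_portion, collapse = ","),
                       "missing portion answer; standard portion assumed")
    }
    if (length(errors) == n_err) n_valid <- n_valid + 1L
  }
  empty <- data.frame(respondent_id = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  structure(
    list(errors = if (length(errors)) do.call(rbind, errors) else empty,
         warnings = if (length(warnings)) do.call(rbind, warnings) else empty,
         n_valid = n_valid),
    class = "ffq_validation"
  )
}

#' @export
print.ffq_validation <- function(x, ...) {
  cat("Validation:", x$n_valid, "valid profile(s),",
      nrow(x$errors), "error(s),", nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) print(x$errors, row.names = FALSE)
  invisible(x)
}

#' Read respondent profiles from CSV or JSON
#'
#' CSV files carry one row per respondent-administration with columns
#' `respondent_id`, `administration`, `age_years`, `sex`, `height_cm`,
#' `weight_kg`, then `freq.<item>`, `portion.<item>` and `behavior.<id>`
#' columns. JSON files carry an array of profile objects with the same
#' field names as [response_profile()]. Missing optional cells are recorded
#' as absent, never imputed.
#'
#' @param path Input file; format chosen by extension (`.json` vs CSV).
#' @param schema Schema used to check column names.
#' @return List of `ffq_profile` objects.
#' @export
read_responses <- function(path, schema = medoc_schema()) {
  if (!file.exists(path)) stop("cannot read responses: file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(read_responses_json(path, schema))
  }
  # read everything as character: type conversion is schema-driven below
  # (plain read.csv would parse a column of "F" sexes as logical)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  demo_cols <- c("respondent_id", "administration", "age_years", "sex",
                 "height_cm", "weight_kg")
  prefixed <- grepl("^(freq|portion|behavior)\\.", names(df))
  unmatched <- setdiff(names(df)[!prefixed], demo_cols)
  stem <- sub("^(freq|portion)\\.", "", names(df)[prefixed])
  kind <- sub("\\..*$", "", names(df)[prefixed])
  bad_item <- stem[kind %in% c("freq", "portion") & !(stem %in% schema$items$id)]
  bstem <- sub("^behavior\\.", "", names(df)[prefixed])
  bad_beh <- bstem[kind == "behavior" & !(bstem %in% names(schema$behaviors))]
  if (length(unmatched) || length(bad_item) || length(bad_beh)) {
    stop("unknown column(s): ",
         paste(unique(c(unmatched, bad_item, bad_beh)), collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    take <- function(prefix) {
      cols <- grep(paste0("^", prefix, "\\."), names(df), value = TRUE)
      vals <- unlist(row[cols], use.names = FALSE)
      names(vals) <- sub(paste0("^", prefix, "\\."), "", cols)
      vals[!is.na(vals) & vals != ""]
    }
    freq <- take("freq")
    freq <- stats::setNames(as.numeric(freq), names(freq))
    beh_raw <- take("behavior")
    beh <- lapply(names(beh_raw), function(bid) {
      if (schema$behaviors[[bid]]$type == "numeric") {
        as.numeric(beh_raw[[bid]])
      } else {
        as.character(beh_raw[[bid]])
      }
    })
    names(beh) <- names(beh_raw)
    num_of <- function(col) {
      if (col %in% names(row) && !is.na(row[[col]]) && row[[col]] != "") {
        as.numeric(row[[col]])
      } else NA_real_
    }
    response_profile(
      respondent_id = row$respondent_id,
      frequencies = freq,
      portions = take("portion"),
      behaviors = beh,
      age_years = num_of("age_years"),
      sex = if ("sex" %in% names(row)) row$sex else NA,
      height_cm = num_of("height_cm"),
      weight_kg = num_of("weight_kg"),
      administration = if ("administration" %in% names(row)) {
        row$administration
      } else "T0"
    )
  })
}

read_responses_json <- function(path, schema) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    beh <- lapply(p$behaviors, function(a) {
      if (is.numeric(a)) as.numeric(a) else as.character(a)
    })
    response_profile(
      respondent_id = p$respondent_id,
      frequencies = unlist(p$frequencies),
      portions = unlist(p$portions) %||% character(0),
      behaviors = beh %||% list(),
      age_years = p$age_years %||% NA,
      sex = p$sex %||% NA,
      height_cm = p$height_cm %||% NA,
      weight_kg = p$weight_kg %||% NA,
      administration = p$administration %||% "T0"
    )
  })
}

#' Write respondent profiles to CSV or JSON
#'
#' Inverse of [read_responses()]. Columns (CSV) and keys (JSON) are emitted
#' in a canonical order (demographics, then frequency, portion and behaviour
#' columns in schema order) so that a write-read-write cycle is stable.
#'
#' @param profiles List of `ffq_profile` objects.
#' @param path Output file; format chosen by extension.
#' @param schema Schema providing the canonical item ordering.
#' @return `path`, invisibly.
#' @export
write_responses <- function(profiles, path, schema = medoc_schema()) {
  if (inherits(profiles, "ffq_profile")) profiles <- list(profiles)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- lapply(profiles, function(p) {
      p <- unclass(p)
      p$frequencies <- as.list(p$frequencies)
      p$portions <- as.list(p$portions)
      p
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  item_ids <- schema$items$id
  beh_ids <- names(schema$behaviors)
  rows <- lapply(profiles, function(p) {
    row <- list(respondent_id = p$respondent_id,
                administration = p$administration,
                age_years = p$age_years, sex = p$sex,
                height_cm = p$height_cm, weight_kg = p$weight_kg)
    for (it in item_ids) {
      row[[paste0("freq.", it)]] <-
        if (it %in% names(p$frequencies)) p$frequencies[[it]] else NA
      if (schema$items$has_portion_question[schema$items$id == it]) {
        row[[paste0("portion.", it)]] <-
          if (it %in% names(p$portions)) p$portions[[it]] else NA
      }
    }
    for (b in beh_ids) {
      row[[paste0("behavior.", b)]] <-
        if (b %in% names(p$behaviors)) p$behaviors[[b]] else NA
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
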