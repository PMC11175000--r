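#' Score a cohort on all three instruments
#'
#' Convenience wrapper computing, per profile, the MEDOC score card plus the
#' MedDietScore and MEDILITE totals, as used by the validity workflow.
#'
#' @param profiles List of `ffq_profile` objects.
#' @param matrix,schema As in [score_profile()].
#' @param mds,medilite Rule sets for the two reference scorers.
#' @return data.frame with one row per profile: `respondent_id`,
#'   `age_years`, `stratum`, `md_subscore`, `wd_subscore`, `raw_total`,
#'   `normalized_total`, `mds_total`, `medilite_total`.
#' @export
compute_scores <- function(profiles, matrix = medoc_matrix(),
                           schema = medoc_schema(), mds = mds_rules(),
                           medilite = medilite_rules()) {
  rows <- lapply(profiles, function(p) {
    card <- score_profile(p, matrix, schema)
    data.frame(
      respondent_id = p$respondent_id,
      age_years = p$age_years,
      stratum = as.character(age_stratum(p$age_years)),
      md_subscore = card$md_subscore,
      wd_subscore = card$wd_subscore,
      raw_total = card$raw_total,
      normalized_total = card$normalized_total,
      mds_total = mds_total(p, mds, schema)$total,
      medilite_total = medilite_total(p, medilite, schema)$total,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Inter-instrument validity correlations
#'
#' Pearson correlation (with Fisher-z 95% interval) between two score
#' columns of a cohort score table, per age stratum -- the workflow used to
#' check that the combined score's Mediterranean part tracks the reference
#' Mediterranean-diet scores.
#'
#' @param scores data.frame from [compute_scores()] (or any table with the
#'   two score columns and `age_years`).
#' @param x,y Names of the two score columns to correlate (default: the
#'   MD-positive subscore of the combined score against the MedDietScore).
#' @param stratify_by_age Split at the age-30 boundary?
#' @param alpha Two-sided error level.
#' @return data.frame with one row per stratum: `stratum`, `x`, `y`, `n`,
#'   `r`, `ci_low`, `ci_high`, `p_value`.
#' @export
validity_report <- function(scores, x = "md_subscore", y = "mds_total",
                            stratify_by_age = TRUE, alpha = 0.05) {
  stopifnot(all(c(x, y) %in% names(scores)))
  strata <- if (stratify_by_age) {
    split(scores, age_stratum(scores$age_years))
  } else {
    list(all = scores)
  }
  rows <- lapply(names(strata), function(sname) {
    s <- strata[[sname]]
    if (nrow(s) < 3) stop("stratum '", sname, "' has fewer than 3 respondents")
    est <- pearson_with_ci(s[[x]], s[[y]], alpha)
    ct <- stats::cor.test(s[[x]], s[[y]])
    data.frame(stratum = sname, x = x, y = y, n = nrow(s),
               r = est$estimate, ci_low = est$ci_low, ci_high = est$ci_high,
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
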