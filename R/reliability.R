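#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Equal-length numeric vectors, each non-constant, n >= 4.
#' @param alpha Two-sided error level for the confidence interval.
#' @return Object of class `reliability_estimate`: list with `statistic`,
#'   `estimate`, `ci_low`, `ci_high`, `n` and `band` (on the correlation
#'   interpretation scale used for frequency reliability).
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  check_corr_input(x, y)
  r <- stats::cor(x, y)
  ci <- fisher_ci(r, length(x), alpha)
  reliability_estimate("pearson_r", r, ci[1], ci[2], length(x),
                       classify_band(r, band_scale("correlation")))
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Pearson correlation on mid-ranks (ties receive average ranks), with an
#' approximate Fisher-z interval.
#'
#' @inheritParams pearson_with_ci
#' @return A `reliability_estimate` with `statistic = "spearman_r"`.
#' @export
spearman_with_ci <- function(x, y, alpha = 0.05) {
  check_corr_input(x, y)
  r <- stats::cor(x, y, method = "spearman")
  ci <- fisher_ci(r, length(x), alpha)
  reliability_estimate("spearman_r", r, ci[1], ci[2], length(x),
                       classify_band(r, band_scale("correlation")))
}

check_corr_input <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
}

fisher_ci <- function(r, n, alpha = 0.05) {
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  tanh(c(z - q * se, z + q * se))
}

reliability_estimate <- function(statistic, estimate, ci_low, ci_high, n,
                                 band = NA_character_) {
  structure(
    list(statistic = statistic, estimate = estimate,
         ci_low = ci_low, ci_high = ci_high, n = n, band = band),
    class = "reliability_estimate"
  )
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%%CI %.3f; %.3f), n = %d%s\n",
              x$statistic, x$estimate, x$ci_low, x$ci_high, x$n,
              if (is.na(x$band)) "" else paste0(" [", x$band, "]")))
  invisible(x)
}

#' Intraclass correlation for test-retest data
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation -- ICC(2,1) in the Shrout-Fleiss nomenclature, ICC(A,1) in
#' McGraw-Wong's -- computed from the two-way ANOVA mean squares of a
#' subjects-by-administrations table, with the standard F-based confidence
#' interval (Satterthwaite degrees of freedom).
#'
#' @param pairs Numeric matrix or data.frame with one row per subject and
#'   one column per administration (two columns for a test-retest design;
#'   n >= 5 subjects).
#' @param alpha Two-sided error level.
#' @return A `reliability_estimate` with `statistic = "icc"`.
#' @export
icc <- function(pairs, alpha = 0.05) {
  m <- as.matrix(pairs)
  stopifnot(is.numeric(m), ncol(m) >= 2)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5) stop("need at least 5 complete subjects")
  if (stats::var(as.vector(m)) == 0) {
    stop("intraclass correlation undefined: zero total variance")
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based interval for ICC(A,1), McGraw & Wong (1996)
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  reliability_estimate("icc", est, lo, hi, n,
                       classify_band(est, band_scale("correlation")))
}

#' Cohen's kappa, simple or weighted
#'
#' Chance-corrected agreement between two categorical ratings over a shared
#' (ordered, for the weighted variants) category domain:
#' kappa = 1 - sum(w * p_obs) / sum(w * p_exp), with disagreement weights
#' `w_ij = |i - j| / (k - 1)` (linear), squared distances (quadratic), or
#' 0/1 off-diagonal (simple kappa, `weights = "none"`). The confidence
#' interval is a seeded nonparametric bootstrap over subjects, chosen over
#' the asymptotic interval because portion categories can be sparse.
#'
#' @param a,b Equal-length vectors of categorical ratings (character or
#'   factor). For weighted kappa the shared levels are taken in their
#'   factor/sorted order.
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @param levels Optional explicit category levels (order matters for
#'   weighted kappa); defaults to the union of observed levels.
#' @param B Bootstrap replicates for the confidence interval; `B = 0` skips
#'   the interval.
#' @param alpha Two-sided error level.
#' @return A `reliability_estimate` (`statistic` of `"kappa_simple"` or
#'   `"kappa_weighted"`) with a Landis-Koch interpretation band.
#' @export
cohen_kappa <- function(a, b, weights = c("none", "linear", "quadratic"),
                        levels = NULL, B = 2000, alpha = 0.05) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) stop("ratings must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]
  b <- as.character(b)[keep]
  if (is.null(levels)) levels <- sort(unique(c(a, b)))
  if (!all(a %in% levels) || !all(b %in% levels)) {
    stop("ratings outside the shared category domain")
  }
  est <- kappa_stat(a, b, levels, weights)
  lo <- hi <- NA_real_
  if (B > 0) {
    n <- length(a)
    boot <- vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kappa_stat(a[idx], b[idx], levels, weights)
    }, numeric(1))
    qs <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  stat <- if (weights == "none") "kappa_simple" else "kappa_weighted"
  reliability_estimate(stat, est, lo, hi, length(a),
                       classify_band(est, band_scale("landis_koch")))
}

kappa_stat <- function(a, b, levels, weights) {
  k <- length(levels)
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  p <- tab / sum(tab)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(weights,
              none = (d > 0) * 1,
              linear = d / (k - 1),
              quadratic = (d / (k - 1))^2)
  if (k == 1) return(1)
  pr <- rowSums(p)
  pc <- colSums(p)
  exp_p <- outer(pr, pc)
  denom <- sum(w * exp_p)
  if (denom == 0) return(1)
  1 - sum(w * p) / denom
}

#' Interpretation band scales
#'
#' Three conventional scales for reading agreement and reliability
#' statistics: `"correlation"` (reliability of frequency questions: < 0.4
#' poor, 0.4-0.6 moderate, 0.6-0.8 substantial, > 0.8 optimal),
#' `"landis_koch"` (kappa: < 0.4 suboptimal, 0.4-0.6 moderate, 0.6-0.8
#' substantial, > 0.8 almost perfect) and `"cade"` (the 0.5-0.7 acceptable
#' range proposed for FFQ reproducibility trials).
#'
#' @param name Scale name.
#' @return A `band_scale` object: list with `name`, increasing `cuts` and
#'   `labels` (one more label than cuts).
#' @export
band_scale <- function(name = c("correlation", "landis_koch", "cade")) {
  name <- match.arg(name)
  sc <- switch(name,
    correlation = list(cuts = c(0.4, 0.6, 0.8),
                       labels = c("poor", "moderate", "substantial",
                                  "optimal")),
    landis_koch = list(cuts = c(0.4, 0.6, 0.8),
                       labels = c("suboptimal", "moderate", "substantial",
                                  "almost perfect")),
    cade = list(cuts = c(0.5, 0.7),
                labels = c("below acceptable", "acceptable",
                           "above acceptable"))
  )
  structure(c(list(name = name), sc), class = "band_scale")
}

#' Classify a value on an interpretation scale
#'
#' Bands are closed on the left and open on the right, with the top band
#' closed, so e.g. 0.6 on the Landis-Koch scale is "substantial" and 0.85
#' "almost perfect".
#'
#' @param value Numeric in `[-1, 1]`.
#' @param scale A [band_scale()].
#' @return Character label.
#' @export
#' @examples
#' classify_band(0.85, band_scale("landis_koch")) # "almost perfect"
#' classify_band(0.6, band_scale("cade"))         # "acceptable"
classify_band <- function(value, scale) {
  stopifnot(inherits(scale, "band_scale"), value >= -1, value <= 1)
  scale$labels[findInterval(value, scale$cuts) + 1]
}

#' Pair test and retest administrations
#'
#' Matches T0 and T1 profiles by respondent id; respondents missing either
#' administration are excluded, mirroring the validation design in which
#' subjects who did not complete both rounds were dropped.
#'
#' @param t0,t1 Lists of `ffq_profile` objects (administrations T0 and T1).
#' @return List of pairs, each `list(respondent_id, t0, t1)`.
#' @export
pair_administrations <- function(t0, t1) {
  id0 <- vapply(t0, `[[`, character(1), "respondent_id")
  id1 <- vapply(t1, `[[`, character(1), "respondent_id")
  shared <- intersect(id0, id1)
  lapply(shared, function(id) {
    list(respondent_id = id,
         t0 = t0[[match(id, id0)]], t1 = t1[[match(id, id1)]])
  })
}

#' Test-retest reliability report
#'
#' Per-item reliability of the questionnaire across two administrations,
#' optionally stratified by age group. Frequency questions get descriptive
#' statistics of both administrations, the Pearson correlation with its
#' Fisher-z 95% interval, the Spearman correlation, the intraclass
#' correlation, and the Cade-range band. Portion questions get Cohen's
#' kappa (linear-weighted when more than two portion levels occur, simple
#' otherwise) with a bootstrap interval and the Landis-Koch band.
#'
#' @param pairs List of test-retest pairs from [pair_administrations()] or
#'   [generate_cohort()].
#' @param schema The questionnaire schema.
#' @param stratify_by_age Split by the age-30 boundary?
#' @param kappa_B Bootstrap replicates for kappa intervals.
#' @return List with data.frames `frequency` and `portion`.
#' @export
reliability_report <- function(pairs, schema = medoc_schema(),
                               stratify_by_age = TRUE, kappa_B = 2000) {
  ages <- vapply(pairs, function(p) p$t0$age_years, numeric(1))
  strata <- if (stratify_by_age) {
    split(seq_along(pairs), age_stratum(ages))
  } else {
    list(all = seq_along(pairs))
  }
  freq_rows <- list()
  portion_rows <- list()
  for (sname in names(strata)) {
    idx <- strata[[sname]]
    if (!length(idx)) {
      warning("empty stratum '", sname, "' skipped")
      next
    }
    sub <- pairs[idx]
    for (item in schema$items$id) {
      f0 <- vapply(sub, function(p) {
        unname(p$t0$frequencies[item])
      }, numeric(1))
      f1 <- vapply(sub, function(p) {
        unname(p$t1$frequencies[item])
      }, numeric(1))
      ok <- !is.na(f0) & !is.na(f1)
      if (sum(ok) < 5) next
      f0 <- f0[ok]
      f1 <- f1[ok]
      est_r <- tryCatch(pearson_with_ci(f0, f1), error = function(e) NULL)
      est_s <- tryCatch(spearman_with_ci(f0, f1), error = function(e) NULL)
      est_i <- tryCatch(icc(cbind(f0, f1)), error = function(e) NULL)
      freq_rows[[length(freq_rows) + 1]] <- data.frame(
        stratum = sname, item = item, n = sum(ok),
        mean_t0 = mean(f0), sd_t0 = stats::sd(f0),
        median_t0 = stats::median(f0),
        mean_t1 = mean(f1), sd_t1 = stats::sd(f1),
        median_t1 = stats::median(f1),
        r = if (is.null(est_r)) NA else est_r$estimate,
        r_ci_low = if (is.null(est_r)) NA else est_r$ci_low,
        r_ci_high = if (is.null(est_r)) NA else est_r$ci_high,
        spearman = if (is.null(est_s)) NA else est_s$estimate,
        icc = if (is.null(est_i)) NA else est_i$estimate,
        band = if (is.null(est_r)) NA_character_ else {
          classify_band(est_r$estimate, band_scale("cade"))
        },
        stringsAsFactors = FALSE
      )
    }
    portion_items <- schema$items$id[schema$items$has_portion_question]
    for (item in portion_items) {
      p0 <- vapply(sub, function(p) {
        as.character(p$t0$portions[item]) %||% NA_character_
      }, character(1))
      p1 <- vapply(sub, function(p) {
        as.character(p$t1$portions[item]) %||% NA_character_
      }, character(1))
      ok <- !is.na(p0) & !is.na(p1)
      if (sum(ok) < 5) next
      levs <- names(schema$portion_levels)
      weighting <- if (length(unique(c(p0[ok], p1[ok]))) > 2) {
        "linear"
      } else "none"
      est_k <- tryCatch(
        cohen_kappa(p0[ok], p1[ok], weights = weighting, levels = levs,
                    B = kappa_B),
        error = function(e) NULL)
      portion_rows[[length(portion_rows) + 1]] <- data.frame(
        stratum = sname, item = item, n = sum(ok),
        kappa = if (is.null(est_k)) NA else est_k$estimate,
        ci_low = if (is.null(est_k)) NA else est_k$ci_low,
        ci_high = if (is.null(est_k)) NA else est_k$ci_high,
        weighting = weighting,
        band = if (is.null(est_k)) NA_character_ else est_k$band,
        stringsAsFactors = FALSE
      )
    }
  }
  list(frequency = do.call(rbind, freq_rows),
       portion = do.call(rbind, portion_rows))
}
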