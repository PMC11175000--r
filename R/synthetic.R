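#' Archetype parameters for synthetic respondents
#'
#' Synthetic respondents are drawn from dietary archetypes positioned on
#' the WD-MD adherence axis. The `md` archetype's item means sit inside
#' every favourable branch of the scoring matrix (mid-interval where the
#' branch is an interval), the `wd` archetype's at unfavourable
#' representative values, and `mixed` interpolates the two linearly with
#' weight `lambda` (1 = fully Mediterranean). Defaults live in
#' `extdata/archetypes.json`, not in code.
#'
#' Weekly frequencies are modelled as half-serving negative binomials:
#' a draw is `rnbinom(mu = 2 * mean, size = 1/dispersion) / 2`, giving item
#' variance `mean/2 + dispersion * mean^2`, matching the overdispersion
#' (SD of the order of the mean) seen in real FFQ frequency data.
#' `dispersion = 0` degenerates to a point mass at the means.
#'
#' @param name `"md"`, `"wd"` or `"mixed"`.
#' @param lambda Interpolation weight for `"mixed"` (0 = wd, 1 = md).
#' @param dispersion Overdispersion parameter (>= 0); `NULL` uses the file
#'   default.
#' @param path Alternative archetype JSON file.
#' @return Object of class `archetype_params`.
#' @export
archetype_params <- function(name = c("md", "wd", "mixed"), lambda = 0.5,
                             dispersion = NULL, path = NULL) {
  name <- match.arg(name)
  stopifnot(lambda >= 0, lambda <= 1)
  cfg <- archetype_config(path)
  md <- cfg$archetypes$md
  wd <- cfg$archetypes$wd
  lam <- switch(name, md = 1, wd = 0, mixed = lambda)
  interp <- function(a, b) lam * a + (1 - lam) * b
  ids <- names(md$item_means)
  means <- stats::setNames(
    vapply(ids, function(i) interp(md$item_means[[i]], wd$item_means[[i]]),
           numeric(1)), ids)
  pp <- stats::setNames(
    vapply(names(md$portion_probs), function(l) {
      interp(md$portion_probs[[l]], wd$portion_probs[[l]])
    }, numeric(1)), names(md$portion_probs))
  structure(
    list(name = name, lambda = lam,
         item_means = means,
         dispersion = dispersion %||% cfg$dispersion,
         behavior_favorable_prob = interp(md$behavior_favorable_prob,
                                          wd$behavior_favorable_prob),
         meal_time = list(mean = interp(md$meal_time$mean, wd$meal_time$mean),
                          sd = interp(md$meal_time$sd, wd$meal_time$sd)),
         dining_out_mean = interp(md$dining_out_mean, wd$dining_out_mean),
         portion_probs = pp / sum(pp),
         age = cfg$age, female_prob = cfg$female_prob),
    class = "archetype_params"
  )
}

archetype_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "archetypes.json", package = "medocr",
                        mustWork = TRUE)
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Theoretical item moments of an archetype
#'
#' Mean and variance of each item's weekly frequency under the half-serving
#' negative-binomial model, used when converting a target test-retest
#' reliability into jitter magnitudes.
#'
#' @param params An `archetype_params`.
#' @return data.frame with `item`, `mean`, `var`.
#' @export
archetype_moments <- function(params) {
  mu <- params$item_means
  d <- params$dispersion
  data.frame(item = names(mu), mean = unname(mu),
             var = unname(mu / 2 + d * mu^2), stringsAsFactors = FALSE)
}

#' Generate one synthetic respondent profile
#'
#' Frequencies are negative-binomial at half-serving resolution (or exactly
#' the archetype means when `dispersion = 0`), portion categories and
#' behaviour answers are drawn categorically with the archetype's
#' favourable-answer probability, and the two numeric behaviours (meal
#' time, dining out) from a truncated normal and a Poisson. The result
#' always validates against the schema.
#'
#' @param params An `archetype_params`.
#' @param schema The questionnaire schema.
#' @param respondent_id Identifier for the profile.
#' @param age_years,sex Demographics; drawn from the configured age/sex
#'   model when `NULL`.
#' @return An `ffq_profile` (administration T0).
#' @export
generate_profile <- function(params, schema = medoc_schema(),
                             respondent_id = "synthetic", age_years = NULL,
                             sex = NULL) {
  mu <- params$item_means
  d <- params$dispersion
  freqs <- if (d == 0) {
    mu
  } else {
    stats::setNames(
      stats::rnbinom(length(mu), mu = 2 * mu, size = 1 / d) / 2, names(mu))
  }
  portion_items <- schema$items$id[schema$items$has_portion_question]
  portions <- stats::setNames(
    sample(names(params$portion_probs), length(portion_items),
           replace = TRUE, prob = params$portion_probs),
    portion_items)
  p_fav <- params$behavior_favorable_prob
  behaviors <- list()
  for (b in schema$behaviors) {
    if (b$type == "numeric") next
    fav <- b$favorable
    others <- setdiff(b$answers, fav)
    behaviors[[b$id]] <- if (stats::runif(1) < p_fav) {
      fav
    } else {
      sample(others, 1)
    }
  }
  behaviors$meal_time_minutes <-
    max(5, stats::rnorm(1, params$meal_time$mean, params$meal_time$sd))
  behaviors$dining_out_per_week <- stats::rpois(1, params$dining_out_mean)
  if (is.null(age_years)) {
    w <- unlist(params$age$weights)
    stratum <- sample(c("young", "old"), 1, prob = w / sum(w))
    a <- params$age[[stratum]]
    age_years <- round(min(a$max, max(a$min, stats::rnorm(1, a$mean, a$sd))))
  }
  if (is.null(sex)) {
    sex <- if (stats::runif(1) < params$female_prob) "F" else "M"
  }
  height <- round(stats::rnorm(1, if (sex == "F") 165 else 177, 7), 1)
  bmi <- stats::rnorm(1, 22.5, 3)
  response_profile(
    respondent_id = respondent_id, frequencies = freqs, portions = portions,
    behaviors = behaviors, age_years = age_years, sex = sex,
    height_cm = height, weight_kg = round(bmi * (height / 100)^2, 1),
    administration = "T0"
  )
}

#' Retest noise parameters
#'
#' Controls how a T1 administration is derived from T0: weekly frequencies
#' are jittered multiplicatively with a mean-one lognormal factor
#' `exp(tau * Z - tau^2 / 2)` and re-rounded to half servings; each portion
#' answer switches to an adjacent category with probability
#' `portion_switch_prob`; each categorical behaviour answer is resampled
#' among the other answers with probability `behavior_flip_prob`; numeric
#' behaviours get a fixed 15% lognormal jitter.
#'
#' Either give `tau` directly (scalar or per-item named vector) or a
#' `target_reliability` rho, from which per-item taus are derived by
#' inverting the exact moment relation
#' `rho = sigma / sqrt((sigma^2 + mu^2) * exp(tau^2) - mu^2)`
#' (see [attenuation_tau()]) using the cohort's theoretical item moments.
#'
#' @param tau Lognormal jitter SD on the log scale, or `NULL` to derive it.
#' @param target_reliability Target item-level test-retest Pearson
#'   correlation; default 0.6, the centre of the 0.5-0.7 acceptable range
#'   for FFQ reproducibility trials.
#' @param portion_switch_prob,behavior_flip_prob Switch/flip probabilities.
#' @return List of class `retest_noise`.
#' @export
retest_noise <- function(tau = NULL, target_reliability = 0.6,
                         portion_switch_prob = 0.2,
                         behavior_flip_prob = 0.1) {
  stopifnot(is.null(tau) || all(tau >= 0),
            target_reliability > 0, target_reliability <= 1,
            portion_switch_prob >= 0, portion_switch_prob <= 1,
            behavior_flip_prob >= 0, behavior_flip_prob <= 1)
  structure(list(tau = tau, target_reliability = target_reliability,
                 portion_switch_prob = portion_switch_prob,
                 behavior_flip_prob = behavior_flip_prob),
            class = "retest_noise")
}

#' Jitter magnitude for a target test-retest correlation
#'
#' For T1 = T0 * exp(tau * Z - tau^2/2) with Z standard normal independent
#' of T0, corr(T0, T1) = sigma / sqrt((sigma^2 + mu^2) * exp(tau^2) -
#' mu^2), where mu, sigma^2 are the cohort mean and variance of T0. This
#' inverts that relation.
#'
#' @param rho Target correlation (0 < rho <= 1).
#' @param mu,sigma2 Cohort mean and variance of the item's T0 frequency.
#' @return tau (0 when the item has no variance).
#' @export
attenuation_tau <- function(rho, mu, sigma2) {
  stopifnot(rho > 0, rho <= 1)
  ifelse(sigma2 <= 0, 0,
         sqrt(log((sigma2 / rho^2 + mu^2) / (sigma2 + mu^2))))
}

#' Derive a retest administration from a profile
#'
#' @param profile The T0 `ffq_profile`.
#' @param noise A [retest_noise()]; its `tau` must be resolved (scalar or
#'   per-item named vector) -- [generate_cohort()] resolves a
#'   `target_reliability` into taus before calling this.
#' @param schema The questionnaire schema.
#' @return The T1 `ffq_profile` (same respondent id).
#' @export
retest_replicate <- function(profile, noise = retest_noise(tau = 0.3),
                             schema = medoc_schema()) {
  tau <- noise$tau
  if (is.null(tau)) {
    stop("retest_noise tau is unresolved; give tau or use generate_cohort()")
  }
  p1 <- profile
  p1$administration <- "T1"
  f <- profile$frequencies
  tau_i <- if (length(tau) == 1) {
    rep(tau, length(f))
  } else {
    unname(tau[names(f)])
  }
  jitter <- which(tau_i > 0)
  if (length(jitter)) {
    z <- stats::rnorm(length(jitter))
    fj <- f[jitter] * exp(tau_i[jitter] * z - tau_i[jitter]^2 / 2)
    f[jitter] <- pmax(0, round(fj * 2) / 2)
  }
  p1$frequencies <- f
  levs <- names(schema$portion_levels)
  po <- profile$portions
  if (length(po) && noise$portion_switch_prob > 0) {
    switch_it <- stats::runif(length(po)) < noise$portion_switch_prob
    for (i in which(switch_it)) {
      idx <- match(po[[i]], levs)
      nbr <- intersect(c(idx - 1, idx + 1), seq_along(levs))
      po[[i]] <- levs[if (length(nbr) == 1) nbr else sample(nbr, 1)]
    }
  }
  p1$portions <- po
  beh <- profile$behaviors
  for (bid in names(beh)) {
    bdef <- schema$behaviors[[bid]]
    if (is.null(bdef)) next
    if (bdef$type == "categorical") {
      if (stats::runif(1) < noise$behavior_flip_prob) {
        beh[[bid]] <- sample(setdiff(bdef$answers, beh[[bid]]), 1)
      }
    } else if (any(tau_i > 0)) {
      beh[[bid]] <- max(0, beh[[bid]] * exp(stats::rnorm(1, 0, 0.15)))
    }
  }
  p1$behaviors <- beh
  p1
}

#' Cohort specification for the synthetic generator
#'
#' @param n Number of respondents (the validation study enrolled 213).
#' @param mixture Named weights over the archetypes `md`, `mixed`, `wd`
#'   (normalized internally).
#' @param lambda Interpolation weight of the `mixed` archetype.
#' @param noise A [retest_noise()].
#' @param age_md_bias Probability, for respondents in the older stratum, of
#'   forcing the `md` archetype -- emulates higher Mediterranean adherence
#'   in older participants (the nutrition-transition direction); 0 disables.
#' @param dispersion Overrides the archetype file's dispersion.
#' @param seed Integer seed; every source of randomness in the generator
#'   flows through it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 213,
                        mixture = c(md = 1, mixed = 1, wd = 1) / 3,
                        lambda = 0.5, noise = retest_noise(),
                        age_md_bias = 0, dispersion = NULL, seed = NULL) {
  stopifnot(n > 0, all(mixture >= 0), sum(mixture) > 0,
            age_md_bias >= 0, age_md_bias <= 1)
  mixture <- mixture[c("md", "mixed", "wd")]
  mixture[is.na(mixture)] <- 0
  names(mixture) <- c("md", "mixed", "wd")
  structure(list(n = n, mixture = mixture / sum(mixture), lambda = lambda,
                 noise = noise, age_md_bias = age_md_bias,
                 dispersion = dispersion, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic test-retest cohort
#'
#' Draws `n` respondents from the archetype mixture, assigns ages from the
#' two-stratum age model, and derives each T1 administration from T0 with
#' the spec's retest noise. When the noise carries a `target_reliability`
#' instead of explicit taus, per-item taus are derived from the mixture's
#' theoretical item moments so that the expected item-level test-retest
#' correlation equals the target.
#'
#' @param spec A [cohort_spec()].
#' @param schema The questionnaire schema.
#' @return List of `n` pairs `list(respondent_id, t0, t1)`.
#' @export
generate_cohort <- function(spec = cohort_spec(), schema = medoc_schema()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  params <- list(
    md = archetype_params("md", dispersion = spec$dispersion),
    mixed = archetype_params("mixed", lambda = spec$lambda,
                             dispersion = spec$dispersion),
    wd = archetype_params("wd", dispersion = spec$dispersion)
  )
  noise <- spec$noise
  if (is.null(noise$tau)) {
    mom <- lapply(params, archetype_moments)
    w <- spec$mixture
    mu_mix <- Reduce(`+`, Map(function(m, wi) wi * m$mean, mom, w))
    m2_mix <- Reduce(`+`, Map(function(m, wi) wi * (m$var + m$mean^2), mom, w))
    var_mix <- pmax(0, m2_mix - mu_mix^2)
    noise$tau <- stats::setNames(
      attenuation_tau(noise$target_reliability, mu_mix, var_mix),
      mom$md$item)
  }
  lapply(seq_len(spec$n), function(i) {
    arch <- sample(names(spec$mixture), 1, prob = spec$mixture)
    pars <- params[[arch]]
    w <- unlist(pars$age$weights)
    stratum <- sample(c("young", "old"), 1, prob = w / sum(w))
    if (stratum == "old" && spec$age_md_bias > 0 &&
        stats::runif(1) < spec$age_md_bias) {
      pars <- params$md
    }
    a <- pars$age[[stratum]]
    age <- round(min(a$max, max(a$min, stats::rnorm(1, a$mean, a$sd))))
    t0 <- generate_profile(pars, schema,
                           respondent_id = sprintf("S%04d", i),
                           age_years = age)
    t1 <- retest_replicate(t0, noise, schema)
    list(respondent_id = t0$respondent_id, t0 = t0, t1 = t1)
  })
}
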