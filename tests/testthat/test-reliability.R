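test_that("pearson estimate and Fisher interval match direct computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_ci(x, x)$estimate, 1)
  expect_equal(pearson_with_ci(x, -x)$estimate, -1)
  # 6-point hand vectors: r from the explicit covariance / sd formula
  a <- c(2, 4, 5, 7, 9, 12)
  b <- c(1, 3, 2, 6, 8, 9)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  est <- pearson_with_ci(a, b)
  expect_equal(est$estimate, r_oracle)
  # interval equals the one cor.test derives from the same transform
  ct <- stats::cor.test(a, b)
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")
})

test_that("spearman is rank-invariant and handles ties by mid-ranks", {
  x <- c(1, 3, 5, 8, 13)
  expect_equal(spearman_with_ci(x, exp(x))$estimate, 1)
  expect_equal(spearman_with_ci(x, rev(x))$estimate, -1)
  a <- c(1, 2, 2, 4, 7, 9)
  b <- c(3, 1, 5, 5, 8, 10)
  # oracle: mid-ranks then product-moment correlation
  oracle <- stats::cor(rank(a), rank(b))
  expect_equal(spearman_with_ci(a, b)$estimate, oracle)
})

test_that("intraclass correlation recovers agreement structure", {
  # perfect agreement
  set.seed(1)
  v <- rnorm(30)
  expect_equal(icc(cbind(v, v))$estimate, 1)
  # independent permutation: near zero
  set.seed(2)
  t0 <- rnorm(200)
  perm <- icc(cbind(t0, sample(t0)))
  expect_lt(abs(perm$estimate), 0.15)
  # variance-component recovery: subject variance 3, error variance 1
  set.seed(3)
  n <- 500
  subj <- rnorm(n, sd = sqrt(3))
  m <- cbind(subj + rnorm(n), subj + rnorm(n))
  est <- icc(m)
  expect_lt(abs(est$estimate - 0.75), 0.05)
  expect_lte(est$ci_low, est$estimate)
  expect_gte(est$ci_high, est$estimate)
  expect_error(icc(cbind(rep(1, 10), rep(1, 10))), "zero total variance")
})

test_that("icc agrees with mixed-model variance components", {
  skip_if_not_installed("lme4")
  set.seed(4)
  n <- 150
  subj <- rnorm(n, sd = 1.5)
  rater <- c(0, 0.3)  # systematic shift between administrations
  m <- cbind(subj + rater[1] + rnorm(n, sd = 0.8),
             subj + rater[2] + rnorm(n, sd = 0.8))
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), 2)),
                  admin = factor(rep(1:2, each = n)))
  fit <- lme4::lmer(y ~ 1 + (1 | subject) + (1 | admin), data = d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  icc_lmm <- v[["subject"]] / sum(v)
  expect_equal(icc(m)$estimate, unname(icc_lmm), tolerance = 0.02)
})

test_that("kappa is 1 under identity, near 0 under independence", {
  a <- rep(c("s", "m", "l"), times = 10)
  for (w in c("none", "linear", "quadratic")) {
    expect_equal(cohen_kappa(a, a, weights = w, B = 0)$estimate, 1)
  }
  set.seed(6)
  x <- sample(c("s", "m", "l"), 1000, replace = TRUE)
  y <- sample(c("s", "m", "l"), 1000, replace = TRUE)
  expect_lt(abs(cohen_kappa(x, y, B = 0)$estimate), 0.1)
  expect_lt(abs(cohen_kappa(x, y, weights = "linear", B = 0)$estimate), 0.1)
})

test_that("weighted kappa matches a hand contingency-table evaluation", {
  # 3x3 table: rows = rating a, cols = rating b
  tab <- matrix(c(20, 5, 1,
                  4, 15, 6,
                  2, 3, 19), nrow = 3, byrow = TRUE)
  a <- rep(rep(c("1", "2", "3"), each = 3), times = as.vector(t(tab)))
  b <- rep(rep(c("1", "2", "3"), times = 3), times = as.vector(t(tab)))
  p <- tab / sum(tab)
  for (w_name in c("none", "linear", "quadratic")) {
    d <- abs(outer(1:3, 1:3, "-"))
    w <- switch(w_name, none = (d > 0) * 1, linear = d / 2,
                quadratic = (d / 2)^2)
    exp_p <- outer(rowSums(p), colSums(p))
    oracle <- 1 - sum(w * p) / sum(w * exp_p)
    expect_equal(
      cohen_kappa(a, b, weights = w_name, levels = c("1", "2", "3"),
                  B = 0)$estimate,
      oracle)
  }
})

test_that("simple kappa cross-checks against an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  a <- sample(c("x", "y", "z"), 200, replace = TRUE)
  b <- ifelse(stats::runif(200) < 0.6, a,
              sample(c("x", "y", "z"), 200, replace = TRUE))
  tab <- table(factor(a, levels = c("x", "y", "z")),
               factor(b, levels = c("x", "y", "z")))
  expect_equal(cohen_kappa(a, b, B = 0)$estimate,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("kappa properties: symmetry, two-level equivalence, bootstrap CIs", {
  set.seed(9)
  a <- sample(c("lo", "hi"), 80, replace = TRUE)
  b <- ifelse(stats::runif(80) < 0.7, a, sample(c("lo", "hi"), 80, TRUE))
  expect_equal(cohen_kappa(a, b, B = 0)$estimate,
               cohen_kappa(b, a, B = 0)$estimate)
  # with k = 2 the weighting is irrelevant
  expect_equal(cohen_kappa(a, b, weights = "linear", B = 0)$estimate,
               cohen_kappa(a, b, B = 0)$estimate)
  expect_equal(cohen_kappa(a, b, weights = "quadratic", B = 0)$estimate,
               cohen_kappa(a, b, B = 0)$estimate)
  # seeded bootstrap reproducibility
  set.seed(123)
  ci1 <- cohen_kappa(a, b, B = 200)
  set.seed(123)
  ci2 <- cohen_kappa(a, b, B = 200)
  expect_identical(c(ci1$ci_low, ci1$ci_high), c(ci2$ci_low, ci2$ci_high))
  expect_lte(ci1$ci_low, ci1$estimate)
  expect_gte(ci1$ci_high, ci1$estimate)
})

test_that("quadratic kappa on discretized bivariate normals tracks latent r", {
  set.seed(10)
  n <- 5000
  rho <- 0.6
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- stats::qnorm(seq(1, 6) / 7)  # seven equal-probability categories
  a <- cut(z1, c(-Inf, cuts, Inf), labels = FALSE)
  b <- cut(z2, c(-Inf, cuts, Inf), labels = FALSE)
  levs <- as.character(1:7)
  k <- cohen_kappa(as.character(a), as.character(b), weights = "quadratic",
                   levels = levs, B = 0)$estimate
  expect_lt(abs(k - rho), 0.05)
  # classical identity: quadratic kappa ~ Pearson r of the category scores
  expect_equal(k, stats::cor(a, b), tolerance = 0.01)
})

test_that("interpretation bands reproduce the conventional labels", {
  lk <- band_scale("landis_koch")
  expect_identical(classify_band(0.85, lk), "almost perfect")
  expect_identical(classify_band(0.5, lk), "moderate")
  expect_identical(classify_band(0.7, lk), "substantial")
  expect_identical(classify_band(0.2, lk), "suboptimal")
  cade <- band_scale("cade")
  expect_identical(classify_band(0.6, cade), "acceptable")
  expect_identical(classify_band(0.45, cade), "below acceptable")
  corr <- band_scale("correlation")
  expect_identical(classify_band(0.85, corr), "optimal")
  # monotone step function of the input
  grid <- seq(-1, 1, by = 0.01)
  for (sc in list(lk, cade, corr)) {
    idx <- match(classify_band(grid, sc), sc$labels)
    expect_false(is.unsorted(idx))
  }
  # left-closed, right-open; top band closed
  expect_identical(classify_band(0.4, lk), "moderate")
  expect_identical(classify_band(1, lk), "almost perfect")
})

test_that("reliability report handles identity, exclusions and strata", {
  set.seed(12)
  pairs <- generate_cohort(cohort_spec(n = 24, seed = 12,
                                       noise = retest_noise(
                                         tau = 0,
                                         portion_switch_prob = 0,
                                         behavior_flip_prob = 0)))
  rep0 <- reliability_report(pairs, stratify_by_age = FALSE, kappa_B = 0)
  expect_true(all(abs(rep0$frequency$r - 1) < 1e-12 |
                    is.na(rep0$frequency$r)))
  expect_true(all(abs(rep0$frequency$icc - 1) < 1e-12 |
                    is.na(rep0$frequency$icc)))
  expect_true(all(rep0$portion$kappa == 1))

  # respondents missing one administration are excluded up front
  t0 <- lapply(pairs[1:13], `[[`, "t0")
  t1 <- lapply(pairs[1:10], `[[`, "t1")
  matched <- pair_administrations(t0, t1)
  expect_length(matched, 10)

  # stratified report covers both age bands
  set.seed(13)
  big <- generate_cohort(cohort_spec(n = 120, seed = 13))
  rep1 <- reliability_report(big, stratify_by_age = TRUE, kappa_B = 0)
  expect_setequal(unique(rep1$frequency$stratum),
                  c("young_adults", "adults_elderly"))
  expect_true(all(rep1$frequency$r >= -1 & rep1$frequency$r <= 1, na.rm = TRUE))
  expect_true(all(rep1$portion$weighting %in% c("linear", "none")))
})
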