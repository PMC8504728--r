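make_female_cohort <- function(n = 48, beta_gv = 0.5, beta_w = 0.3,
                               resid_sd = 0, seed = 1) {
  set.seed(seed)
  gv <- exp(rnorm(n, 8.3, 0.2)); w <- exp(rnorm(n, 4.2, 0.2))
  tibble::tibble(
    specimen_id = sprintf("F%03d", 1:n), sex = "female",
    body_weight_kg = w, gut_volume_cc = gv,
    IAP = exp(0.2 + beta_gv * log(gv) + beta_w * log(w) +
                rnorm(n, 0, resid_sd))
  )
}

test_that("log transform is natural log and respects the ratio identity", {
  cohort <- tibble::tibble(
    specimen_id = c("a", "b"), sex = "female",
    body_weight_kg = c(1, exp(1)), gut_volume_cc = c(exp(1), exp(2)),
    IAP = c(110, 100), IML = c(125, 80),
    inlet_shape = c(110 / 125, 100 / 80)
  )
  lc <- log_transform_cohort(cohort)
  expect_equal(lc$body_weight_kg, c(0, 1))
  expect_equal(lc$gut_volume_cc, c(1, 2))
  # transform-then-divide equals divide-then-transform
  expect_equal(lc$inlet_shape, lc$IAP - lc$IML, tolerance = 1e-12)
  expect_true(isTRUE(attr(lc, "log_scale")))
})

test_that("nonpositive values name the specimen and field", {
  cohort <- tibble::tibble(
    specimen_id = c("a", "b"), sex = "female",
    body_weight_kg = c(60, -1), gut_volume_cc = c(4000, 4100), IAP = c(1, 1)
  )
  expect_error(log_transform_cohort(cohort), regexp = "body_weight_kg.*\\bb\\b",
               class = "pelvimetrics_domain_error")
})

test_that("noiseless female fits recover generating coefficients exactly", {
  lc <- log_transform_cohort(make_female_cohort(resid_sd = 0))
  fit <- fit_sex_model(lc, "IAP", "female")
  # lm warns about the (intended) exact interpolation
  rep <- suppressWarnings(fit_report(fit))
  expect_equal(rep$beta_gv, 0.5, tolerance = 1e-10)
  expect_equal(rep$beta_weight, 0.3, tolerance = 1e-10)
  expect_equal(rep$model_form, "additive")
  expect_true(is.na(rep$beta_interaction))
})

test_that("an uninformative response yields negative adjusted R2 on average", {
  set.seed(77)
  adj <- replicate(1000, {
    n <- 44
    d <- tibble::tibble(
      specimen_id = sprintf("M%03d", 1:n), sex = "male",
      body_weight_kg = exp(rnorm(n, 4.4, 0.2)),
      gut_volume_cc = exp(rnorm(n, 8.6, 0.2)),
      IAP = exp(rnorm(n, 4.6, 0.1))
    )
    glance(fit_sex_model(log_transform_cohort(d), "IAP", "male"))$r.squared.adjusted
  })
  expect_lt(mean(adj), 0)
})

test_that("male interaction coefficient CIs cover the truth", {
  set.seed(13)
  b_int <- 0.6
  covered <- replicate(200, {
    n <- 44
    w <- exp(rnorm(n, 4.4, 0.25)); gv <- exp(rnorm(n, 8.6, 0.25))
    y <- exp(1 + 0.1 * log(gv) + 0.2 * log(w) +
               b_int * log(gv) * log(w) + rnorm(n, 0, 0.5))
    d <- tibble::tibble(specimen_id = sprintf("M%03d", 1:n), sex = "male",
                        body_weight_kg = w, gut_volume_cc = gv, IAP = y)
    fit <- fit_sex_model(log_transform_cohort(d), "IAP", "male")
    ci <- stats::confint(fit$fit)["gut_volume_cc:body_weight_kg", ]
    ci[1] <= b_int && b_int <= ci[2]
  })
  expect_gte(mean(covered), 0.90)
})

test_that("rank-deficient designs raise a collinearity error", {
  d <- make_female_cohort(resid_sd = 0.1)
  d$body_weight_kg <- d$gut_volume_cc    # perfectly collinear predictors
  expect_error(fit_sex_model(log_transform_cohort(d), "IAP", "female"),
               class = "pelvimetrics_collinearity_error")
  expect_error(fit_sex_model(log_transform_cohort(make_female_cohort()), "nope", "female"),
               class = "pelvimetrics_schema_error")
})

test_that("interaction comparison has nominal type-I error and real power", {
  set.seed(19)
  null_p <- replicate(2000, {
    d <- make_female_cohort(n = 48, resid_sd = 0.3, seed = sample.int(1e6, 1))
    compare_interaction(log_transform_cohort(d), "IAP")
  })
  rate <- mean(null_p <= 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)

  strong_p <- replicate(200, {
    n <- 48
    gv <- exp(rnorm(n, 8.3, 0.2)); w <- exp(rnorm(n, 4.2, 0.2))
    cgv <- log(gv) - mean(log(gv)); cw <- log(w) - mean(log(w))
    sd_int <- sd(cgv * cw)
    y <- exp(4 + 0.8 / sd_int * cgv * cw + rnorm(n, 0, 0.04))
    d <- tibble::tibble(specimen_id = sprintf("F%03d", 1:n), sex = "female",
                        body_weight_kg = w, gut_volume_cc = gv, IAP = y)
    compare_interaction(log_transform_cohort(d), "IAP")
  })
  expect_gt(mean(strong_p <= 0.05), 0.9)
})

test_that("a constant interaction column is flagged as degenerate", {
  d <- make_female_cohort(resid_sd = 0.1)
  d$gut_volume_cc <- exp(1)   # log GV constant-> interaction aliased
  expect_error(compare_interaction(log_transform_cohort(d), "IAP"),
               class = "pelvimetrics_degenerate_comparison_error")
})

test_that("relative weights conserve R2 and respect orthogonal closed forms", {
  set.seed(23)
  for (i in 1:25) {
    p <- sample(2:6, 1); n <- 60
    x <- matrix(rnorm(n * p), n, p) %*%
      (diag(p) + matrix(runif(p * p, -0.2, 0.2), p, p))
    y <- x %*% rnorm(p) + rnorm(n)
    rw <- relative_weights(x, y)
    expect_equal(sum(rw$raw_weight), summary(lm(y ~ x))$r.squared,
                 tolerance = 1e-10)
    expect_equal(sum(rw$pct), 100, tolerance = 1e-6)
    # relabeling predictors permutes, never changes, the weights
    perm <- sample(p)
    rw2 <- relative_weights(x[, perm], y)
    expect_equal(rw2$raw_weight, rw$raw_weight[perm], tolerance = 1e-10)
  }

  # exactly orthogonal (in-sample) predictors: eps_k = squared correlation
  x <- qr.Q(qr(scale(matrix(rnorm(200), 50, 4), center = TRUE, scale = FALSE)))
  y <- x %*% c(1, 0.5, 0, -2) + rnorm(50, 0, 0.5)
  rw <- relative_weights(x, y)
  expect_equal(rw$raw_weight, as.vector(cor(x, y))^2, tolerance = 1e-10)

  # one relevant predictor plus pure orthogonal noise
  x2 <- cbind(rnorm(4000), rnorm(4000))
  y2 <- 2 * x2[, 1] + rnorm(4000, 0, 0.05)
  rw2 <- relative_weights(x2, y2)
  expect_gt(rw2$pct[1], 99); expect_lt(rw2$pct[2], 1)

  expect_error(relative_weights(cbind(1:10, 2 * (1:10)), rnorm(10)),
               class = "pelvimetrics_collinearity_error")
})

test_that("significance flags follow the two-level alpha convention", {
  expect_identical(significance_flags(0.002), "**")
  expect_identical(significance_flags(0.02), "*")
  expect_identical(significance_flags(c(0.05, 0.01, 0.051, 0.5)),
                   c("*", "**", "", ""))
  expect_error(significance_flags(1.2), class = "pelvimetrics_schema_error")
})

test_that("body-mass groups split strictly beyond one SD of the sex mean", {
  cohort <- tibble::tibble(
    specimen_id = as.character(1:4), sex = "female",
    body_weight_kg = c(60, 70, 80, 90)   # mean 75, sd ~12.9
  )
  g <- bodymass_groups(cohort)
  expect_identical(as.character(g$weight_group), c("low", "mid", "mid", "high"))

  # boundary: mean - 1 SD is not strictly below, so it stays mid
  three <- tibble::tibble(specimen_id = as.character(1:3), sex = "male",
                          body_weight_kg = c(60, 70, 80))
  expect_identical(as.character(bodymass_groups(three)$weight_group),
                   c("mid", "mid", "mid"))

  flat <- tibble::tibble(specimen_id = as.character(1:3), sex = "male",
                         body_weight_kg = c(70, 70, 70))
  expect_warning(gf <- bodymass_groups(flat), "one group")
  expect_true(all(gf$weight_group == "mid"))
})

test_that("the regression report mirrors the two-table column structure", {
  cohort <- simulate_cohort(generator_config(seed = 4))
  rep <- regression_report(cohort)
  expect_equal(nrow(rep), 22L)
  expect_setequal(unique(rep$sex), c("male", "female"))
  for (sx in c("male", "female")) {
    expect_setequal(rep$response[rep$sex == sx], canal_responses())
  }
  expect_true(all(c("beta_gv", "p_gv", "beta_weight", "p_weight",
                    "r2_adjusted", "r2_raw", "model_p",
                    "rw_gv_pct", "rw_weight_pct") %in% names(rep)))
  expect_equal(rep$rw_gv_pct + rep$rw_weight_pct, rep(100, 22), tolerance = 1e-6)
  expect_true(all(rep$r2_raw >= pmax(0, rep$r2_adjusted) - 1e-12))
  expect_true(all(is.na(rep$beta_interaction[rep$sex == "female"])))
  expect_true(all(!is.na(rep$beta_interaction[rep$sex == "male"])))
})

test_that("tidy and glance expose broom-shaped summaries", {
  lc <- log_transform_cohort(make_female_cohort(resid_sd = 0.05))
  fit <- fit_sex_model(lc, "IAP", "female")
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "gut_volume_cc", "body_weight_kg"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 48)
  expect_gte(gl$r.squared.raw, gl$r.squared.adjusted)
})

test_that("weight_group boundary case at exactly mean - 1 SD stays mid", {
  # weights 60,70,80: mean 70, sd 10; 60 is not strictly below 60
  cohort <- tibble::tibble(specimen_id = as.character(1:3), sex = "male",
                           body_weight_kg = c(60, 70, 80))
  g <- bodymass_groups(cohort)
  expect_identical(as.character(g$weight_group[1]), "mid")
})
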