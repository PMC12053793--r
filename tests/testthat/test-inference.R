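test_that("binomial and Gaussian fits agree with closed forms and stats::glm", {
  # intercept-only MLE of a proportion: 3 successes in 10
  d <- data.frame(y = rep(1:0, c(3, 7)))
  f <- fit_glm(y ~ 1, d, "binomial")
  expect_equal(unname(coef(f)), log(0.3 / 0.7), tolerance = 1e-8)
  expect_equal(unname(predict(f, data.frame(z = 1:5))), rep(0.3, 5),
               tolerance = 1e-8)

  set.seed(10)
  n <- 400
  dd <- data.frame(x = runif(n), z = rnorm(n))
  dd$yb <- rbinom(n, 1, plogis(-0.5 + 1.5 * dd$x))
  dd$yg <- 2 + 3 * dd$x + rnorm(n)

  fb <- fit_glm(yb ~ x + z, dd, "binomial")
  rb <- stats::glm(yb ~ x + z, dd, family = binomial)
  expect_equal(coef(fb), coef(rb), tolerance = 1e-6)
  expect_equal(unname(fb$se), unname(summary(rb)$coefficients[, 2]),
               tolerance = 1e-5)
  expect_equal(fb$loglik, as.numeric(logLik(rb)), tolerance = 1e-8)
  expect_equal(fb$aic, AIC(rb), tolerance = 1e-6)

  # Gaussian equals ordinary least squares, including the AIC convention
  fg <- fit_glm(yg ~ x, dd, "gaussian")
  ols <- stats::lm(yg ~ x, dd)
  expect_equal(coef(fg), coef(ols), tolerance = 1e-10)
  expect_equal(unname(fg$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fg$aic, AIC(ols), tolerance = 1e-8)
})

test_that("IRLS log-likelihood is monotone and hits saturated/null anchors", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 200
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(0.3 - 1.2 * d$x))
    f <- fit_glm(y ~ x, d, "binomial")
    expect_true(all(diff(f$loglik_trace) >= -1e-10))
    expect_true(f$converged)
  }
  # saturated two-point data: zero deviance
  sat <- fit_glm(y ~ x, data.frame(x = c(0, 1), y = c(0, 1)), "binomial")
  expect_equal(sat$deviance, 0, tolerance = 1e-6)
  # null model fitted probability equals the sample mean
  d <- data.frame(y = rbinom(50, 1, 0.4))
  f0 <- fit_glm(y ~ 1, d, "binomial")
  expect_equal(unique(round(f0$fitted, 10)), mean(d$y), tolerance = 1e-8)
})

test_that("degenerate designs are caught: separation, collinearity, coding", {
  d <- data.frame(x = 1:20, y = rep(0:1, each = 10))
  f <- fit_glm(y ~ x, d, "binomial")
  expect_true(f$separation)

  d$x2 <- 2 * d$x
  expect_error(fit_glm(y ~ x + x2, d, "binomial"), "rank deficient.*x2")
  expect_error(fit_glm(y ~ x, data.frame(x = 1:3, y = c(0, 1, 2)), "binomial"),
               "0/1")
})

test_that("AICc follows the small-sample correction and its limits", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)          # k = 0: AICc = AIC
  # correction vanishes monotonically as n grows
  ns <- c(20, 50, 100, 1000, 10000)
  gaps <- sapply(ns, function(n) aicc(-5, 3, n)) - (10 + 6)
  expect_true(all(diff(gaps) < 0) && all(gaps > 0))
  # penalty strictly increasing in k at fixed n
  pens <- sapply(0:5, function(k) aicc(0, k, 30))
  expect_true(all(diff(pens) > 0))
  expect_error(aicc(-5, 9, 10), "undefined")
})

test_that("type II tests respect marginality and match car::Anova", {
  set.seed(31)
  n <- 300
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.2 + 0.8 * d$A))
  f <- fit_glm(y ~ A * B, d, "binomial")
  tt <- type2_tests(f)
  expect_equal(tt$term, c("A", "B", "A:B"))

  skip_if_not_installed("car")
  ref <- car::Anova(stats::glm(y ~ A * B, d, family = binomial),
                    type = 2, test.statistic = "LR")
  expect_equal(tt$chisq, ref[["LR Chisq"]], tolerance = 1e-6)
  expect_equal(tt$df, ref[["Df"]])

  # single-predictor LR statistic is the deviance drop
  f1 <- fit_glm(y ~ A, d, "binomial")
  t1 <- type2_tests(f1)
  expect_equal(t1$chisq, f1$null_deviance - f1$deviance, tolerance = 1e-6)
  expect_equal(t1$df, 1L)
})

test_that("LR test of a null term holds its type I error rate", {
  set.seed(47)
  n <- 500
  rejections <- replicate(1000, {
    d <- data.frame(A = rnorm(n), B = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-0.4 + 0.6 * d$B))  # A has no effect
    tt <- type2_tests(fit_glm(y ~ A + B, d, "binomial"))
    tt$p_value[tt$term == "A"] < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("Wald intervals for a distance slope achieve near-nominal coverage", {
  set.seed(59)
  b_true <- 0.002
  covered <- replicate(200, {
    d <- data.frame(dist = runif(2000, 0, 938))
    d$y <- rbinom(2000, 1, plogis(-1 + b_true * d$dist))
    f <- fit_glm(y ~ dist, d, "binomial")
    abs(coef(f)["dist"] - b_true) <= 1.96 * f$se["dist"]
  })
  expect_gte(mean(covered), 0.93)
})

test_that("prediction is monotone under a monotone predictor and warns on extrapolation", {
  set.seed(63)
  d <- data.frame(x = runif(300, 0, 10))
  d$y <- rbinom(300, 1, plogis(-1 + 0.4 * d$x))
  f <- fit_glm(y ~ x, d, "binomial")
  pr <- predict(f, data.frame(x = seq(0, 10, by = 0.5)))
  expect_true(all(diff(pr) > 0) || all(diff(pr) < 0))
  expect_equal(predict(f)[1], f$fitted[1], tolerance = 1e-12)
  expect_message(predict(f, data.frame(x = 99)), "beyond the fitted range")
  # Wald band brackets the fit and stays in [0, 1]
  band <- metarange:::wald_band(f, data.frame(x = 0:10))
  expect_true(all(band$lo <= band$fit & band$fit <= band$hi))
  expect_true(all(band$lo >= 0 & band$hi <= 1))
})

test_that("Gaussian distance trends recover exact and null slopes", {
  d <- data.frame(dist_km = seq(0, 900, by = 30))
  d$area_t1 <- 0.5 + 0.002 * d$dist_km
  f <- fit_gaussian_trend("area_t1", d, log_transform = FALSE)
  expect_equal(unname(coef(f)["dist_km"]), 0.002, tolerance = 1e-10)
  expect_equal(f$deviance, 0, tolerance = 1e-12)

  d$N_t1 <- rep(7, nrow(d))
  f0 <- fit_gaussian_trend("N_t1", d)
  expect_equal(unname(coef(f0)["dist_km"]), 0, tolerance = 1e-12)
})
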