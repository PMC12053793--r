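# independent oracle for the equilibrium: fixed point of the two-state
# occupancy recursion n' = n (1 - e) + (1 - n) c
levins_fixed_point <- function(c, e, n0 = 0.5, iters = 10000) {
  n <- n0
  for (i in seq_len(iters)) n <- n * (1 - e) + (1 - n) * c
  n
}

test_that("Levins equilibrium equals the recursion fixed point", {
  # the overall crude rates give the headline equilibrium
  expect_equal(levins_equilibrium(0.190, 0.306),
               levins_fixed_point(0.190, 0.306), tolerance = 1e-12)
  expect_equal(round(levins_equilibrium(0.190, 0.306), 4), 0.3831)
  expect_equal(levins_equilibrium(0.3, 0), 1)
  expect_equal(levins_equilibrium(0.25, 0.25), 0.5)
  expect_error(levins_equilibrium(0, 0), "undefined")
  expect_error(levins_equilibrium(1.2, 0.5), "probabilities")

  # n* is increasing in c and decreasing in e over a probability grid
  cs <- seq(0.05, 0.95, length.out = 10)
  for (e in c(0.1, 0.5, 0.9))
    expect_true(all(diff(levins_equilibrium(cs, e)) > 0))
  for (c in c(0.1, 0.5, 0.9))
    expect_true(all(diff(levins_equilibrium(c, cs)) < 0))
})

test_that("equilibrium curve is flat for intercept-only fits and monotone in c", {
  p <- pool_pairs(40, 12, 30, 9)
  cfit <- fit_glm(colonised ~ 1, transform(p[p$colonisation_candidate, ],
                                           colonised = as.numeric(colonised)),
                  "binomial")
  efit <- fit_glm(extinct ~ 1, transform(p[p$extinction_candidate, ],
                                         extinct = as.numeric(extinct)),
                  "binomial")
  eq <- suppressMessages(equilibrium_curve(cfit, efit, seq(0, 900, 100)))
  expect_equal(unique(round(eq$n_star, 10)),
               round(levins_equilibrium(12 / 40, 9 / 30), 10))

  # c declining toward the limit, e constant: n* declines toward the limit
  d <- data.frame(dist_km = runif(3000, 0, 900))
  d$col <- rbinom(3000, 1, plogis(-2 + 0.002 * d$dist_km))
  d$ext <- rbinom(3000, 1, 0.3)
  cfit2 <- fit_glm(col ~ dist_km, d, "binomial")
  efit2 <- fit_glm(ext ~ dist_km, d, "binomial")
  eq2 <- equilibrium_curve(cfit2, efit2, seq(0, 900, length.out = 50))
  expect_true(all(diff(eq2$n_star) > 0))  # increases away from the limit
  expect_true(all(eq2$n_star >= 0 & eq2$n_star <= 1))
})

test_that("fitted equilibrium curve tracks the generator's ground truth", {
  sim <- simulate_survey_pair(sim_config(n_plots = 3000L, generations = 1L,
                                         seed = 1L))
  p <- pair_surveys(sim$t1, sim$t2)
  grid <- seq(0, max(p$dist_km), length.out = 200)
  cp <- transform(p[p$colonisation_candidate, ],
                  colonised = as.numeric(colonised))
  ep <- transform(p[p$extinction_candidate, ], extinct = as.numeric(extinct))
  eq <- equilibrium_curve(fit_glm(colonised ~ dist_km, cp, "binomial"),
                          fit_glm(extinct ~ dist_km, ep, "binomial"), grid)
  truth <- true_event_curves(sim, grid)
  expect_lt(max(abs(eq$n_star - truth$n_star_true)), 0.05)
})

test_that("bootstrap envelope is seed-deterministic and brackets the estimate", {
  sim <- simulate_survey_pair(sim_config(n_plots = 1500L, seed = 2L))
  p <- pair_surveys(sim$t1, sim$t2)
  grid <- seq(0, max(p$dist_km), length.out = 40)
  e1 <- bootstrap_envelope(p, grid, B = 120, seed = 99L)
  e2 <- bootstrap_envelope(p, grid, B = 120, seed = 99L)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_true(all(e1$lo <= e1$n_star & e1$n_star <= e1$hi))
  expect_true(all(e1$lo <= e1$hi))
  expect_equal(attr(e1, "B"), 120)

  e3 <- bootstrap_envelope(p, grid, B = 120, seed = 100L)
  expect_false(identical(e1$lo, e3$lo))
})

test_that("envelope width shrinks as the candidate pools grow", {
  width_at <- function(n) {
    set.seed(17)
    d_col <- data.frame(dist_km = runif(n, 0, 900))
    d_col$colonised <- rbinom(n, 1, plogis(-2 + 0.001 * d_col$dist_km))
    d_ext <- data.frame(dist_km = runif(n, 0, 900))
    d_ext$extinct <- rbinom(n, 1, plogis(-1 - 0.0005 * d_ext$dist_km))
    pairs <- data.frame(
      dist_km = c(d_col$dist_km, d_ext$dist_km),
      colonisation_candidate = rep(c(TRUE, FALSE), each = n),
      extinction_candidate = rep(c(FALSE, TRUE), each = n),
      colonised = c(d_col$colonised, rep(NA, n)),
      extinct = c(rep(NA, n), d_ext$extinct))
    env <- bootstrap_envelope(pairs, seq(0, 900, 100), B = 200, seed = 3L)
    mean(env$hi - env$lo)
  }
  expect_lt(width_at(10000), width_at(500))
})

test_that("observed-occupancy model matches crude rates and flags separation", {
  p <- pool_pairs(30, 10, 20, 5)
  obs <- observed_occupancy_model(p, "t2")
  s <- summarize_events(p)
  # near-null distance effect: fitted probabilities straddle the crude rate
  expect_equal(mean(predict(obs)), s$occupancy_suitable_t2, tolerance = 0.02)
  # intercept-only fit reproduces the crude occupancy exactly
  keep <- p$suitable_t2
  f0 <- fit_glm(occupied_t2 ~ 1,
                data.frame(occupied_t2 = as.numeric(p$occupied_t2[keep])),
                "binomial")
  expect_equal(plogis(unname(coef(f0))), s$occupancy_suitable_t2,
               tolerance = 1e-8)

  # all plots occupied: separation is flagged
  all_occ <- pool_pairs(1, 1, 30, 0)
  expect_true(observed_occupancy_model(all_occ, "t2")$separation)
})

test_that("containment is 1 for matching curves and 0 for disjoint ones", {
  set.seed(8)
  d <- data.frame(dist_km = runif(2000, 0, 900))
  d$occ <- rbinom(2000, 1, plogis(-1 + 0.001 * d$dist_km))
  obs <- fit_glm(occ ~ dist_km, d, "binomial")
  grid <- seq(0, 900, length.out = 100)
  band <- metarange:::wald_band(obs, data.frame(dist_km = grid))
  eq_match <- structure(
    data.frame(dist_km = grid, c_hat = NA, e_hat = NA, n_star = band$fit),
    class = c("equilibrium_curve", "data.frame"))
  cmp <- compare_curves(eq_match, obs)
  expect_equal(cmp$containment, 1)

  eq_zero <- eq_match
  eq_zero$n_star <- 0
  expect_equal(compare_curves(eq_zero, obs)$containment, 0)
})
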