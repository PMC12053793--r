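test_that("survey CSV round-trips and field validation names the bad row", {
  s <- make_survey(c("A", "B", "C"), area = c(2, 0, 25), abundance = c(3, 0, 0),
                   causes = list(character(), c("succession", "wind"),
                                 character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(s, path)
  back <- read_survey(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$plot_id, s$plot_id)
  expect_equal(back$suitable_area_m2, s$suitable_area_m2)
  expect_equal(back$abundance, s$abundance)
  expect_equal(back$causes[[2]], c("succession", "wind"))
  expect_length(back$causes[[1]], 0L)

  # out-of-range suitable area rejected with the row index
  bad <- utils::read.csv(path)
  bad$suitable_area_m2[2] <- 30
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_survey(path), "row 2.*\\[0, 25\\]")

  # non-numeric abundance rejected with the row index
  bad$suitable_area_m2[2] <- 1
  bad$abundance[3] <- "many"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_survey(path), "row 3")

  # missing required column is a format error
  bad2 <- utils::read.csv(path)[, -4]
  utils::write.csv(bad2, path, row.names = FALSE)
  expect_error(read_survey(path), "missing required column")
})

test_that("survey data model invariants are enforced", {
  expect_error(make_survey("A", area = 2, abundance = -1), "non-negative")
  expect_error(make_survey("A", area = 2, abundance = 1, is_dune = FALSE),
               "non-dune")
  # causes only allowed on plots with no suitable habitat
  expect_error(make_survey("A", area = 2, abundance = 0,
                           causes = list("wind")), "causes")
  expect_error(metarange:::parse_causes("succession;flood"), "unknown")
})

test_that("pairing classifies candidates and events by the transition rules", {
  t1 <- make_survey(c("A", "B", "C", "D", "E", "F"),
                    area = c(2, 5, 3, 4, 6, 0),
                    abundance = c(0, 3, 0, 1, 2, 0))
  t2 <- make_survey(c("A", "B", "C", "D", "E", "F"),
                    area = c(5, 4, 0, 3, 0, 2),
                    abundance = c(2, 0, 0, 4, 0, 0), year = 2022L,
                    causes = list(character(), character(), "succession",
                                  character(), c("wind", "driftwood"),
                                  character()))
  p <- pair_surveys(t1, t2)
  expect_equal(p$colonisation_candidate, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(p$extinction_candidate, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(p$colonised, c(TRUE, NA, NA, NA, NA, FALSE))
  expect_equal(p$extinct, c(NA, TRUE, NA, FALSE, TRUE, NA))
  # occupied at t1 with habitat lost at t2 is still an extinction candidate
  expect_true(p$extinction_candidate[p$plot_id == "E"])
  # vacant at t1 and unsuitable at t1, but suitable at t2: can be colonised
  expect_true(all(!p$suitable_t1[p$plot_id == "F"],
                  p$colonisation_candidate[p$plot_id == "F"]))
  # no plot is both kinds of candidate
  expect_false(any(p$colonisation_candidate & p$extinction_candidate))

  expect_error(pair_surveys(rbind(t1, t1[1, ]), t2), "duplicate")
})

test_that("non-dune and unmatched plots are excluded and logged", {
  t1 <- make_survey(c("A", "B", "X"), area = c(2, 3, 1), abundance = 0)
  t2 <- make_survey(c("A", "B", "Y"), area = c(2, 3, 1), abundance = 0,
                    year = 2022L, is_dune = c(TRUE, FALSE, TRUE))
  p <- pair_surveys(t1, t2)
  expect_equal(p$plot_id, "A")
  log <- attr(p, "pairing_log")
  expect_equal(log$n_t1_only, 1L)
  expect_equal(log$n_t2_only, 1L)
  expect_equal(log$n_non_dune, 1L)
})

test_that("candidate pools partition the paired plots", {
  sim <- simulate_survey_pair(sim_config(n_plots = 800L, seed = 4L))
  p <- pair_surveys(sim$t1, sim$t2)
  kind <- p$colonisation_candidate + p$extinction_candidate +
    (!p$occupied_t1 & !p$suitable_t2)
  expect_true(all(kind == 1L))
})

test_that("local abundance is exact, symmetric, and NA for isolated plots", {
  # three collinear plots at 0, 300, 900 m
  t1 <- make_survey(c("a", "b", "c"), area = 5, abundance = c(4, 0, 7),
                    x_m = c(0, 300, 900))
  t2 <- make_survey(c("a", "b", "c"), area = 5, abundance = c(4, 0, 7),
                    x_m = c(0, 300, 900), year = 2022L)
  p <- local_abundance(pair_surveys(t1, t2))
  expect_equal(p$L_t1, c(0, 4, NA))

  single <- pair_surveys(make_survey("z", 1, 0),
                         make_survey("z", 1, 0, year = 2022L))
  expect_true(is.na(local_abundance(single)$L_t1))

  # sweep implementation equals the brute-force pairwise oracle, and is
  # invariant to row order
  set.seed(81)
  n <- 1000
  x <- runif(n, 0, 50e3); y <- runif(n, -200, 200)
  v <- rpois(n, 2)
  fast <- metarange:::local_mean(x, y, v, 500)
  expect_identical(fast, local_mean_bruteforce(x, y, v, 500))
  perm <- sample.int(n)
  expect_identical(metarange:::local_mean(x[perm], y[perm], v[perm], 500),
                   fast[perm])
})

test_that("event summary reports counts, crude rates, and occupancies", {
  p <- pool_pairs(n_col = 20, k_col = 7, n_ext = 10, k_ext = 4)
  s <- summarize_events(p)
  expect_equal(s$n_candidates_col, 20L)
  expect_equal(s$crude_c, 7 / 20)
  expect_equal(s$crude_e, 4 / 10)
  expect_equal(s$occupancy_t1, 10 / 30)
  expect_equal(s$occupancy_suitable_t2, (7 + 6) / 30)

  # permutation invariance
  s2 <- summarize_events(p[sample.int(nrow(p)), ])
  expect_equal(unclass(s2), unclass(s))

  # all candidates colonised; empty extinction pool is NA, not zero
  p3 <- pool_pairs(5, 5, 0, 0)
  s3 <- summarize_events(p3)
  expect_equal(s3$crude_c, 1)
  expect_true(is.na(s3$crude_e))
})

test_that("extinction outcomes split demographic vs environmental with causes", {
  # 6 extinct plots: 3 still suitable, 2 unsuitable with causes (one
  # multi-cause), 1 unsuitable with no recorded cause (incomplete)
  id <- letters[1:6]
  t1 <- make_survey(id, area = c(4, 4, 4, 4, 4, 4), abundance = 2)
  t2 <- make_survey(id, area = c(3, 2, 1, 0, 0, 0), abundance = 0,
                    year = 2022L,
                    causes = list(character(), character(), character(),
                                  c("succession", "wind"), "wind",
                                  character()))
  out <- classify_extinction_outcomes(pair_surveys(t1, t2))
  expect_equal(nrow(out), 6L)
  expect_equal(sum(out$cause_missing), 1L)
  expect_equal(attr(out, "n_complete"), 5L)
  expect_equal(attr(out, "prop_still_suitable"), 3 / 5)
  cp <- attr(out, "cause_props")
  # the multi-cause plot counts once in each cause's numerator
  expect_equal(unname(cp["succession"]), 1 / 2)
  expect_equal(unname(cp["wind"]), 2 / 2)

  # no extinctions: empty table
  t2b <- make_survey(id, area = 4, abundance = 2, year = 2022L)
  expect_equal(nrow(classify_extinction_outcomes(pair_surveys(t1, t2b))), 0L)
})

test_that("paired-event CSV writes missing values as empty fields", {
  p <- local_abundance(pool_pairs(3, 1, 2, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs(p, path)
  txt <- readLines(path)
  expect_equal(length(txt), nrow(p) + 1L)
  back <- utils::read.csv(path)
  expect_equal(sum(is.na(back$colonised)), sum(!p$colonisation_candidate))
})
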