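test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_persons = 800, seed = 101)
  g1 <- generate_raw_cohort(cfg)
  g2 <- generate_raw_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$per_person_annual_hazard,
                   g2$truth$per_person_annual_hazard)
  g3 <- generate_raw_cohort(simulation_config(n_persons = 800, seed = 102))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("with no planted rules the event proportion follows the Bernoulli product", {
  cfg <- simulation_config(n_persons = 32547, seed = 55,
                           planted_rules = list(),
                           baseline_annual_hazard = 0.0025,
                           follow_up_years = 4)
  g <- generate_raw_cohort(cfg)
  p_expected <- 1 - (1 - 0.0025)^4
  se <- sqrt(p_expected * (1 - p_expected) / 32547)
  expect_lt(abs(mean(g$cohort$outcome) - p_expected), 3 * se)
  expect_true(all(g$truth$per_person_annual_hazard == 0.0025))
})

test_that("a planted rule with multiplier 1 leaves the cohort unchanged in law", {
  base <- simulation_config(n_persons = 1500, seed = 7, planted_rules = list())
  unit <- simulation_config(n_persons = 1500, seed = 7,
                            planted_rules = list(planted_rule("smoker", 1)))
  expect_identical(generate_raw_cohort(base)$cohort,
                   generate_raw_cohort(unit)$cohort)
})

test_that("raising a planted multiplier never loses events under a shared seed", {
  mk <- function(mult) simulation_config(
    n_persons = 6000, seed = 31,
    planted_rules = list(planted_rule(c("age_ge_55", "sbp_ge_140"), mult)))
  e <- vapply(c(1, 3, 10, 30), function(m)
    sum(generate_raw_cohort(mk(m))$cohort$outcome), numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("assign_onsets handles the degenerate and calibrated cases", {
  z <- assign_onsets(rep(0, 50), 4, seed = 1)
  expect_false(any(z$outcome))
  expect_true(all(is.na(z$onset_year)))

  one <- assign_onsets(c(1, 0), 4, seed = 1)
  expect_identical(one$onset_year[1], 1L)
  expect_false(one$outcome[2])

  half <- assign_onsets(rep(0.5, 10000), 4, seed = 2)
  p <- 1 - 0.5^4
  expect_lt(abs(mean(half$outcome) - p), 3 * sqrt(p * (1 - p) / 10000))
  # onset year defined iff outcome positive
  expect_identical(is.na(half$onset_year), !half$outcome)

  expect_error(assign_onsets(c(0.5, 1.2), 4, seed = 1), "\\[0, 1\\]")
})

test_that("hazards never fall below baseline and capping is reported", {
  cfg <- simulation_config(n_persons = 2000, seed = 9)
  g <- generate_raw_cohort(cfg)
  expect_true(all(g$truth$per_person_annual_hazard >=
                    cfg$baseline_annual_hazard))
  loud <- simulation_config(
    n_persons = 500, seed = 9, baseline_annual_hazard = 0.6,
    planted_rules = list(planted_rule("smoker", 10)))
  expect_message(g2 <- generate_raw_cohort(loud), "capped")
  expect_true(all(g2$truth$per_person_annual_hazard <= 1))
  expect_gt(g2$truth$n_capped, 0)
})

test_that("summarize_cohort computes order statistics and binary percents", {
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = c(1, 1, 2, 100, NA),
                   flag = rep(1, 5), gone = rep(NA_real_, 5))
  s <- summarize_cohort(df, outcome_col = NULL)
  expect_equal(s$median[s$variable == "a"], 3)
  expect_equal(s$q1[s$variable == "a"], 2)
  expect_equal(s$q3[s$variable == "a"], 4)
  expect_equal(s$median[s$variable == "b"], 1.5)
  expect_equal(s$count[s$variable == "flag"], 5)
  expect_equal(s$percent[s$variable == "flag"], 100)
  expect_equal(s$type[s$variable == "gone"], "missing")
  expect_equal(s$n_missing[s$variable == "gone"], 5)

  df10 <- data.frame(x = rep(1, 10), outcome = rep(0:1, 5))
  s10 <- summarize_cohort(df10)
  expect_match(s10$summary[s10$variable == "x"], "^10 \\(100")
  expect_error(summarize_cohort(df[0, ]), "non-empty")
})

test_that("invalid configurations are rejected with the offending name", {
  expect_error(simulation_config(100, seed = 1,
                 planted_rules = list(planted_rule("no_such_item", 2))),
               "no_such_item")
  expect_error(simulation_config(100, seed = 1, baseline_annual_hazard = 1),
               "\\[0, 1\\)")
  expect_error(simulation_config(100, seed = 1.5), "seed")
  expect_error(planted_rule(letters[1:5], 2), "1-4")
  expect_error(planted_rule("a", 0.5), ">= 1")
  expect_error(var_continuous("v", 10, 12, 14), "'v'")
})
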