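mk_profiles <- function(rows, items) {
  m <- matrix(0L, length(rows), length(items),
              dimnames = list(NULL, items))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  m
}

rule_list <- function(conds) list(condition = conds)

test_that("match_count is exact set containment", {
  m <- mk_profiles(list(c("A", "B", "C"), character(0)),
                   c("A", "B", "C", "D"))
  rules <- rule_list(list("A", c("A", "B"), c("B", "D")))
  expect_equal(match_count(m, rules), c(2L, 0L))
  expect_equal(match_count(m, rule_list(list())), c(0L, 0L))
  expect_error(match_count(m[, 1:2, drop = FALSE], rules), "B, D|D")
})

test_that("match_count equals the per-rule row-scan oracle and is monotone", {
  withr::with_seed(71, {
    m <- rand_item_matrix(20, 8, p = 0.5)
    conds <- replicate(30, sort(sample(colnames(m), sample(1:3, 1))),
                       simplify = FALSE)
    got <- match_count(m, rule_list(conds))
    want <- vapply(seq_len(nrow(m)), function(i)
      sum(vapply(conds, function(cc) all(m[i, cc] == 1L), logical(1))),
      integer(1))
    expect_equal(got, want)
    # adding items never decreases the count
    m2 <- m
    m2[, sample(ncol(m), 3)] <- 1L
    expect_true(all(match_count(m2, rule_list(conds)) >= got))
  })
})

test_that("group assignment respects the printed range boundaries", {
  b <- group_binning()
  expect_equal(as.character(assign_group(c(0, 1, 50, 51, 100, 101, 250), b)),
               c("0", "1-50", "1-50", "51-100", "51-100", "101-150",
                 "201-250"))
  expect_warning(g <- assign_group(260, b), "overflow")
  expect_equal(as.character(g), ">250")
  expect_warning(gc <- assign_group(c(10, 260), group_binning(overflow = "clamp")),
                 "clamped")
  expect_equal(as.character(gc), c("1-50", "201-250"))
  expect_error(assign_group(260, group_binning(overflow = "error")),
               "exceed")
  expect_error(assign_group(-1, b), "non-negative")
})

test_that("group incidence conserves totals and reports the published arithmetic", {
  ref <- jmdc_reference()$groups
  groups <- factor(rep(ref$label, ref$n), levels = ref$label)
  outcome <- unlist(lapply(seq_len(nrow(ref)), function(i)
    rep(c(1L, 0L), c(ref$events[i], ref$n[i] - ref$events[i]))))
  tab <- group_incidence(groups, outcome)
  expect_equal(sum(tab$n), sum(ref$n))
  expect_equal(sum(tab$events), sum(ref$events))
  expect_equal(round(100 * tab$incidence[tab$group == "0"], 2), 1.48)
  expect_equal(round(100 * tab$incidence[tab$group == "201-250"], 1), 13.2)
})

test_that("empty and event-free groups are reported sanely", {
  g <- factor(rep("0", 5), levels = c("0", "1-50"))
  tab <- group_incidence(g, rep(0, 5))
  expect_equal(tab$incidence, c(0, NA_real_))
  expect_equal(tab$n, c(5L, 0L))
})

test_that("the trend statistic reproduces the Cochran-Armitage formula", {
  tab <- data.frame(n = c(10, 10, 10), events = c(1, 5, 9))
  res <- trend_test(tab)
  # hand computation with scores 0,1,2
  s <- 0:2; n <- tab$n; d <- tab$events
  pbar <- sum(d) / sum(n)
  z_hand <- sum(s * (d - n * pbar)) /
    sqrt(pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / sum(n)))
  expect_equal(res$statistic, z_hand)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_hand)))
  # chi-square form agrees with stats::prop.trend.test
  ptt <- suppressWarnings(prop.trend.test(tab$events, tab$n, score = s))
  expect_equal(res$statistic^2, unname(ptt$statistic))

  # antisymmetry under group reversal
  rev_res <- trend_test(tab[3:1, ])
  expect_equal(rev_res$statistic, -res$statistic)

  flat <- trend_test(data.frame(n = c(50, 50), events = c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(trend_test(data.frame(n = 10, events = 1)), "two non-empty")
})

test_that("discrete Kaplan-Meier matches hand products and survfit", {
  # 10 persons, events at years 1 and 2
  g <- factor(rep("all", 10))
  outcome <- c(1, 1, rep(0, 8))
  onset <- c(1L, 2L, rep(NA_integer_, 8))
  km <- km_curves(g, outcome, onset, follow_up_years = 4)
  expect_equal(km$survival, c(0.9, 0.8, 0.8, 0.8))
  expect_equal(km$at_risk, c(10L, 9L, 8L, 8L))
  expect_equal(km$events, c(1L, 1L, 0L, 0L))

  skip_if_not_installed("survival")
  time <- ifelse(outcome == 1, onset, 4)
  fit <- survival::survfit(survival::Surv(time, outcome) ~ 1)
  s_fit <- summary(fit, times = 1:4)$surv
  expect_equal(km$survival, s_fit)
})

test_that("zero-event groups stay at survival one; curves never increase", {
  g <- factor(rep(c("a", "b"), each = 20))
  outcome <- withr::with_seed(61, c(rep(0, 20), rbinom(20, 1, 0.5)))
  outcome[21] <- 1
  onset <- withr::with_seed(62,
    ifelse(outcome == 1, sample(1:4, 40, replace = TRUE), NA_integer_))
  km <- km_curves(g, outcome, onset, 4)
  expect_true(all(km$survival[km$group == "a"] == 1))
  for (gr in levels(g))
    expect_true(all(diff(km$survival[km$group == gr]) <= 0))
  expect_error(km_curves(g, outcome, replace(onset, which(outcome == 1)[1],
                                             NA_integer_), 4),
               "onset year")
})
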