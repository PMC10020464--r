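# build an itemset_hypotheses frame directly, for filter-only tests
mk_hyps <- function(conds) {
  df <- data.frame(
    rule = vapply(conds, paste, character(1), collapse = " & "),
    arity = lengths(conds), support = 20L, n11 = 10L, n10 = 10L,
    n01 = 0L, n00 = 0L, raw_p = 1e-8, adjusted_p = 1e-4,
    stringsAsFactors = FALSE)
  df$condition <- conds
  df <- df[, c("condition", setdiff(names(df), "condition"))]
  class(df) <- c("itemset_hypotheses", "data.frame")
  df
}

test_that("a strongly enriched singleton is mined as significant", {
  # planted item carried by all 20 positives and 5 of 180 negatives
  N <- 200
  m <- matrix(0L, N, 3, dimnames = list(NULL, c("planted", "noiseA", "noiseB")))
  y <- rep(c(1, 0), c(20, 180))
  m[c(1:20, 30:34), "planted"] <- 1L
  m[seq(1, N, by = 3), "noiseA"] <- 1L
  m[seq(2, N, by = 2), "noiseB"] <- 1L
  ds <- labeled_dataset(m, y)
  cal <- suppressMessages(calibrate_sigma_star(ds, support_floor = 5))
  hyps <- mine_significant(ds, cal)
  expect_true("planted" %in% hyps$rule)
  expect_true(all(hyps$raw_p < cal$adjusted_level))
  expect_true(all(hyps$support >= cal$sigma_star))
  expect_equal(hyps$adjusted_p, pmin(1, hyps$raw_p * cal$k_sigma_star))
})

test_that("mining equals the brute-force test-everything oracle", {
  withr::with_seed(101, {
    for (i in 1:6) {
      N <- sample(80:200, 1)
      m <- rand_item_matrix(N, 8, p = runif(1, 0.2, 0.6))
      y <- rep(FALSE, N); y[sample(N, sample(10:30, 1))] <- TRUE
      ds <- labeled_dataset(m, y)
      cal <- suppressMessages(
        calibrate_sigma_star(ds, max_arity = 3, support_floor = 5))
      got <- mine_significant(ds, cal)
      want <- brute_mine(m, y, cal$sigma_star, cal$k_sigma_star,
                         0.05, 3)
      expect_identical(cond_key(got$condition), cond_key(want$condition))
    }
  })
})

test_that("mismatched calibration is refused", {
  m <- rand_item_matrix(50, 4, seed = 1)
  y <- rep(c(1, 0), c(10, 40))
  cal <- suppressMessages(
    calibrate_sigma_star(labeled_dataset(m, y), support_floor = 3))
  other <- labeled_dataset(m[1:40, ], y[1:40])
  expect_error(mine_significant(other, cal), "does not match")
})

test_that("superset exclusion retains only the simplest significant conditions", {
  both <- minimal_filter(mk_hyps(list("A", c("A", "B"))))
  expect_equal(both$rules$rule, "A")

  incomparable <- minimal_filter(mk_hyps(list(c("A", "B"), c("A", "C"))))
  expect_setequal(incomparable$rules$rule, c("A & B", "A & C"))

  chain <- minimal_filter(mk_hyps(list("A", c("A", "B"), c("A", "B", "C"))))
  expect_equal(chain$rules$rule, "A")
})

test_that("the retained rule set is an antichain", {
  withr::with_seed(55, {
    m <- rand_item_matrix(150, 7, p = 0.5)
    y <- m[, 1] == 1 & runif(150) < 0.6
    y[1] <- TRUE; y[2] <- FALSE        # guard against degenerate labels
    rs <- suppressMessages(lamp_mine(labeled_dataset(m, y),
                                     support_floor = 5))
    conds <- rs$rules$condition
    if (length(conds) >= 2) {
      for (i in seq_along(conds)) for (j in seq_along(conds)) {
        if (i != j)
          expect_false(length(conds[[i]]) < length(conds[[j]]) &&
                         all(conds[[i]] %in% conds[[j]]))
      }
    }
    expect_identical(cond_key(conds),
                     cond_key(brute_minimal(conds)))
  })
})
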