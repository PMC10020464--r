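test_that("with a single always-frequent item sigma* solves f(sigma) >= alpha", {
  # k_D(sigma) = 1 for every sigma <= N, so the balance condition reduces
  # to f(sigma) >= alpha and sigma* has a closed-form scan solution
  N <- 40; n_p <- 20
  m <- matrix(1L, N, 1, dimnames = list(NULL, "always"))
  y <- rep(c(1, 0), c(n_p, N - n_p))
  cal <- calibrate_sigma_star(labeled_dataset(m, y), alpha = 0.05,
                              max_arity = 1, support_floor = 1)
  feasible <- which(vapply(1:N, function(s) brute_f(s, n_p, N) >= 0.05,
                           logical(1)))
  expect_equal(cal$sigma_star, max(feasible))
  expect_equal(cal$k_sigma_star, 1L)
  expect_equal(cal$adjusted_level, 0.05)
  expect_false(cal$fallback)
})

test_that("sigma* matches the exhaustive scan oracle on toy datasets", {
  withr::with_seed(77, {
    for (i in 1:6) {
      N <- 50
      m <- rand_item_matrix(N, 6, p = runif(1, 0.3, 0.7))
      y <- rep(FALSE, N); y[sample(N, 10)] <- TRUE
      floor <- sample(c(2, 3, 5), 1)
      ds <- labeled_dataset(m, y)
      cal <- suppressMessages(
        calibrate_sigma_star(ds, alpha = 0.05, max_arity = 3,
                             support_floor = floor))
      br <- brute_calibrate(m, y, alpha = 0.05, max_arity = 3, floor = floor)
      expect_equal(cal$sigma_star, br$sigma_star)
      expect_equal(cal$k_sigma_star, br$k_sigma_star)
      expect_equal(cal$adjusted_level, br$adjusted_level)
      expect_equal(cal$fallback, br$fallback)
      # exact Bonferroni identity
      expect_identical(cal$adjusted_level, cal$alpha / cal$k_sigma_star)
    }
  })
})

test_that("sigma* moves against alpha: a laxer level lowers the support threshold", {
  # raising alpha raises the corrected level alpha/k_D(sigma), so the
  # balance f(sigma) >= alpha/k_D(sigma) fails earlier: more hypotheses
  # become testable and sigma* cannot increase
  m <- rand_item_matrix(120, 6, p = 0.6, seed = 13)
  y <- withr::with_seed(14, rbinom(120, 1, 0.4) == 1)
  ds <- labeled_dataset(m, y)
  stars <- vapply(c(0.001, 0.01, 0.05, 0.2),
                  function(a) suppressMessages(
                    calibrate_sigma_star(ds, alpha = a, max_arity = 3,
                                         support_floor = 2))$sigma_star,
                  integer(1))
  expect_true(all(diff(stars) <= 0))
})

test_that("rare outcomes fall back to the pre-declared support floor", {
  m <- rand_item_matrix(500, 8, p = 0.5, seed = 15)
  y <- rep(FALSE, 500); y[1:5] <- TRUE
  expect_message(
    cal <- calibrate_sigma_star(labeled_dataset(m, y), support_floor = 10),
    "support floor")
  expect_true(cal$fallback)
  expect_equal(cal$sigma_star, 10L)
  expect_equal(cal$adjusted_level, 0.05 / cal$k_sigma_star)
})

test_that("the f(sigma-1) variant is at least as permissive", {
  m <- rand_item_matrix(120, 6, p = 0.6, seed = 18)
  y <- withr::with_seed(19, rbinom(120, 1, 0.4) == 1)
  ds <- labeled_dataset(m, y)
  a <- suppressMessages(calibrate_sigma_star(ds, support_floor = 2,
                                             max_arity = 3))
  b <- suppressMessages(calibrate_sigma_star(ds, support_floor = 2,
                                             max_arity = 3,
                                             bound = "f_sigma_minus_one"))
  expect_gte(b$sigma_star, a$sigma_star)
})

test_that("degenerate labels are rejected", {
  m <- rand_item_matrix(30, 3, seed = 20)
  expect_error(calibrate_sigma_star(labeled_dataset(m, rep(0, 30))),
               "degenerate")
  expect_error(calibrate_sigma_star(labeled_dataset(m, rep(1, 30))),
               "degenerate")
})
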