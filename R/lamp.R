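#' Support of an item combination
#'
#' Number of persons carrying every item of the condition; the empty
#' condition is carried by everyone.
#'
#' @param condition character vector of item names (or integer column
#'   indices).
#' @param matrix 0/1 item matrix.
#' @return integer count.
#' @export
item_support <- function(condition, matrix) {
  check_item_matrix(matrix)
  if (length(condition) == 0L) return(nrow(matrix))
  if (is.character(condition)) {
    bad <- setdiff(condition, colnames(matrix))
    if (length(bad))
      stop("unknown item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  } else if (any(condition < 1L | condition > ncol(matrix))) {
    stop("item index out of range", call. = FALSE)
  }
  sum(rowSums(matrix[, condition, drop = FALSE]) == length(condition))
}

#' Minimum attainable one-sided p-value at a given support
#'
#' The Tarone bound: a combination carried by `sigma` persons can never
#' achieve a one-sided Fisher p-value below
#' `f(sigma) = choose(n_p, sigma) / choose(N, sigma)`, the probability that
#' all `sigma` carriers are positives. `f` is 1 at `sigma = 0`, strictly
#' decreasing up to `sigma = n_p`, and 0 beyond (computed on the log scale
#' for numerical stability). Combinations with `f(sigma)` above the
#' corrected level are untestable and need not count towards the
#' Bonferroni factor.
#'
#' @param sigma support value(s), `0 <= sigma <= N` (vectorized).
#' @param n_p number of positive labels, `0 < n_p < N`.
#' @param N total number of persons.
#' @return probability vector, same length as `sigma`.
#' @examples
#' min_attainable_p(2, n_p = 5, N = 100)   # 10 / 4950
#' @export
min_attainable_p <- function(sigma, n_p, N) {
  if (!is_count(N) || !is_count(n_p) || n_p >= N)
    stop("need integers 0 < n_p < N", call. = FALSE)
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma != floor(sigma)) ||
      any(sigma < 0) || any(sigma > N))
    stop("sigma must be integer(s) in [0, N]", call. = FALSE)
  exp(lchoose(n_p, sigma) - lchoose(N, sigma))
}

#' 2x2 contingency table of a combination against the outcome
#'
#' @param n11 carriers with positive label.
#' @param n10 carriers with negative label.
#' @param n01 non-carriers with positive label.
#' @param n00 non-carriers with negative label.
#' @return a `contingency_table` with derived margins `support`
#'   (`n11 + n10`), `n_p` (`n11 + n01`) and `N`.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 support = n11 + n10, n_p = n11 + n01,
                 N = n11 + n10 + n01 + n00),
            class = "contingency_table")
}

# vectorized hypergeometric upper tail P(X >= n11) given margins
hyper_tail_p <- function(n11, support, n_p, N) {
  phyper(n11 - 1, n_p, N - n_p, support, lower.tail = FALSE)
}

#' One-sided Fisher exact p-value (enrichment among positives)
#'
#' Upper-tail hypergeometric probability `P(X >= n11)` for the carrier ×
#' outcome table with fixed margins. One-sided by design: the testability
#' bound [min_attainable_p()] is exactly the one-sided minimum, attained
#' when every carrier is a positive.
#'
#' @param table a [contingency_table()].
#' @return probability.
#' @examples
#' fisher_one_sided_p(contingency_table(2, 0, 3, 5))   # 10 / 45
#' @export
fisher_one_sided_p <- function(table) {
  if (!inherits(table, "contingency_table"))
    stop("table must be a contingency_table()", call. = FALSE)
  hyper_tail_p(table$n11, table$support, table$n_p, table$N)
}

# growing collector for DFS results
new_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$cond <- vector("list", 256L)
  env$sup <- integer(256L)
  env$n11 <- integer(256L)
  env$k <- 0L
  env
}

collector_push <- function(env, condition, support, n11) {
  k <- env$k + 1L
  if (k > length(env$sup)) {
    new_len <- 2L * length(env$sup)
    length(env$cond) <- new_len
    length(env$sup) <- new_len
    length(env$n11) <- new_len
  }
  env$cond[[k]] <- condition
  env$sup[k] <- support
  env$n11[k] <- n11
  env$k <- k
}

#' Enumerate frequent item combinations
#'
#' Depth-first enumeration of every combination of 1 to `max_arity` items
#' carried by at least `sigma` persons. Items are totally ordered by name;
#' the emission order is lexicographic over sorted conditions and the search
#' uses anti-monotone pruning (an infrequent combination is never extended).
#'
#' @param matrix 0/1 item matrix.
#' @param sigma minimum support, `>= 1`.
#' @param max_arity largest combination size.
#' @param labels optional logical outcome vector; when given, each
#'   combination's positive-carrier count `n11` is returned too.
#' @return a `frequent_itemsets` list: `condition` (list of sorted item-name
#'   vectors), `support` (integer), and `n11` when labels were supplied.
#' @export
enumerate_frequent <- function(matrix, sigma, max_arity, labels = NULL) {
  check_item_matrix(matrix)
  if (!is_count(sigma)) stop("sigma must be a positive integer", call. = FALSE)
  if (!is_count(max_arity) || max_arity > ncol(matrix))
    stop("max_arity must be an integer in [1, M]", call. = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(matrix))
    labels <- as.logical(labels)
  }
  nm <- colnames(matrix)
  ord <- order(nm, method = "radix")          # C-locale lexicographic order
  nm_sorted <- nm[ord]
  rowsets <- lapply(ord, function(j) which(matrix[, j] != 0L))
  m <- length(rowsets)
  acc <- new_collector()
  has_labels <- !is.null(labels)

  dfs <- function(prefix, rows, start, depth) {
    if (start > m) return(invisible())
    for (t in start:m) {
      r2 <- if (is.null(rows)) rowsets[[t]] else rows[rows %in% rowsets[[t]]]
      if (length(r2) >= sigma) {
        cond <- c(prefix, nm_sorted[t])
        collector_push(acc, cond, length(r2),
                       if (has_labels) sum(labels[r2]) else NA_integer_)
        if (depth < max_arity) dfs(cond, r2, t + 1L, depth + 1L)
      }
    }
  }
  if (sigma <= nrow(matrix)) dfs(character(0), NULL, 1L, 1L)

  k <- acc$k
  out <- list(condition = acc$cond[seq_len(k)],
              support = acc$sup[seq_len(k)])
  if (has_labels) out$n11 <- acc$n11[seq_len(k)]
  structure(out, items = nm_sorted, sigma = sigma, max_arity = max_arity,
            class = "frequent_itemsets")
}

#' Number of testable hypotheses at a given support threshold
#'
#' `k_D(sigma)`: how many combinations (arity-limited) are carried by at
#' least `sigma` persons. Always computed by mining — the function has no
#' closed form — and non-increasing in `sigma`.
#'
#' @inheritParams enumerate_frequent
#' @return integer count.
#' @export
count_testable <- function(matrix, sigma, max_arity) {
  length(enumerate_frequent(matrix, sigma, max_arity)$support)
}

#' Calibrate the support threshold (Tarone/LAMP balance)
#'
#' Chooses `sigma*` as the largest support threshold in
#' `[support_floor, N]` at which the minimum attainable p-value still
#' dominates the Bonferroni-corrected level:
#' `sigma* = max { sigma : f(sigma) >= alpha / k_D(sigma) }`,
#' scanning upward from the floor and stopping at the first failure
#' (`f` is decreasing while `alpha/k_D` is non-decreasing, so the feasible
#' set is an initial segment). Combinations rarer than `sigma*` can never
#' reach significance at the corrected level, so only the `k_D(sigma*)`
#' frequent ones count towards the Bonferroni factor. When even the floor
#' fails the balance condition — typical for rare outcomes — the procedure
#' falls back to the pre-declared floor: the tested family is then all
#' combinations of arity `<= max_arity` carried by at least `support_floor`
#' persons, Bonferroni-corrected by `k_D(support_floor)`.
#'
#' The `bound = "f_sigma_minus_one"` variant compares `f(sigma - 1)` to the
#' corrected level instead; it is the tight form of the exclusion argument
#' (a hypothesis with support below `sigma` has minimum p at least
#' `f(sigma - 1)`), yielding a slightly larger `sigma*`. The default
#' `"f_sigma"` is the conservative reading.
#'
#' @param dataset a [labeled_dataset()] with `0 < n_p < N`.
#' @param alpha familywise error level.
#' @param max_arity largest combination size searched.
#' @param support_floor pre-declared minimum number of carriers a reportable
#'   combination must have (default 10).
#' @param bound which minimum-p bound to balance against the corrected
#'   level.
#' @return a `lamp_calibration` with `sigma_star`, `k_sigma_star`,
#'   `adjusted_level = alpha / k_sigma_star`, and a `fallback` flag.
#' @export
calibrate_sigma_star <- function(dataset, alpha = 0.05, max_arity = 4L,
                                 support_floor = 10L,
                                 bound = c("f_sigma", "f_sigma_minus_one")) {
  bound <- match.arg(bound)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (dataset$n_p == 0L || dataset$n_p == dataset$n_total)
    stop("degenerate labels: mining needs 0 < n_p < N", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is_count(support_floor))
    stop("support_floor must be a positive integer", call. = FALSE)
  if (!is_count(max_arity))
    stop("max_arity must be a positive integer", call. = FALSE)
  max_arity <- min(max_arity, ncol(dataset$matrix))

  N <- dataset$n_total
  n_p <- dataset$n_p
  supports <- enumerate_frequent(dataset$matrix, support_floor,
                                 max_arity)$support
  k_of <- function(s) sum(supports >= s)

  sigma_star <- NA_integer_
  sigma <- as.integer(support_floor)
  repeat {
    if (sigma > N) break
    k <- k_of(sigma)
    if (k == 0L) break
    f_sig <- if (bound == "f_sigma") sigma else sigma - 1L
    if (min_attainable_p(f_sig, n_p, N) >= alpha / k) {
      sigma_star <- sigma
      sigma <- sigma + 1L
    } else break
  }
  fallback <- is.na(sigma_star)
  if (fallback) {
    sigma_star <- as.integer(support_floor)
    message("calibrate_sigma_star: no sigma in [", support_floor, ", ", N,
            "] balances f(sigma) against alpha/k_D(sigma); ",
            "using the pre-declared support floor ", support_floor)
  }
  k_star <- k_of(sigma_star)
  structure(list(alpha = alpha,
                 sigma_star = sigma_star,
                 k_sigma_star = k_star,
                 adjusted_level = if (k_star > 0L) alpha / k_star else NA_real_,
                 max_arity = as.integer(max_arity),
                 support_floor = as.integer(support_floor),
                 bound = bound,
                 fallback = fallback,
                 n_p = n_p, n_total = N),
            class = "lamp_calibration")
}

#' @export
print.lamp_calibration <- function(x, ...) {
  cat("LAMP calibration\n")
  cat(sprintf("  N = %d persons, n_p = %d positives\n", x$n_total, x$n_p))
  cat(sprintf("  alpha = %g, max arity = %d, support floor = %d\n",
              x$alpha, x$max_arity, x$support_floor))
  cat(sprintf("  sigma* = %d%s, k_D(sigma*) = %d testable hypotheses\n",
              x$sigma_star, if (x$fallback) " (floor fallback)" else "",
              x$k_sigma_star))
  cat(sprintf("  adjusted level alpha/k = %.4g\n", x$adjusted_level))
  invisible(x)
}

#' Mine the significant combinations
#'
#' Tests every combination with support at least `max(sigma*,
#' support_floor)` and arity at most `max_arity` with the one-sided Fisher
#' exact test, keeping those whose raw p-value falls strictly below the
#' calibrated level `alpha / k_D(sigma*)`. Adjusted p-values are the
#' Bonferroni products `min(1, raw_p * k_D(sigma*))`. Output order is the
#' deterministic lexicographic enumeration order.
#'
#' @param dataset the [labeled_dataset()] that `calibration` was computed
#'   from.
#' @param calibration a `lamp_calibration`.
#' @return an `itemset_hypotheses` data.frame: `condition` (list column of
#'   sorted item names), `rule` (collapsed label), `arity`, `support`,
#'   `n11`, `n10`, `n01`, `n00`, `raw_p`, `adjusted_p`; the calibration is
#'   attached as attribute `calibration`.
#' @export
mine_significant <- function(dataset, calibration) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(calibration, "lamp_calibration"))
  if (dataset$n_total != calibration$n_total ||
      dataset$n_p != calibration$n_p)
    stop("calibration does not match the dataset's size or label count",
         call. = FALSE)
  sigma <- max(calibration$sigma_star, calibration$support_floor)
  empty <- data.frame(rule = character(0), arity = integer(0),
                      support = integer(0), n11 = integer(0),
                      n10 = integer(0), n01 = integer(0), n00 = integer(0),
                      raw_p = numeric(0), adjusted_p = numeric(0))
  empty$condition <- list()
  empty <- empty[, c("condition", setdiff(names(empty), "condition"))]
  if (is.na(calibration$adjusted_level) || calibration$k_sigma_star == 0L) {
    attr(empty, "calibration") <- calibration
    class(empty) <- c("itemset_hypotheses", "data.frame")
    return(empty)
  }
  fi <- enumerate_frequent(dataset$matrix, sigma, calibration$max_arity,
                           labels = dataset$labels)
  if (length(fi$support) == 0L) {
    attr(empty, "calibration") <- calibration
    class(empty) <- c("itemset_hypotheses", "data.frame")
    return(empty)
  }
  N <- dataset$n_total
  n_p <- dataset$n_p
  raw_p <- hyper_tail_p(fi$n11, fi$support, n_p, N)
  keep <- raw_p < calibration$adjusted_level
  out <- data.frame(
    rule = vapply(fi$condition[keep], paste, character(1), collapse = " & "),
    arity = lengths(fi$condition[keep]),
    support = fi$support[keep],
    n11 = fi$n11[keep],
    stringsAsFactors = FALSE)
  out$n10 <- out$support - out$n11
  out$n01 <- n_p - out$n11
  out$n00 <- N - n_p - out$n10
  out$raw_p <- raw_p[keep]
  out$adjusted_p <- pmin(1, out$raw_p * calibration$k_sigma_star)
  out$condition <- fi$condition[keep]
  out <- out[, c("condition", "rule", "arity", "support", "n11", "n10",
                 "n01", "n00", "raw_p", "adjusted_p")]
  rownames(out) <- NULL
  attr(out, "calibration") <- calibration
  class(out) <- c("itemset_hypotheses", "data.frame")
  out
}

#' Drop significant combinations that contain a simpler significant one
#'
#' A significant combination whose condition strictly contains another
#' retained, simpler significant condition is trivially significant and is
#' excluded. Retention proceeds by ascending arity, so the result is an
#' antichain under set inclusion.
#'
#' @param hypotheses an `itemset_hypotheses` data.frame (all rows already
#'   significant).
#' @return a `significant_rule_set`: list with `rules` (the retained
#'   hypotheses, ordered by arity then rule label) and `calibration`.
#' @export
minimal_filter <- function(hypotheses) {
  stopifnot(inherits(hypotheses, "itemset_hypotheses"))
  calibration <- attr(hypotheses, "calibration")
  h <- as.data.frame(hypotheses)
  if (nrow(h) > 0L) {
    h <- h[order(h$arity, h$rule, method = "radix"), , drop = FALSE]
    retained_conds <- list()
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      cond <- h$condition[[i]]
      dominated <- any(vapply(retained_conds, function(rc)
        length(rc) < length(cond) && all(rc %in% cond), logical(1)))
      if (!dominated) {
        keep[i] <- TRUE
        retained_conds[[length(retained_conds) + 1L]] <- cond
      }
    }
    h <- h[keep, , drop = FALSE]
    rownames(h) <- NULL
  }
  structure(list(rules = h, calibration = calibration),
            class = "significant_rule_set")
}

#' @export
print.significant_rule_set <- function(x, ...) {
  cat(sprintf("Significant rule set: %d minimal predictive combination(s)\n",
              nrow(x$rules)))
  if (!is.null(x$calibration)) print(x$calibration)
  if (nrow(x$rules) > 0L) {
    show <- head(x$rules[, c("rule", "support", "n11", "raw_p", "adjusted_p")],
                 10L)
    print(show, row.names = FALSE)
    if (nrow(x$rules) > 10L) cat("  ... and", nrow(x$rules) - 10L, "more\n")
  }
  invisible(x)
}

#' End-to-end LAMP mining
#'
#' Calibrate the support threshold, test the testable combinations, and
#' apply the minimality filter.
#'
#' @inheritParams calibrate_sigma_star
#' @return a `significant_rule_set`.
#' @examples
#' m <- matrix(rbinom(200 * 6, 1, 0.4), 200,
#'             dimnames = list(NULL, letters[1:6]))
#' y <- as.integer(m[, "a"] == 1 & runif(200) < 0.6)
#' lamp_mine(labeled_dataset(m, y), support_floor = 5)
#' @export
lamp_mine <- function(dataset, alpha = 0.05, max_arity = 4L,
                      support_floor = 10L,
                      bound = c("f_sigma", "f_sigma_minus_one")) {
  calibration <- calibrate_sigma_star(dataset, alpha = alpha,
                                      max_arity = max_arity,
                                      support_floor = support_floor,
                                      bound = bound)
  minimal_filter(mine_significant(dataset, calibration))
}
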