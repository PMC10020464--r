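#' Count matched predictive combinations per person
#'
#' For each person in the validation cohort, the number of mined rules
#' whose condition the person fully carries — the risk score used for
#' stratification. Monotone in the profile: adding items can never
#' decrease the count.
#'
#' @param matrix 0/1 item matrix of the validation persons.
#' @param rules a `significant_rule_set` (or an `itemset_hypotheses`
#'   data.frame).
#' @return integer vector of per-person match counts.
#' @export
match_count <- function(matrix, rules) {
  check_item_matrix(matrix)
  conds <- if (inherits(rules, "significant_rule_set"))
    rules$rules$condition else rules$condition
  counts <- integer(nrow(matrix))
  if (length(conds) == 0L) return(counts)
  all_items <- unique(unlist(conds))
  missing <- setdiff(all_items, colnames(matrix))
  if (length(missing))
    stop("rule item(s) absent from the person profiles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cond in conds) {
    counts <- counts +
      (rowSums(matrix[, cond, drop = FALSE]) == length(cond))
  }
  counts
}

#' Combination-count group binning
#'
#' Ordered, contiguous inclusive count ranges starting at 0. The default is
#' the six-group scheme 0, 1-50, 51-100, 101-150, 151-200, 201-250. Counts
#' above the top range are handled per `overflow`: an extra labelled bin
#' with a warning (default), clamping into the top bin, or an error.
#'
#' @param upper inclusive upper bounds of the ranges; the first range starts
#'   at 0, each later one starts just above the previous bound.
#' @param overflow `"extra"`, `"clamp"` or `"error"`.
#' @return a `group_binning`.
#' @export
group_binning <- function(upper = c(0, 50, 100, 150, 200, 250),
                          overflow = c("extra", "clamp", "error")) {
  overflow <- match.arg(overflow)
  if (!is.numeric(upper) || length(upper) < 1L || anyNA(upper) ||
      any(upper != floor(upper)) || upper[1] < 0 ||
      is.unsorted(upper, strictly = TRUE))
    stop("upper bounds must be strictly increasing non-negative integers",
         call. = FALSE)
  low <- c(0L, as.integer(head(upper, -1L)) + 1L)
  high <- as.integer(upper)
  if (any(low > high))
    stop("binning ranges must be non-empty", call. = FALSE)
  label <- ifelse(low == high, as.character(low), paste0(low, "-", high))
  structure(list(low = low, high = high, label = label,
                 overflow = overflow,
                 overflow_label = paste0(">", high[length(high)])),
            class = "group_binning")
}

#' Assign persons to combination-count groups
#'
#' @param count integer vector of per-person match counts (`>= 0`).
#' @param binning a [group_binning()].
#' @return factor of group labels, ordered by range; an overflow level is
#'   appended only when the default `"extra"` policy had to use it.
#' @export
assign_group <- function(count, binning = group_binning()) {
  stopifnot(inherits(binning, "group_binning"))
  if (!is.numeric(count) || anyNA(count) || any(count < 0) ||
      any(count != floor(count)))
    stop("counts must be non-negative integers", call. = FALSE)
  top <- binning$high[length(binning$high)]
  over <- count > top
  if (any(over)) {
    switch(binning$overflow,
      error = stop(sum(over), " count(s) exceed the top range (", top, ")",
                   call. = FALSE),
      clamp = {
        warning(sum(over), " count(s) above ", top,
                " clamped into the top group", call. = FALSE)
        count[over] <- top
        over <- rep(FALSE, length(count))
      },
      extra = warning(sum(over), " count(s) above ", top,
                      " placed in an overflow group", call. = FALSE))
  }
  idx <- findInterval(pmin(count, top), binning$low)
  lab <- binning$label[idx]
  levels <- binning$label
  if (any(over)) {
    lab[over] <- binning$overflow_label
    levels <- c(levels, binning$overflow_label)
  }
  factor(lab, levels = levels)
}

#' Per-group incidence table
#'
#' Person counts, event counts and incidence proportions per group; totals
#' are conserved by construction. Empty groups get an `NA` incidence.
#'
#' @param groups factor of group labels, one per person.
#' @param outcome 0/1 outcome vector.
#' @return a `risk_group_table` data.frame with columns `group`, `n`,
#'   `events`, `incidence`.
#' @examples
#' g <- factor(rep(c("0", "1-50"), c(4, 4)))
#' group_incidence(g, c(0, 0, 0, 1, 0, 1, 1, 1))
#' @export
group_incidence <- function(groups, outcome) {
  if (length(groups) != length(outcome))
    stop("one group label and one outcome per person", call. = FALSE)
  if (anyNA(outcome) || !all(outcome %in% c(0, 1, TRUE, FALSE)))
    stop("outcome must be binary with no missing values", call. = FALSE)
  groups <- as.factor(groups)
  outcome <- as.integer(as.logical(outcome))
  n <- as.integer(table(groups))
  events <- as.integer(tapply(outcome, groups, sum, default = 0L))
  out <- data.frame(group = levels(groups), n = n, events = events,
                    incidence = ifelse(n > 0L, events / n, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("risk_group_table", "data.frame")
  out
}

#' Trend test for incidence across ordered groups
#'
#' Primary method: the Cochran–Armitage trend test with integer scores
#' `0..G-1` over the non-empty groups, reported as the signed standard
#' normal statistic `Z` with a two-sided p-value. A chi-square homogeneity
#' test over the same groups is reported alongside.
#'
#' @param table a [group_incidence()] result (or any data.frame with `n`
#'   and `events`).
#' @param scores optional numeric group scores (defaults to consecutive
#'   integers over the non-empty groups; mid-range count scores are a
#'   reasonable alternative).
#' @return a `trend_test_result`: `statistic` (signed Z), `p_value`,
#'   `method`, `scores`, plus `chisq_statistic`, `chisq_df`,
#'   `chisq_p_value`.
#' @export
trend_test <- function(table, scores = NULL) {
  stopifnot(is.data.frame(table), all(c("n", "events") %in% names(table)))
  keep <- table$n > 0L
  if (any(!keep))
    message("trend_test: dropping ", sum(!keep), " empty group(s)")
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) < 2L)
    stop("trend test needs at least two non-empty groups", call. = FALSE)
  s <- scores %||% (seq_len(nrow(tab)) - 1)
  if (length(s) != nrow(tab))
    stop("need one score per non-empty group", call. = FALSE)
  n <- tab$n; d <- tab$events
  N <- sum(n); E <- sum(d)
  pbar <- E / N
  num <- sum(s * (d - n * pbar))
  v <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N)
  z <- if (v > 0) num / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  chi <- suppressWarnings(chisq.test(cbind(d, n - d), correct = FALSE))
  structure(list(statistic = z, p_value = p,
                 method = "Cochran-Armitage trend test (two-sided)",
                 scores = s,
                 chisq_statistic = unname(chi$statistic),
                 chisq_df = unname(chi$parameter),
                 chisq_p_value = unname(chi$p.value)),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  Z = %.4f, p = %.4g  (scores: %s)\n", x$statistic,
              x$p_value, paste(x$scores, collapse = ", ")))
  cat(sprintf("  chi-square homogeneity: X2 = %.4f, df = %d, p = %.4g\n",
              x$chisq_statistic, x$chisq_df, x$chisq_p_value))
  invisible(x)
}

#' Discrete-time Kaplan-Meier curves per group
#'
#' Product-limit estimator on the annual follow-up grid. Events occur at
#' integer years; event-free persons are administratively censored at the
#' end of follow-up, so they remain at risk through every year.
#'
#' @param groups factor of group labels.
#' @param outcome 0/1 outcome vector.
#' @param onset_year integer onset year for events (1..`follow_up_years`),
#'   `NA` for event-free persons.
#' @param follow_up_years length of follow-up.
#' @return a `km_curve_table` data.frame: `group`, `year`, `at_risk`,
#'   `events`, `survival`.
#' @export
km_curves <- function(groups, outcome, onset_year, follow_up_years) {
  stopifnot(length(groups) == length(outcome),
            length(onset_year) == length(outcome))
  if (!is_count(follow_up_years))
    stop("follow_up_years must be a positive integer", call. = FALSE)
  outcome <- as.logical(outcome)
  if (any(outcome & (is.na(onset_year) | onset_year < 1 |
                     onset_year > follow_up_years)))
    stop("every event needs an onset year in 1..follow_up_years",
         call. = FALSE)
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    in_g <- groups == g
    ev <- outcome[in_g]
    yr <- onset_year[in_g]
    n_g <- sum(in_g)
    at_risk <- events <- integer(follow_up_years)
    surv <- numeric(follow_up_years)
    s <- 1
    for (t in seq_len(follow_up_years)) {
      r <- n_g - sum(ev & yr < t)
      d <- sum(ev & yr == t)
      if (r > 0L) s <- s * (1 - d / r)
      at_risk[t] <- r; events[t] <- d; surv[t] <- s
    }
    data.frame(group = g, year = seq_len(follow_up_years),
               at_risk = at_risk, events = events, survival = surv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("km_curve_table", "data.frame")
  out
}
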