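# Brute-force oracles: same definitions as the package, no pruning, no
# shared code paths. Everything here enumerates exhaustively.

# uniform integer in [lo, hi] without sample()'s scalar surprise
rint <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

rand_item_matrix <- function(n, m, p = 0.5, seed = NULL) {
  draw <- function() matrix(rbinom(n * m, 1L, p), n, m,
                            dimnames = list(NULL, sprintf("i%02d", seq_len(m))))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# all item subsets of size 1..max_arity, sorted names, lexicographic order
brute_subsets <- function(item_names, max_arity) {
  nms <- sort(item_names)
  out <- unlist(lapply(seq_len(max_arity), function(k)
    combn(nms, k, simplify = FALSE)), recursive = FALSE)
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

brute_support <- function(cond, mat) {
  sum(rowSums(mat[, cond, drop = FALSE]) == length(cond))
}

brute_enumerate <- function(mat, sigma, max_arity) {
  subs <- brute_subsets(colnames(mat), max_arity)
  sup <- vapply(subs, brute_support, integer(1), mat = mat)
  keep <- sup >= sigma
  list(condition = subs[keep], support = sup[keep])
}

brute_f <- function(sigma, n_p, N) choose(n_p, sigma) / choose(N, sigma)

# hypergeometric upper tail by explicit summation
brute_fisher_p <- function(n11, support, n_p, N) {
  xs <- n11:min(support, n_p)
  if (length(xs) == 0L) return(0)
  sum(choose(n_p, xs) * choose(N - n_p, support - xs)) / choose(N, support)
}

# scan every sigma; same selection rule as the package, independent code
brute_calibrate <- function(mat, labels, alpha, max_arity, floor) {
  N <- nrow(mat); n_p <- sum(labels)
  subs <- brute_subsets(colnames(mat), max_arity)
  sup <- vapply(subs, brute_support, integer(1), mat = mat)
  feasible <- integer(0)
  for (sigma in floor:N) {
    k <- sum(sup >= sigma)
    if (k == 0L) break
    if (brute_f(sigma, n_p, N) >= alpha / k) feasible <- c(feasible, sigma)
    else break
  }
  sigma_star <- if (length(feasible)) max(feasible) else floor
  k_star <- sum(sup >= sigma_star)
  list(sigma_star = sigma_star, k_sigma_star = k_star,
       adjusted_level = alpha / k_star,
       fallback = length(feasible) == 0L)
}

brute_mine <- function(mat, labels, sigma_star, k_star, alpha, max_arity) {
  N <- nrow(mat); n_p <- sum(labels)
  subs <- brute_subsets(colnames(mat), max_arity)
  sup <- vapply(subs, brute_support, integer(1), mat = mat)
  keep <- sup >= sigma_star
  subs <- subs[keep]; sup <- sup[keep]
  n11 <- vapply(subs, function(cc)
    sum(labels[rowSums(mat[, cc, drop = FALSE]) == length(cc)]), numeric(1))
  p <- mapply(brute_fisher_p, n11, sup, MoreArgs = list(n_p = n_p, N = N))
  sig <- p < alpha / k_star
  list(condition = subs[sig], support = sup[sig], n11 = n11[sig],
       raw_p = p[sig])
}

brute_minimal <- function(conds) {
  keep <- rep(TRUE, length(conds))
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (i != j && length(conds[[j]]) < length(conds[[i]]) &&
        all(conds[[j]] %in% conds[[i]])) { keep[i] <- FALSE; break }
  }
  conds[keep]
}

cond_key <- function(conds) sort(vapply(conds, paste, character(1),
                                        collapse = "+"))

# recovery-study configuration: planted 1-, 2- and 3-item rules with
# hazard ratio 5 among 16 generic binary indicators
recovery_config <- function(n, seed, multiplier = 5) {
  rule_vars <- c("r1", "r2a", "r2b", "r3a", "r3b", "r3c")
  noise_vars <- sprintf("z%02d", 1:10)
  specs <- c(lapply(rule_vars, var_binary, prob = 0.5),
             lapply(noise_vars, var_binary, prob = 0.3))
  scheme <- binarization_scheme(lapply(c(rule_vars, noise_vars), function(v)
    bin_item(v, v, "eq", 1)))
  simulation_config(
    n_persons = n, seed = seed, variable_specs = specs, scheme = scheme,
    planted_rules = list(planted_rule("r1", multiplier),
                         planted_rule(c("r2a", "r2b"), multiplier),
                         planted_rule(c("r3a", "r3b", "r3c"), multiplier)),
    baseline_annual_hazard = 0.0025, follow_up_years = 4L)
}
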