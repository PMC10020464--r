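#' Split a cohort into analysis and validation parts
#'
#' Random, disjoint, exhaustive partition with the analysis size equal to
#' `round(fraction * N)`; deterministic for a given seed. The default
#' fraction mirrors a 32,547 / 308,205 two-protocol design.
#'
#' @param cohort cohort data.frame.
#' @param fraction analysis-cohort fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `analysis` and `validation` data.frames.
#' @export
split_cohort <- function(cohort, fraction = 32547 / 308205, seed) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n < 2L) stop("cohort must have at least 2 rows to split", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  n_a <- round(fraction * n)
  if (n_a < 1L || n_a > n - 1L)
    stop("fraction leaves an empty analysis or validation part",
         call. = FALSE)
  idx <- sort(withr::with_seed(seed, sample.int(n, n_a)))
  list(analysis = cohort[idx, , drop = FALSE],
       validation = cohort[-idx, , drop = FALSE])
}

#' Pipeline configuration
#'
#' Everything needed for the two-protocol run: the simulation
#' configuration, the split fraction and seed, the mining parameters and
#' the stratification binning. Splitting happens before any calibration, so
#' the validation cohort never influences the mined rule set.
#'
#' @param sim a [simulation_config()].
#' @param split_seed seed of the random allocation into analysis and
#'   validation cohorts.
#' @param split_fraction analysis fraction (default 32,547 / 308,205).
#' @param alpha familywise error level for mining.
#' @param max_arity,support_floor,bound see [calibrate_sigma_star()].
#' @param binning a [group_binning()].
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(sim, split_seed,
                            split_fraction = 32547 / 308205,
                            alpha = 0.05, max_arity = 4L,
                            support_floor = 10L,
                            bound = "f_sigma",
                            binning = group_binning()) {
  stopifnot(inherits(sim, "simulation_config"),
            inherits(binning, "group_binning"))
  if (!is_count(split_seed, min = -.Machine$integer.max))
    stop("an integer split_seed is required", call. = FALSE)
  structure(list(sim = sim, split_seed = as.integer(split_seed),
                 split_fraction = split_fraction, alpha = alpha,
                 max_arity = as.integer(max_arity),
                 support_floor = as.integer(support_floor),
                 bound = bound, binning = binning),
            class = "pipeline_config")
}

pipeline_provenance <- function(config) {
  list(package = "lamprisk",
       package_version = as.character(packageVersion("lamprisk")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed_simulate = config$sim$seed,
       seed_split = config$split_seed,
       config_hash = config_hash(list(
         n_persons = config$sim$n_persons,
         seed = config$sim$seed,
         baseline_annual_hazard = config$sim$baseline_annual_hazard,
         follow_up_years = config$sim$follow_up_years,
         planted_rules = lapply(config$sim$planted_rules, unclass),
         split_seed = config$split_seed,
         split_fraction = config$split_fraction,
         alpha = config$alpha, max_arity = config$max_arity,
         support_floor = config$support_floor, bound = config$bound)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full two-protocol pipeline
#'
#' simulate -> split -> binarize -> calibrate/mine/filter on the analysis
#' cohort -> match counts, grouping, incidence, trend test and
#' Kaplan-Meier curves on the validation cohort. Idempotent for a given
#' configuration; with `out_dir` set, all artifacts are written (rules as
#' JSON and CSV, group table, trend test, KM curves, and a provenance
#' manifest carrying the seeds and config hash).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return report bundle: list with `rules`, `calibration`, `risk_groups`,
#'   `trend`, `km`, `match_counts`, `split_sizes`, `truth`, `provenance`
#'   (and, invisibly large, the `cohort`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- run_stage("simulate", generate_raw_cohort(config$sim))
  parts <- run_stage("split",
    split_cohort(gen$cohort, config$split_fraction, config$split_seed))
  ds <- run_stage("binarize",
    labeled_dataset_from_cohort(parts$analysis, config$sim$scheme))
  rules <- run_stage("mine",
    lamp_mine(ds, alpha = config$alpha, max_arity = config$max_arity,
              support_floor = config$support_floor, bound = config$bound))
  vmat <- run_stage("binarize_validation",
    binarize(parts$validation, config$sim$scheme))
  counts <- run_stage("match", match_count(vmat, rules))
  groups <- run_stage("stratify",
    suppressWarnings(assign_group(counts, config$binning)))
  tab <- run_stage("incidence",
    group_incidence(groups, parts$validation$outcome))
  trend <- if (sum(tab$n > 0L) >= 2L)
    run_stage("trend", trend_test(tab)) else NULL
  km <- run_stage("km",
    km_curves(groups, parts$validation$outcome,
              parts$validation$onset_year, config$sim$follow_up_years))
  bundle <- list(rules = rules,
                 calibration = rules$calibration,
                 risk_groups = tab,
                 trend = trend,
                 km = km,
                 match_counts = counts,
                 split_sizes = c(analysis = nrow(parts$analysis),
                                 validation = nrow(parts$validation)),
                 truth = gen$truth,
                 cohort = gen$cohort,
                 provenance = pipeline_provenance(config))
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

# ---- file I/O ---------------------------------------------------------------

provenance_comment <- function(prov) {
  sprintf("# provenance: config_hash=%s seed_simulate=%d seed_split=%d lamprisk=%s",
          prov$config_hash, prov$seed_simulate, prov$seed_split,
          prov$package_version)
}

write_csv_with_provenance <- function(df, path, prov) {
  writeLines(provenance_comment(prov), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
}

#' Read and write rule sets as JSON
#'
#' The JSON carries the calibration block (alpha, sigma*, k_D(sigma*),
#' adjusted level) and one record per rule with the sorted condition item
#' names, support, carrier-positive count and raw/adjusted p-values.
#'
#' @param rules a `significant_rule_set`.
#' @param path file path.
#' @param provenance optional provenance list stored alongside.
#' @export
write_rules_json <- function(rules, path, provenance = NULL) {
  stopifnot(inherits(rules, "significant_rule_set"))
  cal <- rules$calibration
  payload <- list(
    calibration = list(alpha = cal$alpha, sigma_star = cal$sigma_star,
                       k_sigma_star = cal$k_sigma_star,
                       adjusted_level = cal$adjusted_level,
                       max_arity = cal$max_arity,
                       support_floor = cal$support_floor,
                       bound = cal$bound, fallback = cal$fallback,
                       n_p = cal$n_p, n_total = cal$n_total),
    rules = lapply(seq_len(nrow(rules$rules)), function(i) {
      r <- rules$rules[i, ]
      list(condition = r$condition[[1]], support = r$support,
           n11 = r$n11, raw_p = r$raw_p, adjusted_p = r$adjusted_p)
    }))
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path) {
  payload <- jsonlite::read_json(path)
  cal <- payload$calibration
  calibration <- structure(list(
    alpha = cal$alpha, sigma_star = as.integer(cal$sigma_star),
    k_sigma_star = as.integer(cal$k_sigma_star),
    adjusted_level = cal$adjusted_level,
    max_arity = as.integer(cal$max_arity),
    support_floor = as.integer(cal$support_floor),
    bound = cal$bound, fallback = isTRUE(cal$fallback),
    n_p = as.integer(cal$n_p), n_total = as.integer(cal$n_total)),
    class = "lamp_calibration")
  conds <- lapply(payload$rules, function(r)
    sort(unlist(r$condition, use.names = FALSE)))
  rules <- data.frame(
    rule = vapply(conds, paste, character(1), collapse = " & "),
    arity = lengths(conds),
    support = vapply(payload$rules, function(r) as.integer(r$support),
                     integer(1)),
    n11 = vapply(payload$rules, function(r) as.integer(r$n11), integer(1)),
    raw_p = vapply(payload$rules, function(r) as.numeric(r$raw_p),
                   numeric(1)),
    adjusted_p = vapply(payload$rules, function(r) as.numeric(r$adjusted_p),
                        numeric(1)),
    stringsAsFactors = FALSE)
  rules$condition <- conds
  rules <- rules[, c("condition", setdiff(names(rules), "condition"))]
  structure(list(rules = rules, calibration = calibration),
            class = "significant_rule_set")
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- bundle$provenance
  write_rules_json(bundle$rules, file.path(out_dir, "rules.json"),
                   provenance = prov)
  flat <- bundle$rules$rules
  if (nrow(flat) > 0L) flat$condition <- NULL
  write_csv_with_provenance(flat, file.path(out_dir, "rules.csv"), prov)
  write_csv_with_provenance(bundle$risk_groups,
                            file.path(out_dir, "risk_groups.csv"), prov)
  write_csv_with_provenance(bundle$km, file.path(out_dir, "km_curves.csv"),
                            prov)
  if (!is.null(bundle$trend))
    jsonlite::write_json(c(unclass(bundle$trend), list(provenance = prov)),
                         file.path(out_dir, "trend_test.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(prov, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read and write cohort tables
#'
#' Plain CSV: one row per person, `person_id`, the raw variables, `outcome`
#' (0/1) and `onset_year` (empty for event-free persons).
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Load a simulation configuration from YAML or JSON
#'
#' Mirrors the [simulation_config()] fields; `seed` is mandatory.
#' `variable_specs` entries carry `name`, `kind` and the distribution
#' parameters; `planted_rules` entries carry `items` and `multiplier`.
#' Omitted sections fall back to the package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `simulation_config`.
#' @export
simulation_config_from_file <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("config file must set a seed", call. = FALSE)
  specs <- if (is.null(raw$variable_specs)) default_variable_specs()
  else lapply(raw$variable_specs, function(s) {
    switch(s$kind,
      continuous = var_continuous(s$name, s$median, s$q1, s$q3,
                                  family = s$family %||% "normal",
                                  digits = s$digits %||% 1),
      binary = var_binary(s$name, s$prob),
      categorical = var_categorical(s$name, unlist(s$levels),
                                    unlist(s$probs)),
      stop("unknown variable kind '", s$kind, "' for '", s$name, "'",
           call. = FALSE))
  })
  rules <- if (is.null(raw$planted_rules)) default_planted_rules()
  else lapply(raw$planted_rules, function(r)
    planted_rule(unlist(r$items), r$multiplier))
  simulation_config(
    n_persons = raw$n_persons,
    seed = raw$seed,
    variable_specs = specs,
    planted_rules = rules,
    baseline_annual_hazard = raw$baseline_annual_hazard %||% 0.0025,
    follow_up_years = raw$follow_up_years %||% 4L,
    missing_rate = raw$missing_rate %||% 0)
}
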