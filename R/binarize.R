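#' Binarization scheme
#'
#' A scheme maps raw clinical variables to binary indicator items: a
#' threshold direction and cutoff for continuous variables, a level (or set
#' of levels) for categorical ones, and explicit negation items for habit
#' indicators (e.g. `non_smoker`), since protective combinations such as
#' "no smoking" are part of the search space.
#'
#' @param item name of the produced binary item (unique within a scheme).
#' @param variable raw variable the predicate reads.
#' @param op one of `"ge"`, `"gt"`, `"le"`, `"lt"` (numeric threshold),
#'   `"eq"`, `"ne"` (single value) or `"in"` (set membership).
#' @param value threshold, level or level set.
#' @return `bin_item` / `binarization_scheme` objects.
#' @examples
#' binarization_scheme(list(
#'   bin_item("sbp_ge_140", "sbp", "ge", 140),
#'   bin_item("non_smoker", "smoker", "eq", 0)
#' ))
#' @export
bin_item <- function(item, variable, op = c("ge", "gt", "le", "lt", "eq", "ne", "in"),
                     value) {
  op <- match.arg(op)
  if (!is.character(item) || length(item) != 1L || !nzchar(item))
    stop("item name must be a non-empty string", call. = FALSE)
  if (op %in% c("ge", "gt", "le", "lt") &&
      (!is.numeric(value) || length(value) != 1L || !is.finite(value)))
    stop("item '", item, "': threshold predicates need a single finite cutoff",
         call. = FALSE)
  if (op %in% c("eq", "ne") && length(value) != 1L)
    stop("item '", item, "': eq/ne predicates need a single value",
         call. = FALSE)
  structure(list(item = item, variable = variable, op = op, value = value),
            class = "bin_item")
}

#' @rdname bin_item
#' @param items list of [bin_item()] rules.
#' @export
binarization_scheme <- function(items) {
  if (!length(items) || !all(vapply(items, inherits, logical(1), "bin_item")))
    stop("a scheme is a non-empty list of bin_item() rules", call. = FALSE)
  nm <- vapply(items, function(it) it$item, character(1))
  if (anyDuplicated(nm))
    stop("duplicate item names in scheme: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  structure(list(items = items), class = "binarization_scheme")
}

#' Default binarization scheme
#'
#' Cutoffs follow standard Japanese clinical guideline thresholds
#' (hypertension 140/90 with an elevated band at 130/85, obesity BMI >= 25,
#' metabolic-syndrome waist 85 cm, HbA1c 5.6/6.0/6.5, dyslipidemia
#' LDL >= 140, HDL < 40, TG >= 150, liver enzymes >= 31 IU/L, gamma-GTP
#' >= 51 IU/L, hyperuricemia >= 7 mg/dL, anemia Hb < 12 g/dL), plus
#' indicator and negation items for habits, prescriptions and check-up
#' findings. 37 items in total.
#'
#' @return a [binarization_scheme()].
#' @export
default_binarization_scheme <- function() {
  binarization_scheme(list(
    bin_item("age_ge_55",  "age",   "ge", 55),
    bin_item("age_ge_65",  "age",   "ge", 65),
    bin_item("bmi_ge_25",  "bmi",   "ge", 25),
    bin_item("bmi_lt_18p5", "bmi",  "lt", 18.5),
    bin_item("abd_ge_85",  "abd_circumference", "ge", 85),
    bin_item("sbp_ge_130", "sbp",   "ge", 130),
    bin_item("sbp_ge_140", "sbp",   "ge", 140),
    bin_item("dbp_ge_85",  "dbp",   "ge", 85),
    bin_item("dbp_ge_90",  "dbp",   "ge", 90),
    bin_item("hb_lt_12",   "hb",    "lt", 12),
    bin_item("hba1c_ge_5p6", "hba1c", "ge", 5.6),
    bin_item("hba1c_ge_6p0", "hba1c", "ge", 6.0),
    bin_item("hba1c_ge_6p5", "hba1c", "ge", 6.5),
    bin_item("hdl_lt_40",  "hdl",   "lt", 40),
    bin_item("ldl_ge_140", "ldl",   "ge", 140),
    bin_item("ldl_ge_160", "ldl",   "ge", 160),
    bin_item("tg_ge_150",  "tg",    "ge", 150),
    bin_item("ast_ge_31",  "ast",   "ge", 31),
    bin_item("alt_ge_31",  "alt",   "ge", 31),
    bin_item("ggt_ge_51",  "ggt",   "ge", 51),
    bin_item("ua_ge_7",    "ua",    "ge", 7),
    bin_item("female",     "female", "eq", 1),
    bin_item("male",       "female", "eq", 0),
    bin_item("smoker",     "smoker", "eq", 1),
    bin_item("non_smoker", "smoker", "eq", 0),
    bin_item("exercise_30min",    "exercise_30min", "eq", 1),
    bin_item("no_exercise_30min", "exercise_30min", "eq", 0),
    bin_item("weight_change_2kg", "weight_change_2kg", "eq", 1),
    bin_item("aspirin_use",       "aspirin_use", "eq", 1),
    bin_item("rosuvastatin_use",  "rosuvastatin_use", "eq", 1),
    bin_item("alcohol_daily", "alcohol", "eq", "daily"),
    bin_item("alcohol_none",  "alcohol", "eq", "none"),
    bin_item("urinary_sugar_pos",   "urinary_sugar",
             "in", c("1plus", "2plus", "3plus", "4plus")),
    bin_item("urinary_protein_pos", "urinary_protein",
             "in", c("1plus", "2plus", "3plus", "4plus")),
    bin_item("ecg_abnormal", "ecg_finding", "in", c("C", "H")),
    bin_item("cxr_abnormal", "cxr_finding", "in", c("C", "H"))
  ))
}

#' Binarize a cohort table into an item matrix
#'
#' Applies every scheme predicate to its raw variable; the result is the
#' N x M 0/1 data table the mining stage works on. Row order is preserved.
#' Missing raw values map to item absence under the default policy (the
#' imputed count is reported via a message and an attribute), or raise an
#' error under `missing_policy = "error"`.
#'
#' @param cohort data.frame of raw variables.
#' @param scheme a [binarization_scheme()].
#' @param missing_policy `"zero"` (default) or `"error"`.
#' @return integer 0/1 matrix with item names as columns; attributes
#'   `person_id` and `n_missing_imputed`.
#' @export
binarize <- function(cohort, scheme, missing_policy = c("zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(cohort))
  if (!inherits(scheme, "binarization_scheme"))
    stop("scheme must be a binarization_scheme()", call. = FALSE)
  need <- unique(vapply(scheme$items, function(it) it$variable, character(1)))
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stop("cohort table lacks variable(s) required by the scheme: ",
         paste(absent, collapse = ", "), call. = FALSE)

  n <- nrow(cohort)
  m <- length(scheme$items)
  out <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(NULL,
                                vapply(scheme$items, function(it) it$item,
                                       character(1))))
  n_imputed <- 0L
  for (j in seq_len(m)) {
    it <- scheme$items[[j]]
    v <- cohort[[it$variable]]
    val <- switch(it$op,
      ge = v >= it$value,
      gt = v >  it$value,
      le = v <= it$value,
      lt = v <  it$value,
      eq = v == it$value,
      ne = v != it$value,
      `in` = if (anyNA(v)) ifelse(is.na(v), NA, v %in% it$value)
             else v %in% it$value)
    miss <- is.na(val)
    if (any(miss)) {
      if (missing_policy == "error")
        stop("missing value(s) in variable '", it$variable,
             "' while binarizing item '", it$item, "'", call. = FALSE)
      val[miss] <- FALSE
      n_imputed <- n_imputed + sum(miss)
    }
    out[, j] <- as.integer(val)
  }
  if (n_imputed > 0L)
    message("binarize: ", n_imputed,
            " missing cell(s) treated as item absence")
  attr(out, "person_id") <- if ("person_id" %in% names(cohort))
    cohort$person_id else seq_len(n)
  attr(out, "n_missing_imputed") <- n_imputed
  out
}

#' Labeled dataset for mining
#'
#' Couples a binary item matrix with the outcome labels (and optional onset
#' years). Mining requires `0 < n_p < N`.
#'
#' @param matrix 0/1 item matrix (items as named columns).
#' @param labels binary outcome vector, one per row.
#' @param onset_year optional integer onset years (`NA` for event-free).
#' @return a `labeled_dataset` with fields `matrix`, `labels` (logical),
#'   `n_p`, `n_total`, `onset_year`.
#' @export
labeled_dataset <- function(matrix, labels, onset_year = NULL) {
  check_item_matrix(matrix)
  if (length(labels) != nrow(matrix))
    stop("labels must have one entry per matrix row", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0, 1, TRUE, FALSE)))
    stop("labels must be binary with no missing values", call. = FALSE)
  labels <- as.logical(labels)
  if (!is.null(onset_year) && length(onset_year) != nrow(matrix))
    stop("onset_year must have one entry per matrix row", call. = FALSE)
  structure(list(matrix = matrix, labels = labels,
                 n_p = sum(labels), n_total = nrow(matrix),
                 onset_year = onset_year),
            class = "labeled_dataset")
}

#' @rdname labeled_dataset
#' @param cohort raw cohort data.frame with an `outcome` column (0/1) and
#'   optionally `onset_year`.
#' @param scheme binarization scheme applied to the raw variables.
#' @export
labeled_dataset_from_cohort <- function(cohort, scheme) {
  if (!"outcome" %in% names(cohort))
    stop("cohort has no 'outcome' column", call. = FALSE)
  labeled_dataset(binarize(cohort, scheme), cohort$outcome,
                  onset_year = cohort$onset_year)
}
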