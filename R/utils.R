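`%||%` <- function(a, b) if (is.null(a)) b else a

# single positive whole number
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Short stable fingerprint of a configuration, used in provenance blocks.
# Polynomial rolling hash over the canonical JSON encoding; not cryptographic,
# just enough to tell two configurations apart in a manifest.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                                     force = TRUE, null = "null"))
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# validate a 0/1 item matrix with unique column names
check_item_matrix <- function(matrix) {
  if (!is.matrix(matrix) || is.null(colnames(matrix)))
    stop("item matrix must be a matrix with item names as column names",
         call. = FALSE)
  if (nrow(matrix) < 1L || ncol(matrix) < 1L)
    stop("item matrix must have at least one row and one column", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("item names must be unique", call. = FALSE)
  if (anyNA(matrix) || !all(matrix == 0L | matrix == 1L))
    stop("item matrix cells must all be 0 or 1", call. = FALSE)
  invisible(matrix)
}
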