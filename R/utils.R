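# Internal validation helpers shared across modules.

# An expression matrix is numeric, features x samples, with unique non-empty
# dimnames. Most entry points funnel through here so error wording is uniform.
check_expr <- function(expr, min_samples = 1L, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    rlang::abort(sprintf("`%s` must be a numeric matrix (features x samples).", arg))
  }
  if (nrow(expr) < 1L || ncol(expr) < min_samples) {
    rlang::abort(sprintf(
      "`%s` must have >= 1 feature and >= %d sample(s).", arg, min_samples
    ))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    rlang::abort(sprintf("`%s` must carry feature rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    rlang::abort(sprintf("`%s` has duplicated feature or sample identifiers.", arg))
  }
  invisible(expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s.", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  as.numeric(x)
}

# Survival tables come in as data frames with sample_id/time/event columns.
check_survival <- function(records, arg = "records") {
  if (!is.data.frame(records)) {
    rlang::abort(sprintf("`%s` must be a data frame of survival records.", arg))
  }
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    rlang::abort(sprintf(
      "`%s` is missing column(s): %s.", arg, paste(miss, collapse = ", ")
    ))
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    rlang::abort(sprintf("`%s$time` must be finite and > 0.", arg))
  }
  if (!all(records$event %in% c(0, 1))) {
    rlang::abort(sprintf("`%s$event` must be 0 (censored) or 1 (event).", arg))
  }
  if (anyDuplicated(records$sample_id)) {
    rlang::abort(sprintf("`%s$sample_id` must be unique.", arg))
  }
  invisible(records)
}

# Seeded evaluation that does not disturb the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

row_means_by <- function(expr, groups) {
  vapply(
    split(seq_len(ncol(expr)), groups),
    function(j) rowMeans(expr[, j, drop = FALSE]),
    numeric(nrow(expr))
  )
}

row_sds <- function(expr) {
  n <- ncol(expr)
  m <- rowMeans(expr)
  sqrt(pmax(rowSums((expr - m)^2), 0) / (n - 1))
}
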