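#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator over the event times, with the median survival
#' defined as the first time at which the estimated survival drops to 0.5
#' or below; when the curve never reaches 0.5 the median is "not reached",
#' encoded as `NA` with `median_reached = FALSE` (never as a number).
#'
#' @param records Survival data frame (`sample_id`, `time`, `event`).
#' @return A `km_fit`: `$steps` tibble (`time`, `n_risk`, `n_event`,
#'   `surv`), `$median` (`NA` if not reached), `$median_reached`.
#' @export
km_estimate <- function(records) {
  check_survival(records)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  steps <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv
  )
  reached <- any(steps$surv <= 0.5)
  med <- if (reached) min(steps$time[steps$surv <= 0.5]) else NA_real_
  structure(list(steps = steps, median = med, median_reached = reached,
                 n = nrow(records), n_events = sum(records$event)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n", x$n, x$n_events,
              if (x$median_reached) format(x$median) else "not reached"))
  invisible(x)
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @describeIn km_estimate Step plot of the estimated survival curve.
#' @param object A `km_fit`.
#' @param ... Unused.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1),
    object$steps[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank over the pooled event times
#' with `df = groups - 1`, via [survival::survdiff()].
#'
#' @param records Survival data frame.
#' @param group Vector of group labels, one per record (or the name of a
#'   column of `records`).
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records, group) {
  check_survival(records)
  if (length(group) == 1L && is.character(group) && group %in% names(records)) {
    group <- records[[group]]
  }
  if (length(group) != nrow(records)) {
    rlang::abort("`group` must supply one label per record.")
  }
  g <- factor(group)
  if (nlevels(g) < 2L) rlang::abort("Need >= 2 non-empty groups.")
  if (sum(records$event) == 0) rlang::abort("No events: log-rank undefined.")
  df_in <- data.frame(time = records$time, event = records$event, g = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df_in)
  df <- nlevels(g) - 1L
  tibble::tibble(
    chisq = unname(sd_$chisq), df = df,
    p = pchisq(unname(sd_$chisq), df = df, lower.tail = FALSE)
  )
}

#' Permutation survival-association screening
#'
#' Per-feature association between expression and progression-free survival
#' via the Cox score test at `beta = 0`: observed statistic
#' `U^2 / V` with `U = sum over events of (x_i - mean of x over the risk
#' set)` and `V` the corresponding score variance. The permutation p-value
#' pairs each feature with `n_perm` random permutations of the (time, event)
#' records against the expression columns, using the score numerator `|U|`
#' (a linear functional of the expression values, so all permutations are a
#' single matrix product) as the permutation statistic, with the +1
#' correction `p = (1 + #{|U*| >= |U|}) / (1 + n_perm)`.
#'
#' This is the package's stand-in for per-feature Cox screening of the
#' "most-variable" features: inputs (feature matrix, survival records,
#' permutation count) and output (a ranked list of per-feature p-values)
#' match that screening contract.
#'
#' @param expr log2 feature x sample matrix; columns must cover the
#'   record sample ids.
#' @param records Survival data frame.
#' @param n_perm Number of permutations (a warning is issued below 100).
#' @param seed Integer seed (mandatory).
#' @return Tibble with `feature_id`, `score_stat` (U^2/V), `p_asymptotic`
#'   (chi-square 1 df) and `p` (permutation), sorted by `p` then statistic.
#' @export
screen_features_perm <- function(expr, records, n_perm = 1000L, seed) {
  check_expr(expr, min_samples = 3L)
  check_survival(records)
  if (missing(seed)) rlang::abort("`seed` is required for permutations.")
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100) rlang::warn("Fewer than 100 permutations: p-values are coarse.")
  miss <- setdiff(records$sample_id, colnames(expr))
  if (length(miss)) {
    rlang::abort(sprintf("Records missing from expression matrix: %s",
                         paste(head(miss, 5), collapse = ", ")))
  }
  if (sum(records$event) < 1) rlang::abort("Need >= 1 event.")
  x <- expr[, records$sample_id, drop = FALSE]
  n <- ncol(x)

  # score coefficients: U_f = sum_j a_j x_fj with
  # a_j = delta_j - sum_{event times t_i <= t_j} 1 / |R(t_i)|
  score_coefs <- function(time, event) {
    ord <- order(time)
    t_s <- time[ord]; e_s <- event[ord]
    # risk set at an event time counts all samples with time >= t, so tied
    # blocks share the risk-set size of their first sorted position and a
    # sample accumulates every event in its own tied block
    first_idx <- match(t_s, t_s)
    last_idx <- n - match(t_s, rev(t_s)) + 1L
    risk <- n - first_idx + 1L
    inc <- ifelse(e_s == 1, 1 / risk, 0)
    cum <- cumsum(inc)
    a <- numeric(n)
    a[ord] <- e_s - cum[last_idx]
    a
  }
  # observed exact score statistic U^2/V
  ord <- order(records$time)
  t_s <- records$time[ord]; e_s <- records$event[ord]
  xs <- x[, ord, drop = FALSE]
  first_idx <- match(t_s, t_s)
  U <- drop(x %*% score_coefs(records$time, records$event))
  m <- nrow(x)
  V <- numeric(m)
  # per event time: V += S2/S0 - (S1/S0)^2 over the risk set (suffix sums)
  cs1 <- t(apply(xs[, n:1, drop = FALSE], 1, cumsum))[, n:1, drop = FALSE]
  cs2 <- t(apply(xs[, n:1, drop = FALSE]^2, 1, cumsum))[, n:1, drop = FALSE]
  for (j in which(e_s == 1)) {
    r0 <- n - first_idx[j] + 1L
    s1 <- cs1[, first_idx[j]]
    s2 <- cs2[, first_idx[j]]
    V <- V + s2 / r0 - (s1 / r0)^2
  }
  stat <- ifelse(V > 0, U^2 / V, 0)

  # permutation reference for |U|: one coefficient vector per permutation
  a0 <- score_coefs(records$time, records$event)
  A <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      out <- numeric(n)
      out[sample.int(n)] <- a0
      out
    }, numeric(n))
  })
  U_perm <- abs(x %*% A)
  p_perm <- (1 + rowSums(U_perm >= abs(U) - 1e-12)) / (1 + n_perm)

  out <- tibble::tibble(
    feature_id = rownames(x),
    score_stat = unname(stat),
    p_asymptotic = pchisq(unname(stat), df = 1, lower.tail = FALSE),
    p = unname(p_perm)
  )
  dplyr::arrange(out, .data$p, dplyr::desc(.data$score_stat))
}

#' Exact one-dimensional two-means dichotomization
#'
#' Splits one feature's expression values into "high" and "low" expressors
#' by the globally optimal two-cluster solution in one dimension: all `n-1`
#' sorted split points are scanned and the within-cluster sum of squares is
#' minimized exactly (no Lloyd iterations, no initialization dependence).
#' "high" is the cluster with the larger mean.
#'
#' @param values Named numeric vector (names = sample ids) with at least two
#'   distinct values.
#' @param feature_id Optional feature identifier carried into the result.
#' @return A `dichotomy` list: `feature_id`, `boundary` (the maximum of the
#'   low cluster: every high value is `> boundary`, every low value is
#'   `<= boundary`), `labels` tibble (`sample_id`, `label`), cluster means,
#'   and the achieved within-cluster sum of squares.
#' @export
kmeans2_split <- function(values, feature_id = NA_character_) {
  if (!is.numeric(values) || length(values) < 2L) {
    rlang::abort("`values` must be a numeric vector of length >= 2.")
  }
  if (length(unique(values)) < 2L) {
    rlang::abort("Degenerate split: all values are equal.")
  }
  ids <- names(values) %||% as.character(seq_along(values))
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  csum <- cumsum(v)
  csq <- cumsum(v^2)
  tot_sum <- csum[n]
  tot_sq <- csq[n]
  ks <- seq_len(n - 1L)
  wss <- (csq[ks] - csum[ks]^2 / ks) +
    ((tot_sq - csq[ks]) - (tot_sum - csum[ks])^2 / (n - ks))
  # only splits between distinct values are admissible cluster boundaries
  admissible <- v[ks] < v[ks + 1L]
  wss[!admissible] <- Inf
  k_best <- which.min(wss)
  low_idx <- ord[seq_len(k_best)]
  lab <- rep("high", n)
  lab[seq_len(k_best)] <- "low"
  labels <- character(n)
  labels[ord] <- lab
  structure(list(
    feature_id = feature_id,
    boundary = unname(v[k_best]),
    labels = tibble::tibble(sample_id = ids, label = labels),
    mean_low = mean(v[seq_len(k_best)]),
    mean_high = mean(v[(k_best + 1L):n]),
    wss = unname(wss[k_best])
  ), class = "dichotomy")
}

#' @export
print.dichotomy <- function(x, ...) {
  cat(sprintf("<dichotomy> %s: boundary %.4g, low mean %.4g (n=%d), high mean %.4g (n=%d)\n",
              x$feature_id %||% "?", x$boundary,
              x$mean_low, sum(x$labels$label == "low"),
              x$mean_high, sum(x$labels$label == "high")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' invariant to input order. Wraps [stats::p.adjust()] after validating the
#' inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("`p` must be numeric in [0, 1] with no NA.")
  }
  p.adjust(p, method = "BH")
}
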