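#' Assign three-group risk labels from two dichotomized lncRNAs
#'
#' Combines the high/low dichotomies of an anchor and a partner lncRNA:
#' low/low is low risk, high/high is high risk, discordant expression is
#' intermediate.
#'
#' @param dich_a,dich_b [kmeans2_split()] results for the anchor and partner
#'   feature over the same sample set.
#' @return A `risk_assignment`: tibble `$groups` (`sample_id`, `group` in
#'   low/intermediate/high), the anchor/partner feature ids and group
#'   counts.
#' @export
assign_risk_groups <- function(dich_a, dich_b) {
  stopifnot(inherits(dich_a, "dichotomy"), inherits(dich_b, "dichotomy"))
  ids_a <- dich_a$labels$sample_id
  ids_b <- dich_b$labels$sample_id
  if (!setequal(ids_a, ids_b) || length(ids_a) != length(ids_b)) {
    rlang::abort("Dichotomies cover different sample sets.")
  }
  b <- dich_b$labels$label[match(ids_a, ids_b)]
  a <- dich_a$labels$label
  group <- dplyr::case_when(
    a == "low" & b == "low" ~ "low",
    a == "high" & b == "high" ~ "high",
    TRUE ~ "intermediate"
  )
  groups <- tibble::tibble(sample_id = ids_a, group = group)
  structure(list(
    groups = groups,
    anchor = dich_a$feature_id,
    partner = dich_b$feature_id,
    counts = table(factor(group, levels = c("low", "intermediate", "high")))
  ), class = "risk_assignment")
}

#' @export
print.risk_assignment <- function(x, ...) {
  cat(sprintf("<risk_assignment> anchor %s + partner %s: low %d / intermediate %d / high %d\n",
              x$anchor, x$partner, x$counts[["low"]],
              x$counts[["intermediate"]], x$counts[["high"]]))
  invisible(x)
}

#' Estimate hazards of the three risk groups
#'
#' Cox model with indicator covariates for the intermediate and high groups
#' against the low-risk reference (HR of the reference is 1 by definition),
#' Kaplan-Meier median progression-free survival per group ("not reached"
#' encoded as `NA` + flag), and the log-rank test across the groups. Empty
#' groups are dropped from the fit and flagged.
#'
#' @param assignment A `risk_assignment`.
#' @param records Survival data frame covering the assigned samples.
#' @param ties Tie handling passed to [cox_fit()].
#' @return A `risk_model_fit`: `$hazards` tibble (`group`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `median_pfs`, `median_reached`, `n`, `n_events`),
#'   `$logrank` tibble, `$cox` the underlying [cox_fit()], `$dropped_groups`.
#' @export
fit_group_hazards <- function(assignment, records, ties = "efron") {
  stopifnot(inherits(assignment, "risk_assignment"))
  check_survival(records)
  dat <- dplyr::inner_join(assignment$groups, records, by = "sample_id")
  if (!nrow(dat)) rlang::abort("No overlap between assignment and records.")
  if (sum(dat$event) < 1) rlang::abort("Need >= 1 event in the pooled data.")
  present <- c("low", "intermediate", "high")[
    c("low", "intermediate", "high") %in% dat$group
  ]
  dropped <- setdiff(c("low", "intermediate", "high"), present)
  if (length(dropped)) {
    rlang::warn(sprintf("Empty risk group(s) omitted from fit: %s",
                        paste(dropped, collapse = ", ")))
  }
  if (length(present) < 2L) {
    rlang::abort("Only one risk group present; nothing to compare.")
  }
  # reference = first present group (low when it exists); one indicator per
  # remaining group
  ref <- present[1]
  non_ref <- present[-1]
  for (g in non_ref) dat[[paste0("ind_", g)]] <- as.numeric(dat$group == g)
  cox <- cox_fit(dat, paste0("ind_", non_ref), ties = ties)

  med_tbl <- dplyr::bind_rows(lapply(present, function(g) {
    km <- km_estimate(dat[dat$group == g, , drop = FALSE])
    tibble::tibble(group = g, median_pfs = km$median,
                   median_reached = km$median_reached,
                   n = km$n, n_events = km$n_events)
  }))
  hr_tbl <- tibble::tibble(
    group = c(ref, non_ref),
    hr = c(1, cox$terms$hr),
    ci_lo = c(NA_real_, cox$terms$ci_lo),
    ci_hi = c(NA_real_, cox$terms$ci_hi),
    p = c(NA_real_, cox$terms$p)
  )
  hazards <- dplyr::left_join(med_tbl, hr_tbl, by = "group")
  hazards <- hazards[, c("group", "hr", "ci_lo", "ci_hi", "p",
                         "median_pfs", "median_reached", "n", "n_events")]

  lr <- logrank_test(dat, dat$group)
  structure(list(
    hazards = hazards, logrank = lr, cox = cox,
    anchor = assignment$anchor, partner = assignment$partner,
    dropped_groups = dropped
  ), class = "risk_model_fit")
}

#' @export
print.risk_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<risk_model_fit> anchor %s + partner %s\n", x$anchor, x$partner))
  df <- as.data.frame(x$hazards)
  df$median_pfs <- ifelse(df$median_reached, format(df$median_pfs),
                          "not reached")
  print(df[, c("group", "hr", "ci_lo", "ci_hi", "median_pfs", "n", "n_events")],
        digits = digits, row.names = FALSE)
  cat(sprintf("3-group log-rank p = %.3g%s\n", x$logrank$p,
              if (!x$cox$converged) " [Cox NOT CONVERGED]" else ""))
  invisible(x)
}

#' @method tidy risk_model_fit
#' @export
tidy.risk_model_fit <- function(x, ...) x$hazards

#' @method glance risk_model_fit
#' @export
glance.risk_model_fit <- function(x, ...) {
  tibble::tibble(
    anchor = x$anchor, partner = x$partner,
    logrank_chisq = x$logrank$chisq, logrank_p = x$logrank$p,
    converged = x$cox$converged,
    n = x$cox$n, n_events = x$cox$n_events
  )
}

#' Search candidate partners for the anchor lncRNA
#'
#' Builds the three-group model of the anchor with each candidate partner
#' and selects the partner minimizing the three-group log-rank p-value; ties
#' are broken toward fewest high-risk samples, then lexicographic feature
#' id. Candidates whose expression cannot be dichotomized (all values
#' equal) are skipped with a message.
#'
#' @param expr log2 feature x sample matrix.
#' @param records Survival data frame; samples are matched against `expr`
#'   columns.
#' @param anchor Anchor feature id (e.g. the smallest univariate
#'   screening p).
#' @param candidates Candidate partner feature ids.
#' @return A `partner_search`: `$best` (the selected partner id),
#'   `$fits` tibble (one row per scored candidate: `partner`, `logrank_p`,
#'   `n_high`, `hr_high`, `hr_intermediate`), `$best_fit` the winning
#'   `risk_model_fit`, `$skipped`.
#' @export
search_best_partner <- function(expr, records, anchor, candidates) {
  check_expr(expr)
  check_survival(records)
  feats <- c(anchor, candidates)
  miss <- setdiff(feats, rownames(expr))
  if (length(miss)) {
    rlang::abort(sprintf("Feature(s) not in expression matrix: %s",
                         paste(miss, collapse = ", ")))
  }
  x <- expr[, records$sample_id, drop = FALSE]
  dich_a <- kmeans2_split(x[anchor, ], feature_id = anchor)
  rows <- list()
  fits <- list()
  skipped <- character(0)
  for (cand in candidates) {
    dich_b <- tryCatch(kmeans2_split(x[cand, ], feature_id = cand),
                       error = function(e) NULL)
    if (is.null(dich_b)) {
      skipped <- c(skipped, cand)
      next
    }
    asn <- assign_risk_groups(dich_a, dich_b)
    fit <- suppressWarnings(fit_group_hazards(asn, records))
    hr_h <- fit$hazards$hr[fit$hazards$group == "high"]
    hr_i <- fit$hazards$hr[fit$hazards$group == "intermediate"]
    rows[[cand]] <- tibble::tibble(
      partner = cand,
      logrank_p = fit$logrank$p,
      n_high = sum(asn$groups$group == "high"),
      hr_high = if (length(hr_h)) hr_h else NA_real_,
      hr_intermediate = if (length(hr_i)) hr_i else NA_real_
    )
    fits[[cand]] <- fit
  }
  if (length(skipped)) {
    rlang::inform(sprintf("Skipped degenerate candidate(s): %s",
                          paste(skipped, collapse = ", ")))
  }
  if (!length(rows)) rlang::abort("No candidate could be dichotomized.")
  tbl <- dplyr::bind_rows(rows)
  tbl <- dplyr::arrange(tbl, .data$logrank_p, .data$n_high, .data$partner)
  best <- tbl$partner[1]
  structure(list(best = best, fits = tbl, best_fit = fits[[best]],
                 anchor = anchor, skipped = skipped),
            class = "partner_search")
}

#' @export
print.partner_search <- function(x, ...) {
  cat(sprintf("<partner_search> anchor %s: best partner %s (log-rank p %.3g)\n",
              x$anchor, x$best, x$fits$logrank_p[1]))
  invisible(x)
}

#' Test independence of the risk model from clinical covariates
#'
#' Multivariate Cox model with the risk-group indicators plus the supplied
#' covariates; each term's hazard ratio, confidence interval and p-value is
#' reported. Collinear covariates raise an error naming an offending pair.
#'
#' @param assignment A `risk_assignment`.
#' @param records Survival data frame carrying the covariate columns.
#' @param covariates Covariate column names (e.g. IGHV status, CD38,
#'   ZAP70, NOTCH1 mutation, cytogenetics).
#' @param ties Passed to [cox_fit()].
#' @return A [cox_fit()] with terms `ind_intermediate`, `ind_high` and the
#'   covariates.
#' @export
covariate_independence <- function(assignment, records, covariates,
                                   ties = "efron") {
  stopifnot(inherits(assignment, "risk_assignment"))
  check_survival(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) {
    rlang::abort(sprintf("Covariate(s) missing from records: %s",
                         paste(miss, collapse = ", ")))
  }
  if (any(!complete.cases(records[, covariates]))) {
    rlang::abort("Covariates must be present for all samples.")
  }
  dat <- dplyr::inner_join(assignment$groups, records, by = "sample_id")
  dat$ind_intermediate <- as.numeric(dat$group == "intermediate")
  dat$ind_high <- as.numeric(dat$group == "high")
  covs <- c(
    if (any(dat$ind_intermediate > 0)) "ind_intermediate",
    if (any(dat$ind_high > 0)) "ind_high",
    covariates
  )
  cox_fit(dat, covs, ties = ties)
}

#' Write a risk model to JSON
#'
#' Serializes group assignment counts, hazard ratios with confidence
#' intervals, per-group medians (with an explicit `"not reached"` sentinel)
#' and the log-rank p-value.
#'
#' @param fit A `risk_model_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(fit, path) {
  stopifnot(inherits(fit, "risk_model_fit"))
  hz <- fit$hazards
  payload <- list(
    anchor = fit$anchor, partner = fit$partner,
    groups = lapply(seq_len(nrow(hz)), function(i) list(
      group = hz$group[i], hr = hz$hr[i],
      ci_lo = hz$ci_lo[i], ci_hi = hz$ci_hi[i],
      median_pfs = if (hz$median_reached[i]) hz$median_pfs[i] else "not reached",
      n = hz$n[i], n_events = hz$n_events[i]
    )),
    logrank_p = fit$logrank$p
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
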