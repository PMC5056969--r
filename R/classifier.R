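# Nearest-shrunken-centroid (NSC / "PAM") classification.
#
# Per-feature class deviation d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))
# with m_k = sqrt(1/n_k - 1/n), soft-thresholded by Delta; shrunken
# centroids xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik; discriminant
# delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k.

nsc_fit_raw <- function(expr, labels, s0 = NULL, priors = NULL) {
  lev <- sort(unique(labels))
  n <- ncol(expr)
  nk <- vapply(lev, function(l) sum(labels == l), numeric(1))
  overall <- rowMeans(expr)
  cent <- matrix(
    vapply(lev, function(l) rowMeans(expr[, labels == l, drop = FALSE]),
           numeric(nrow(expr))),
    nrow = nrow(expr), ncol = length(lev),
    dimnames = list(rownames(expr), lev)
  )
  # pooled within-class SD
  ssw <- 0
  for (l in lev) {
    j <- labels == l
    ssw <- ssw + rowSums((expr[, j, drop = FALSE] - cent[, l])^2)
  }
  s_i <- sqrt(ssw / (n - length(lev)))
  if (is.null(s0)) s0 <- median(s_i)
  mk <- sqrt(pmax(1 / nk - 1 / n, .Machine$double.eps))
  dik <- sweep(cent - overall, 1, s_i + s0, "/")
  dik <- sweep(dik, 2, mk, "/")
  if (is.null(priors)) priors <- nk / n
  list(classes = lev, overall = overall, centroids = cent, s = s_i, s0 = s0,
       mk = mk, dik = dik, priors = priors, n = n, nk = nk)
}

nsc_shrink <- function(raw, delta) {
  dshr <- sign(raw$dik) * pmax(abs(raw$dik) - delta, 0)
  shrunk <- raw$overall +
    sweep(sweep(dshr, 2, raw$mk, "*"), 1, raw$s + raw$s0, "*")
  surviving <- rownames(shrunk)[rowSums(abs(dshr) > 0) > 0]
  list(dshr = dshr, centroids = shrunk, surviving = surviving)
}

nsc_predict_scores <- function(model, expr) {
  feats <- rownames(model$centroids)
  miss <- setdiff(feats, rownames(expr))
  if (length(miss)) {
    rlang::abort(sprintf("Expression matrix is missing model features: %s",
                         paste(head(miss, 10), collapse = ", ")))
  }
  x <- expr[feats, , drop = FALSE]
  w <- (model$s[feats] + model$s0)^2
  scores <- vapply(seq_along(model$classes), function(k) {
    colSums((x - model$centroids[, k])^2 / w) - 2 * log(model$priors[k])
  }, numeric(ncol(x)))
  scores <- matrix(scores, ncol = length(model$classes),
                   dimnames = list(colnames(x), model$classes))
  scores
}

#' Train a nearest-shrunken-centroid classifier
#'
#' Fits class centroids, soft-thresholds the standardized class deviations
#' at each candidate shrinkage `delta`, and selects the `delta` minimizing
#' stratified cross-validated misclassification error; ties are broken
#' toward the largest `delta` (fewest surviving features).
#'
#' @param expr log2 feature x sample matrix.
#' @param labels Class label per sample (>= 2 classes, each >= 2 samples).
#' @param delta_grid Candidate shrinkage thresholds; `NULL` builds an
#'   evenly spaced grid of `n_delta` values from 0 to `max |d_ik|`.
#' @param n_delta Grid size when `delta_grid` is `NULL`.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param s0 Fudge factor added to the per-feature pooled SD; default is
#'   the median of the pooled SDs.
#' @param priors Class prior probabilities; default = class proportions.
#' @return An `nsc_model` with the selected `delta`, shrunken centroids,
#'   surviving features, and the per-delta CV error curve in `$cv`.
#' @export
pam_train <- function(expr, labels, delta_grid = NULL, n_delta = 30L,
                      cv_folds = 10L, seed = 1L, s0 = NULL, priors = NULL) {
  check_expr(expr, min_samples = 4L)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    rlang::abort("`labels` must have one entry per sample.")
  }
  tab <- table(labels)
  if (length(tab) < 2L) rlang::abort("Need >= 2 classes.")
  if (any(tab < 2L)) rlang::abort("Each class needs >= 2 samples.")
  cv_folds <- check_count(cv_folds, "cv_folds", min = 2L)
  cv_folds <- min(cv_folds, min(tab))

  raw <- nsc_fit_raw(expr, labels, s0 = s0, priors = priors)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(raw$dik)), length.out = n_delta)
  }
  delta_grid <- sort(unique(as.numeric(delta_grid)))

  # stratified folds
  folds <- integer(length(labels))
  with_seed(seed, {
    for (l in names(tab)) {
      j <- which(labels == l)
      folds[j] <- sample(rep_len(seq_len(cv_folds), length(j)))
    }
  })
  cv_err <- matrix(NA_real_, cv_folds, length(delta_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    te <- !tr
    raw_f <- nsc_fit_raw(expr[, tr, drop = FALSE], labels[tr],
                         s0 = s0, priors = priors)
    for (g in seq_along(delta_grid)) {
      sh <- nsc_shrink(raw_f, delta_grid[g])
      mod_f <- list(classes = raw_f$classes, centroids = sh$centroids,
                    s = raw_f$s, s0 = raw_f$s0, priors = raw_f$priors)
      sc <- nsc_predict_scores(mod_f, expr[, te, drop = FALSE])
      pred <- raw_f$classes[max.col(-sc, ties.method = "first")]
      cv_err[f, g] <- mean(pred != labels[te])
    }
  }
  err <- colMeans(cv_err)
  best <- max(which(err == min(err)))  # ties -> largest delta, sparsest model
  delta <- delta_grid[best]
  sh <- nsc_shrink(raw, delta)

  structure(list(
    classes = raw$classes,
    overall_centroid = raw$overall,
    centroids = sh$centroids,
    dik_shrunk = sh$dshr,
    s = raw$s, s0 = raw$s0, mk = raw$mk,
    priors = raw$priors,
    delta = delta,
    surviving_features = sh$surviving,
    cv = tibble::tibble(delta = delta_grid, cv_error = err,
                        n_features = vapply(delta_grid, function(d)
                          length(nsc_shrink(raw, d)$surviving), numeric(1))),
    labels = labels
  ), class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("<nsc_model>\n")
  cat(sprintf("  classes : %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  delta   : %.4g (CV error %.4f)\n", x$delta,
              x$cv$cv_error[x$cv$delta == x$delta][1]))
  cat(sprintf("  features: %d surviving of %d\n",
              length(x$surviving_features), length(x$overall_centroid)))
  invisible(x)
}

#' Predict classes from a nearest-shrunken-centroid model
#'
#' Assigns each sample the class minimizing the shrunken-centroid
#' discriminant (standardized squared distance minus `2 log` prior). Ties
#' go to the higher-prior class.
#'
#' @param model An `nsc_model` from [pam_train()].
#' @param expr log2 feature x sample matrix containing the model features.
#' @return Tibble with `sample_id`, `predicted`, and one discriminant-score
#'   column per class.
#' @export
pam_predict <- function(model, expr) {
  stopifnot(inherits(model, "nsc_model"))
  check_expr(expr)
  sc <- nsc_predict_scores(model, expr)
  # tie-break toward the larger prior
  ord <- order(model$priors, decreasing = TRUE)
  sc_t <- sc[, ord, drop = FALSE]
  pred <- model$classes[ord][max.col(-sc_t, ties.method = "first")]
  out <- tibble::tibble(sample_id = colnames(expr), predicted = pred)
  dplyr::bind_cols(out, tibble::as_tibble(sc))
}

#' Evaluate predicted against true class labels
#'
#' Accuracy, sensitivity and specificity (as percentages) from the confusion
#' matrix, with `positive_class` defining sensitivity. When a rate's
#' denominator is empty (e.g. no positive-class truth samples) it is
#' reported as `NA` with a warning rather than propagating `NaN`.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_class The class counted as "positive".
#' @return A `classifier_evaluation` tibble with `accuracy`, `sensitivity`,
#'   `specificity` (percent) and confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_classifier <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth)) {
    rlang::abort("`predicted` and `truth` must have equal length.")
  }
  known <- unique(c(predicted, truth))
  if (!positive_class %in% known) {
    rlang::abort(sprintf("Unknown positive class '%s'.", positive_class))
  }
  tp <- sum(predicted == positive_class & truth == positive_class)
  fp <- sum(predicted == positive_class & truth != positive_class)
  tn <- sum(predicted != positive_class & truth != positive_class)
  fn <- sum(predicted != positive_class & truth == positive_class)
  sens <- if (tp + fn == 0) {
    rlang::warn("No positive-class truth samples; sensitivity undefined.")
    NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    rlang::warn("No negative-class truth samples; specificity undefined.")
    NA_real_
  } else 100 * tn / (tn + fp)
  out <- tibble::tibble(
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
  class(out) <- c("classifier_evaluation", class(out))
  out
}

# ridge-regularized pooled-covariance linear discriminant; the ridge is
# scaled to the average feature variance (trace(S)/p), so ridge_scale = 2
# shrinks strongly toward the spherical covariance (RDA-style), which is
# required for stability when features outnumber training samples
lda_train_predict <- function(x_train, y_train, x_test, ridge_scale = 2) {
  lev <- sort(unique(y_train))
  p <- ncol(x_train)
  means <- matrix(vapply(lev, function(l)
    colMeans(x_train[y_train == l, , drop = FALSE]), numeric(p)),
    nrow = length(lev), ncol = p, byrow = TRUE)
  S <- matrix(0, p, p)
  for (l in lev) {
    xc <- sweep(x_train[y_train == l, , drop = FALSE], 2,
                means[match(l, lev), ])
    S <- S + crossprod(xc)
  }
  S <- S / max(nrow(x_train) - length(lev), 1)
  lambda <- ridge_scale * sum(diag(S)) / p
  regularized <- FALSE
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond_ok(S) < 1e-12) {
    S <- S + diag(max(lambda, .Machine$double.eps), p)
    Sinv <- solve(S)
    regularized <- TRUE
  }
  priors <- as.numeric(table(factor(y_train, levels = lev))) / length(y_train)
  disc <- vapply(seq_along(lev), function(k) {
    mu <- means[k, ]
    drop(x_test %*% Sinv %*% mu) - 0.5 * drop(mu %*% Sinv %*% mu) +
      log(priors[k])
  }, numeric(nrow(x_test)))
  disc <- matrix(disc, ncol = length(lev))
  list(pred = lev[max.col(disc, ties.method = "first")],
       regularized = regularized)
}

rcond_ok <- function(S) {
  tryCatch(rcond(S), error = function(e) 0)
}

#' Leave-one-out linear discriminant validation
#'
#' For every sample, a linear discriminant classifier (pooled covariance)
#' is trained on all other samples and used to predict it. Whenever the
#' pooled covariance is singular — the rule when features outnumber
#' training samples — it is ridge-regularized with
#' `lambda = ridge_scale * trace(S)/p` (shrinkage toward the spherical
#' average-variance covariance, in the spirit of regularized discriminant
#' analysis), and the regularization is reported. The aggregated
#' predictions are scored with [evaluate_classifier()].
#'
#' @param expr log2 feature x sample matrix.
#' @param labels Class label per sample.
#' @param positive_class Class treated as positive; defaults to the first
#'   sorted label.
#' @param ridge_scale Ridge magnitude relative to the average feature
#'   variance `trace(S)/p`.
#' @return A `classifier_evaluation` tibble (see [evaluate_classifier()]),
#'   with the per-sample predictions in attribute `predictions` and a
#'   `regularized` attribute recording whether the ridge was engaged.
#' @export
loo_lda <- function(expr, labels, positive_class = NULL, ridge_scale = 2) {
  check_expr(expr, min_samples = 4L)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  n <- ncol(expr)
  if (n < length(lev) + 2L) rlang::abort("Need at least n >= classes + 2 samples.")
  if (is.null(positive_class)) positive_class <- lev[1]
  x <- t(expr)
  pred <- character(n)
  reg_any <- FALSE
  for (i in seq_len(n)) {
    if (length(unique(labels[-i])) < 2L) {
      rlang::abort("A class vanishes when holding out a sample; need >= 2 per class.")
    }
    fit <- lda_train_predict(x[-i, , drop = FALSE], labels[-i],
                             x[i, , drop = FALSE], ridge_scale = ridge_scale)
    pred[i] <- fit$pred
    reg_any <- reg_any || fit$regularized
  }
  if (reg_any) {
    rlang::inform("LOO-LDA: singular pooled covariance; ridge regularization applied.")
  }
  out <- evaluate_classifier(pred, labels, positive_class)
  attr(out, "predictions") <- tibble::tibble(
    sample_id = colnames(expr), truth = labels, predicted = pred
  )
  attr(out, "regularized") <- reg_any
  out
}

#' Serialize / restore a nearest-shrunken-centroid model as JSON
#'
#' @param model An `nsc_model`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_nsc_model()` returns the `nsc_model`.
#' @export
write_nsc_model <- function(model, path) {
  stopifnot(inherits(model, "nsc_model"))
  payload <- list(
    classes = model$classes,
    features = rownames(model$centroids),
    overall_centroid = unname(model$overall_centroid),
    centroids = unname(model$centroids),
    s = unname(model$s), s0 = model$s0, mk = unname(model$mk),
    priors = unname(model$priors), delta = model$delta,
    surviving_features = model$surviving_features
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nsc_model
#' @export
read_nsc_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(unlist(p$centroids), ncol = length(p$classes),
                 dimnames = list(p$features, p$classes))
  structure(list(
    classes = p$classes,
    overall_centroid = setNames(p$overall_centroid, p$features),
    centroids = cent,
    s = setNames(p$s, p$features), s0 = p$s0,
    mk = setNames(p$mk, p$classes),
    priors = setNames(p$priors, p$classes),
    delta = p$delta,
    surviving_features = p$surviving_features,
    cv = NULL, labels = NULL
  ), class = "nsc_model")
}
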