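#' Fold-from-mean variance filter
#'
#' Retains features whose log2 expression deviates from their own mean by at
#' least `log2(fold)` in at least one sample, i.e. features varying at least
#' `fold`-fold from the mean across the data set.
#'
#' @param expr log2 feature x sample matrix.
#' @param fold Minimum fold change (> 1); the default 1.5 reproduces the
#'   usual "1.5-fold from the mean" screen.
#' @return A `filter_result` tibble with columns `feature_id` and
#'   `max_abs_dev`; the threshold used is stored in the `threshold`
#'   attribute.
#' @export
fold_from_mean_filter <- function(expr, fold = 1.5) {
  check_expr(expr)
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1) {
    rlang::abort("`fold` must be a single number > 1.")
  }
  thr <- log2(fold)
  dev <- abs(expr - rowMeans(expr))
  mx <- apply(dev, 1, max)
  out <- tibble::tibble(
    feature_id = rownames(expr)[mx >= thr],
    max_abs_dev = unname(mx[mx >= thr])
  )
  attr(out, "threshold") <- thr
  class(out) <- c("filter_result", class(out))
  out
}

#' SD-above-median-plus-MAD variance filter
#'
#' Computes each feature's expression standard deviation and retains the
#' features whose SD strictly exceeds the median plus one (unscaled) median
#' absolute deviation of all the SDs. This is the pre-filter applied before
#' survival screening.
#'
#' @param expr log2 feature x sample matrix with >= 2 samples.
#' @return A `filter_result` tibble with `feature_id` and `sd`; threshold in
#'   the `threshold` attribute.
#' @export
sd_mad_filter <- function(expr) {
  check_expr(expr, min_samples = 2L)
  sds <- row_sds(expr)
  thr <- median(sds) + mad(sds, constant = 1)
  keep <- sds > thr
  out <- tibble::tibble(feature_id = rownames(expr)[keep],
                        sd = unname(sds[keep]))
  attr(out, "threshold") <- thr
  class(out) <- c("filter_result", class(out))
  out
}

# pooled-SD denominator of the two-class SAM d statistic
sam_pooled_s <- function(expr, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  m1 <- rowMeans(expr[, idx1, drop = FALSE])
  m2 <- rowMeans(expr[, idx2, drop = FALSE])
  ss <- rowSums((expr[, idx1, drop = FALSE] - m1)^2) +
    rowSums((expr[, idx2, drop = FALSE] - m2)^2)
  list(diff = m2 - m1,
       s = sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2)))
}

# SAM's fudge-factor recipe: pick s0 among the percentiles of s that
# minimizes the coefficient of variation of mad(d) across bins of s.
sam_choose_s0 <- function(diff, s, n_bins = 100L) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  n_bins <- min(n_bins, max(2L, floor(length(s) / 5)))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- diff / (s + s0)
    v <- vapply(split(d, bins), mad, numeric(1))
    v <- v[is.finite(v)]
    if (!length(v) || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

# SAM q-values by the delta-threshold recipe: genes are ranked, the expected
# order statistics dbar_(i) are the permutation means of the sorted scores,
# and a gene is called at threshold delta when its observed order statistic
# departs from the expected one by at least delta (upward, or downward for
# two-sided scores). The false-positive count at the implied score cutoffs
# is averaged across permutations (the plug-in E[V]/R estimate; the mean is
# used rather than SAM's median because the median collapses to zero for
# the top-ranked gene whenever it beats half the permutation maxima, which
# under a complete null mislabels one gene per data set); a gene's q is the
# smallest estimated FDR among the thresholds that call it. pi0 is fixed at
# 1 (conservative).
sam_qvalues <- function(d_obs, d_perm, two_sided = TRUE, pi0 = 1,
                        max_grid = 128L) {
  m <- length(d_obs)
  n_perm <- ncol(d_perm)
  ord <- order(d_obs)
  ds <- d_obs[ord]
  perm_sort <- apply(matrix(d_perm, nrow = m), 2, sort)
  dbar <- rowMeans(perm_sort)
  dif <- ds - dbar
  grid <- sort(unique(abs(dif)))
  if (length(grid) > max_grid) {
    grid <- unique(quantile(grid, seq(0, 1, length.out = max_grid),
                            names = FALSE))
  }
  eps <- 1e-12
  q_sorted <- rep(1, m)
  for (delta in grid) {
    up <- which(dif >= delta - eps & dif > 0)
    cut_up <- if (length(up)) min(ds[up]) else Inf
    if (two_sided) {
      dn <- which(dif <= -delta + eps & dif < 0)
      cut_lo <- if (length(dn)) max(ds[dn]) else -Inf
    } else {
      cut_lo <- -Inf
    }
    called <- ds >= cut_up - eps | ds <= cut_lo + eps
    nc <- sum(called)
    if (nc == 0) next
    fp <- vapply(seq_len(n_perm), function(b) {
      col <- perm_sort[, b]
      (m - findInterval(cut_up - eps, col)) + findInterval(cut_lo + eps, col)
    }, numeric(1))
    fdr <- min(1, pi0 * mean(fp) / nc)
    q_sorted[called] <- pmin(q_sorted[called], fdr)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Two-class SAM differential expression
#'
#' The SAM d statistic \eqn{d_i = (\bar x_{i2} - \bar x_{i1}) / (s_i + s_0)}
#' with pooled per-feature standard deviation \eqn{s_i}, fudge factor
#' \eqn{s_0} chosen by the percentile / coefficient-of-variation recipe (or
#' forced, e.g. to 0 for hand-checkable tests), and false-discovery q-values
#' from label permutations. The default `"sam"` q estimator follows the
#' delta-threshold recipe with the mean false-positive count (a plug-in
#' `E[V]/R` estimate); `"bh"` applies Benjamini-Hochberg to +1-corrected
#' permutation p-values, which is strictly conservative under a complete
#' null.
#'
#' @param expr log2 feature x sample matrix.
#' @param labels Two-class factor/character vector, one entry per sample;
#'   `d > 0` means higher expression in the second class level.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations (mandatory).
#' @param s0 Optional forced fudge factor; `NULL` (default) uses the SAM
#'   recipe.
#' @param q_method `"sam"` (median false positives, default) or `"bh"`
#'   (Benjamini-Hochberg on permutation p-values).
#' @param exhaustive If `TRUE`, enumerate every distinct assignment of
#'   samples to the first class instead of sampling `n_perm` random
#'   permutations (only sensible for small cohorts).
#' @return A `sam_result` tibble: `feature_id`, `d`, `s0`, `q`, `direction`.
#' @export
sam_two_class <- function(expr, labels, n_perm = 200L, seed, s0 = NULL,
                          q_method = c("sam", "bh"), exhaustive = FALSE) {
  check_expr(expr, min_samples = 4L)
  q_method <- match.arg(q_method)
  n_perm <- check_count(n_perm, "n_perm")
  if (missing(seed)) rlang::abort("`seed` is required for permutations.")
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    rlang::abort("`labels` must have one entry per sample.")
  }
  lev <- sort(unique(labels))
  if (length(lev) != 2L) rlang::abort("`labels` must have exactly two classes.")
  idx1 <- which(labels == lev[1])
  idx2 <- which(labels == lev[2])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    rlang::abort("Each class needs >= 2 samples.")
  }
  ps <- sam_pooled_s(expr, idx1, idx2)
  s0_use <- if (is.null(s0)) sam_choose_s0(ps$diff, ps$s) else as.numeric(s0)
  d_obs <- ps$diff / (ps$s + s0_use)

  n1 <- length(idx1)
  if (isTRUE(exhaustive)) {
    combos <- utils::combn(ncol(expr), n1, simplify = FALSE)
    d_perm <- vapply(combos, function(pi1) {
      pb <- sam_pooled_s(expr, pi1, setdiff(seq_len(ncol(expr)), pi1))
      pb$diff / (pb$s + s0_use)
    }, numeric(nrow(expr)))
    n_perm <- length(combos)
  } else {
    d_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        pi1 <- sample(ncol(expr), n1)
        pb <- sam_pooled_s(expr, pi1, setdiff(seq_len(ncol(expr)), pi1))
        pb$diff / (pb$s + s0_use)
      }, numeric(nrow(expr)))
    })
  }
  d_perm <- matrix(d_perm, nrow = nrow(expr))

  q <- if (q_method == "sam") {
    sam_qvalues(d_obs, d_perm, two_sided = TRUE)
  } else if (isTRUE(exhaustive)) {
    # identity assignment is one of the enumerated permutations: the
    # uncorrected count / total is already an exact p-value
    p <- rowSums(abs(d_perm) >= abs(d_obs) - 1e-12) / n_perm
    p.adjust(p, method = "BH")
  } else {
    p <- (1 + rowSums(abs(d_perm) >= abs(d_obs) - 1e-12)) / (1 + n_perm)
    p.adjust(p, method = "BH")
  }
  out <- tibble::tibble(
    feature_id = rownames(expr),
    d = unname(d_obs),
    s0 = s0_use,
    q = unname(q),
    direction = ifelse(unname(d_obs) >= 0, "up", "down")
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$d)))
  attr(out, "classes") <- lev
  attr(out, "n_perm") <- n_perm
  class(out) <- c("sam_result", class(out))
  out
}

#' Multiclass SAM differential expression
#'
#' F-like SAM statistic for k >= 3 classes:
#' \eqn{d_i = r_i / (s_i + s_0)} with
#' \eqn{r_i = \sqrt{(\sum_k n_k / \prod_k n_k)\sum_k n_k(\bar x_{ik}-\bar x_i)^2}}
#' and \eqn{s_i} the pooled within-class standard deviation scaled by
#' \eqn{\sqrt{\sum_k 1/n_k}}. q-values by class-label permutation; no
#' direction is reported.
#'
#' @inheritParams sam_two_class
#' @return A `sam_result` tibble: `feature_id`, `d`, `s0`, `q` (direction is
#'   `NA` for the multiclass statistic).
#' @export
sam_multiclass <- function(expr, labels, n_perm = 200L, seed, s0 = NULL,
                           q_method = c("sam", "bh")) {
  check_expr(expr, min_samples = 6L)
  q_method <- match.arg(q_method)
  n_perm <- check_count(n_perm, "n_perm")
  if (missing(seed)) rlang::abort("`seed` is required for permutations.")
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    rlang::abort("`labels` must have one entry per sample.")
  }
  if (length(unique(labels)) < 3L) {
    rlang::abort("Multiclass SAM needs >= 3 classes (use sam_two_class).")
  }
  if (any(table(labels) < 2L)) rlang::abort("Each class needs >= 2 samples.")

  stat <- function(lab) {
    nn <- table(lab)
    k <- length(nn)
    mbar <- rowMeans(expr)
    num <- 0
    ssw <- 0
    for (cl in names(nn)) {
      j <- which(lab == cl)
      mk <- rowMeans(expr[, j, drop = FALSE])
      num <- num + nn[[cl]] * (mk - mbar)^2
      ssw <- ssw + rowSums((expr[, j, drop = FALSE] - mk)^2)
    }
    fac <- sum(nn) / prod(nn)
    scor <- sqrt(fac * num)
    s <- sqrt(ssw / sum(nn - 1) * sum(1 / nn))
    list(scor = scor, s = s)
  }
  ob <- stat(labels)
  s0_use <- if (is.null(s0)) sam_choose_s0(ob$scor, ob$s) else as.numeric(s0)
  d_obs <- ob$scor / (ob$s + s0_use)

  d_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pb <- stat(sample(labels))
      pb$scor / (pb$s + s0_use)
    }, numeric(nrow(expr)))
  })
  d_perm <- matrix(d_perm, nrow = nrow(expr))
  q <- if (q_method == "sam") {
    sam_qvalues(d_obs, d_perm, two_sided = FALSE)
  } else {
    p <- (1 + rowSums(d_perm >= d_obs - 1e-12)) / (1 + n_perm)
    p.adjust(p, method = "BH")
  }
  out <- tibble::tibble(
    feature_id = rownames(expr),
    d = unname(d_obs),
    s0 = s0_use,
    q = unname(q),
    direction = NA_character_
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$d))
  attr(out, "n_perm") <- n_perm
  class(out) <- c("sam_result", class(out))
  out
}

#' Wilcoxon rank-sum test
#'
#' Thin wrapper over [stats::wilcox.test()]: exact p-value when both groups
#' have at most 10 observations and no ties, normal approximation with tie
#' and continuity correction otherwise.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return Tibble with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) rlang::abort("Both inputs must be non-empty.")
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}
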