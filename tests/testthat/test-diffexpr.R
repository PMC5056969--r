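mk_expr <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("fold-from-mean filter applies the log2 threshold per feature", {
  m <- mk_expr(rbind(
    constant = rep(5, 4),
    strong = c(5, 5, 5, 7),          # max dev 1.5 >= log2(1.5)
    weak = c(5, 5.1, 4.9, 5.2)       # max dev 0.2 < log2(1.5)
  ))
  out <- fold_from_mean_filter(m, fold = 1.5)
  expect_setequal(out$feature_id, "strong")
  # random matrix equals the brute-force per-feature check
  set.seed(1)
  r <- mk_expr(matrix(rnorm(200), 20, 10))
  got <- fold_from_mean_filter(r, fold = 1.5)$feature_id
  brute <- rownames(r)[apply(abs(r - rowMeans(r)), 1, max) >= log2(1.5)]
  expect_setequal(got, brute)
  expect_error(fold_from_mean_filter(r, fold = 1), "> 1")
})

test_that("sd > median + MAD filter follows the stated rule strictly", {
  # identical SDs: MAD = 0 and strict inequality empties the result
  m <- mk_expr(rbind(a = c(0, 1), b = c(5, 6), c = c(2, 3)))
  expect_equal(nrow(sd_mad_filter(m)), 0)
  # SDs {1,1,1,10}: median 1, unscaled MAD 0, threshold 1 -> only the 10
  m2 <- mk_expr(rbind(
    a = c(0, 2) / sqrt(2), b = c(1, 3) / sqrt(2), c = c(5, 7) / sqrt(2),
    d = c(0, 20) / sqrt(2)
  ))
  out <- sd_mad_filter(m2)
  expect_equal(out$feature_id, "d")
  expect_equal(attr(out, "threshold"), 1)
  expect_error(sd_mad_filter(m2[, 1, drop = FALSE]), "sample")
})

test_that("sd/mad filter recovers planted high-variance features", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- mk_expr(rbind(
      matrix(rnorm(90 * 30, sd = 1), 90, 30),
      matrix(rnorm(10 * 30, sd = 4), 10, 30)
    ))
    planted <- rownames(m)[91:100]
    got <- sd_mad_filter(m)$feature_id
    hits <- hits + all(planted %in% got)
  }
  expect_gte(hits, 19)
})

test_that("two-class SAM d matches the pooled-SD hand computation", {
  m <- mk_expr(rbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = c(2, 1, 3, 2, 3, 1)))
  labs <- rep(c("A", "B"), each = 3)
  out <- sam_two_class(m, labs, n_perm = 20, seed = 1, s0 = 0)
  expect_equal(out$d[out$feature_id == "f1"], 3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(out$direction[out$feature_id == "f1"], "up")
  # identical groups give d = 0
  m0 <- mk_expr(matrix(rep(c(1, 2, 3, 1, 2, 3), 2), nrow = 2, byrow = TRUE))
  expect_equal(sam_two_class(m0, rep(c("A", "B"), each = 3),
                             n_perm = 10, seed = 1, s0 = 0)$d, c(0, 0))
  expect_error(sam_two_class(m, c("A", "A", "A", "A", "A", "B"),
                             n_perm = 5, seed = 1), ">= 2 samples")
})

test_that("SAM d is antisymmetric under label swap", {
  set.seed(3)
  m <- mk_expr(matrix(rnorm(80), 10, 8))
  labs <- rep(c("A", "B"), each = 4)
  d1 <- sam_two_class(m, labs, n_perm = 10, seed = 1, s0 = 0.2)
  labs2 <- rep(c("B", "A"), each = 4)  # levels sort the same; classes swap
  d2 <- sam_two_class(m, labs2, n_perm = 10, seed = 1, s0 = 0.2)
  expect_equal(
    d1$d[order(d1$feature_id)], -d2$d[order(d2$feature_id)], tolerance = 1e-12
  )
})

test_that("exhaustive permutations reproduce the q-value oracle exactly", {
  set.seed(7)
  m <- mk_expr(matrix(rnorm(5 * 4), 5, 4))
  labs <- c("A", "A", "B", "B")
  out <- sam_two_class(m, labs, seed = 1, s0 = 0.1, exhaustive = TRUE,
                       q_method = "bh")
  # independent oracle: exact p over all C(4,2)=6 assignments, then the
  # step-up adjustment computed from first principles
  combos <- utils::combn(4, 2, simplify = FALSE)
  dstat <- function(i1) {
    i2 <- setdiff(1:4, i1)
    s <- sqrt((1 / 2 + 1 / 2) *
                (rowSums((m[, i1, drop = FALSE] - rowMeans(m[, i1, drop = FALSE]))^2) +
                   rowSums((m[, i2, drop = FALSE] - rowMeans(m[, i2, drop = FALSE]))^2)) / 2)
    (rowMeans(m[, i2, drop = FALSE]) - rowMeans(m[, i1, drop = FALSE])) / (s + 0.1)
  }
  d_obs <- dstat(c(1, 2))
  d_perm <- sapply(combos, dstat)
  p_exact <- sapply(seq_len(5), function(f)
    mean(abs(d_perm[f, ]) >= abs(d_obs[f]) - 1e-12))
  o <- order(p_exact)
  q <- p_exact[o] * 5 / seq_len(5)
  q <- pmin(rev(cummin(rev(q))), 1)
  q_exp <- numeric(5); q_exp[o] <- q
  expect_equal(out$q[match(rownames(m), out$feature_id)], q_exp,
               tolerance = 1e-12)
  # observed d must equal the identity assignment's statistic
  expect_equal(out$d[match(rownames(m), out$feature_id)], unname(d_obs),
               tolerance = 1e-12)
})

test_that("q-values are invariant to feature order and monotone in |d| rank", {
  set.seed(11)
  m <- mk_expr(matrix(rnorm(30 * 10), 30, 10))
  labs <- rep(c("A", "B"), each = 5)
  out <- sam_two_class(m, labs, n_perm = 50, seed = 2)
  perm <- sample(nrow(m))
  out2 <- sam_two_class(m[perm, ], labs, n_perm = 50, seed = 2)
  j <- match(out$feature_id, out2$feature_id)
  expect_equal(out$q, out2$q[j], tolerance = 1e-12)
  expect_equal(out$d, out2$d[j], tolerance = 1e-12)
  # already sorted by |d| descending: q must be non-decreasing down the list
  expect_true(all(diff(out$q) >= -1e-12))
})

test_that("multiclass SAM matches the brute-force formula and ranks signal first", {
  set.seed(5)
  m <- mk_expr(matrix(rnorm(6 * 9), 6, 9))
  labs <- rep(c("A", "B", "C"), each = 3)
  out <- sam_multiclass(m, labs, n_perm = 20, seed = 1, s0 = 0.15)
  # brute-force evaluation of the statistic
  nn <- table(labs)
  for (f in rownames(m)) {
    x <- m[f, ]
    mbar <- mean(x)
    num <- sum(sapply(names(nn), function(k) nn[[k]] * (mean(x[labs == k]) - mbar)^2))
    ssw <- sum(sapply(names(nn), function(k) sum((x[labs == k] - mean(x[labs == k]))^2)))
    scor <- sqrt(sum(nn) / prod(nn) * num)
    sdv <- sqrt(ssw / sum(nn - 1) * sum(1 / nn))
    expect_equal(out$d[out$feature_id == f], unname(scor / (sdv + 0.15)),
                 tolerance = 1e-12)
  }
  # identical classes -> statistic 0; a separated class ranks first
  m2 <- mk_expr(rbind(
    null = rep(1, 9) + rnorm(9, 0, 1e-6),
    hit = c(rep(0, 3), rep(10, 3), rep(0, 3)) + rnorm(9, 0, 1e-3),
    null2 = rep(2, 9) + rnorm(9, 0, 1e-6)
  ))
  out2 <- sam_multiclass(m2, labs, n_perm = 10, seed = 1, s0 = 0.1)
  expect_equal(out2$feature_id[1], "hit")
  expect_error(sam_multiclass(m, rep(c("A", "B"), c(5, 4)), n_perm = 5, seed = 1),
               ">= 3 classes")
})

test_that("null SAM q-values are conservative", {
  frac_sam <- numeric(30)
  frac_bh <- numeric(30)
  for (s in 1:30) {
    set.seed(s)
    m <- mk_expr(matrix(rnorm(100 * 12), 100, 12))
    labs <- rep(c("A", "B"), each = 6)
    out <- sam_two_class(m, labs, n_perm = 60, seed = s)
    frac_sam[s] <- mean(out$q < 0.05)
    out_bh <- sam_two_class(m, labs, n_perm = 60, seed = s, q_method = "bh")
    frac_bh[s] <- mean(out_bh$q < 0.05)
  }
  # the BH-on-permutation-p mode is strictly conservative; the plug-in
  # E[V]/R estimate of the default mode stays near its nominal level
  expect_lte(mean(frac_bh), 0.001)
  expect_lte(mean(frac_sam), 0.005)
})

test_that("rank-sum test is exact for small samples and matches at n = 10", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")$p_value,
               1 / 6, tolerance = 1e-12)
  x <- c(5, 6, 7); y <- c(5, 6, 7) + 1e-9
  expect_gt(wilcoxon_rank_sum(x, c(5, 6, 7) + 0)$p_value, 0.99)
  # normal approximation close to exact at n = 10 per group
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
  p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_norm), 0.01)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, p_exact, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})
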