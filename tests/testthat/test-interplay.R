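mk_expr <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("cross-correlations match the direct formula to 1e-12", {
  set.seed(1)
  a <- mk_expr(matrix(rnorm(20 * 15), 20, 15))
  b <- mk_expr(matrix(rnorm(20 * 15), 20, 15))
  rownames(b) <- paste0("g", 1:20)
  pairs <- correlate_pairs(a, b)
  expect_equal(nrow(pairs), 400)
  for (i in sample(400, 25)) {
    orc <- oracle_pearson(a[pairs$feature_a[i], ], b[pairs$feature_b[i], ])
    expect_equal(pairs$r[i], orc$r, tolerance = 1e-12)
    expect_equal(pairs$p[i], orc$p, tolerance = 1e-12)
  }
  expect_equal(pairs$q, bh_adjust(pairs$p), tolerance = 1e-15)
  # self-correlation 1, exact negation -1
  self <- correlate_pairs(a[1, , drop = FALSE],
                          mk_expr(rbind(same = a[1, ], neg = -a[1, ])))
  expect_equal(self$r[self$feature_b == "same"], 1, tolerance = 1e-12)
  expect_equal(self$r[self$feature_b == "neg"], -1, tolerance = 1e-12)
})

test_that("Kendall correlations match cor() and flag zero-variance rows", {
  set.seed(2)
  a <- mk_expr(matrix(rnorm(3 * 12), 3, 12))
  b <- mk_expr(matrix(rnorm(2 * 12), 2, 12))
  rownames(b) <- c("g1", "g2")
  tau <- correlate_pairs(a, b, method = "kendall")
  for (i in seq_len(nrow(tau))) {
    expect_equal(tau$r[i],
                 cor(a[tau$feature_a[i], ], b[tau$feature_b[i], ],
                     method = "kendall"),
                 tolerance = 1e-12)
  }
  a2 <- rbind(a, flat = rep(1, 12))
  out <- correlate_pairs(mk_expr(a2), b)
  expect_false("flat" %in% out$feature_a)
  expect_true("flat" %in% attr(out, "excluded_features"))
})

test_that("Pearson r is invariant to positive affine rescaling per feature", {
  set.seed(3)
  a <- mk_expr(matrix(rnorm(4 * 10), 4, 10))
  b <- mk_expr(matrix(rnorm(4 * 10), 4, 10))
  rownames(b) <- paste0("g", 1:4)
  base <- correlate_pairs(a, b)
  a2 <- a * 3 + 7
  expect_equal(correlate_pairs(mk_expr(a2), b)$r, base$r, tolerance = 1e-12)
})

test_that("co-expression screen applies a strict threshold", {
  pairs <- tibble::tibble(feature_a = c("l1", "l2", "l3"),
                          feature_b = c("g1", "g2", "g3"),
                          r = c(0.9, 0.95, 0.2), p = 0, q = 0)
  out <- screen_coexpression(pairs, 0.9)
  expect_equal(out$feature_a, "l2")  # exactly 0.9 excluded
  expect_equal(nrow(screen_coexpression(pairs[0, ], 0.9)), 0)
})

test_that("anti-correlation screen requires negative r and small q", {
  pairs <- tibble::tibble(feature_a = "l", feature_b = "m",
                          r = 0.9, p = 1e-12, q = 1e-10)
  expect_equal(nrow(screen_anticorrelation(pairs, 0.01)), 0)
  pairs2 <- tibble::tibble(feature_a = c("l1", "l2"), feature_b = c("m1", "m2"),
                           r = c(-0.4, -0.4), q = c(0.005, 0.02), p = c(0, 0))
  expect_equal(screen_anticorrelation(pairs2, 0.01)$feature_a, "l1")
})

test_that("planted co-expressed and anti-correlated pairs are recovered", {
  coexpr_ok <- 0; anti_ok <- 0
  for (s in 1:10) {
    co <- generate_cohort(small_cohort_config(seed = s), sequences = FALSE)
    pc <- correlate_pairs(
      co$lnc_expr[startsWith(rownames(co$lnc_expr), "lnc_coexpr"), , drop = FALSE],
      co$mrna_expr
    )
    planted <- co$truth$corr_pairs[co$truth$corr_pairs$partner_type == "mrna", ]
    got <- screen_coexpression(pc, 0.9)
    coexpr_ok <- coexpr_ok +
      all(paste(planted$lnc, planted$partner) %in%
            paste(got$feature_a, got$feature_b))
    pm <- correlate_pairs(
      co$lnc_expr[startsWith(rownames(co$lnc_expr), "lnc_sponge"), , drop = FALSE],
      co$mirna_expr
    )
    sponges <- co$truth$corr_pairs[co$truth$corr_pairs$partner_type == "mirna", ]
    gotm <- screen_anticorrelation(pm, 0.01)
    anti_ok <- anti_ok +
      all(paste(sponges$lnc, sponges$partner) %in%
            paste(gotm$feature_a, gotm$feature_b))
  }
  expect_gte(coexpr_ok, 9)
  expect_gte(anti_ok, 9)
})

test_that("all-noise matrices yield almost no anti-correlated pairs", {
  set.seed(4)
  a <- mk_expr(matrix(rnorm(30 * 217), 30, 217))
  b <- mk_expr(matrix(rnorm(30 * 217), 30, 217))
  rownames(b) <- paste0("m", 1:30)
  out <- screen_anticorrelation(correlate_pairs(a, b), 0.01)
  expect_lte(nrow(out), 0.01 * 900 + 1)
})

test_that("duplex hits require the constructed seed and pairing pattern", {
  mir <- "ACGUACGUACGUACGUACGUAC"  # 22 nt
  lnc0 <- paste(rep("A", 200), collapse = "")
  site <- rna_revcomp(mir)
  lnc <- paste0(substr(lnc0, 1, 50), site, substr(lnc0, 1, 128))
  hits <- duplex_predict(lnc, mir)
  expect_true(any(hits$from == 51 & hits$to == 72))
  full <- hits[hits$from == 51, ]
  expect_equal(full$paired_bases, 22L)
  expect_equal(full$seed_mismatch, 0L)
  expect_lt(full$energy, -12)
  # two seed mismatches kill the hit
  chars <- strsplit(site, "")[[1]]
  # seed = miRNA positions 2..8 -> window positions 15..21 of the site;
  # position 15 pairs miRNA U8 (break with C), 16 pairs G7 (break with A)
  chars[15] <- "C"; chars[16] <- "A"
  broken <- paste0(substr(lnc0, 1, 50), paste(chars, collapse = ""),
                   substr(lnc0, 1, 128))
  hits2 <- duplex_predict(broken, mir)
  expect_false(any(hits2$from == 51))
})

test_that("duplex prediction is invariant to case and T/U encoding", {
  fx <- generate_sequence_fixture(1, 1, planted_sites = 1, seed = 3)
  a <- duplex_predict(fx$lnc[[1]], fx$mir[[1]])
  b <- duplex_predict(tolower(fx$lnc[[1]]), fx$mir[[1]])
  expect_equal(a, b)
  dna <- gsub("U", "T", fx$lnc[[1]])
  expect_warning(cc <- duplex_predict(dna, fx$mir[[1]]), "DNA")
  expect_equal(a, cc)
  expect_error(duplex_predict("ACGX", "ACGU"), "non-RNA")
})

test_that("random duplex scans equal the brute-force oracle", {
  set.seed(5)
  for (i in 1:20) {
    fx <- generate_sequence_fixture(1, 1, planted_sites = i %% 2, seed = 100 + i,
                                    lnc_len = 300)
    got <- duplex_predict(fx$lnc[[1]], fx$mir[[1]])
    orc <- oracle_duplex(fx$lnc[[1]], fx$mir[[1]])
    expect_equal(nrow(got), nrow(orc))
    if (nrow(got)) {
      expect_equal(got$from, orc$from)
      expect_equal(got$paired_bases, orc$paired_bases)
      expect_equal(got$energy, orc$energy, tolerance = 1e-12)
    }
  }
})

test_that("stricter parameters yield a subset of hits", {
  fx <- generate_sequence_fixture(3, 3, planted_sites = 3, seed = 9)
  loose <- duplex_params()
  strict <- loose
  strict$min_paired <- 16L
  strict$max_energy <- -20
  strict$max_seed_mismatch <- 0L
  for (i in 1:3) {
    h_loose <- duplex_predict(fx$lnc[[i]], fx$mir[[i]], loose)
    h_strict <- duplex_predict(fx$lnc[[i]], fx$mir[[i]], strict)
    expect_true(all(h_strict$from %in% h_loose$from))
  }
})

test_that("supported pairs intersect anti-correlation with target prediction", {
  anticorr <- tibble::tibble(
    feature_a = c("l1", "l2", "l3"), feature_b = c("m1", "m2", "m3"),
    r = c(-0.3, -0.3, 0.4), p = c(1e-5, 1e-5, 1e-5), q = c(0.01, 0.2, 0.001)
  )
  preds <- tibble::tibble(
    lnc = c("l1", "l3"), mirna = c("m1", "m3"),
    from = c(10L, 20L), to = c(31L, 41L),
    seed_matched = 7L, seed_mismatch = 0L, seed_wobble = 0L,
    paired_bases = 14L, energy = c(-20, -25)
  )
  out <- supported_pairs(anticorr, preds, q_max = 0.05)
  # l2 has no site; l3 is positively correlated; only l1 survives
  expect_equal(out$lnc, "l1")
  expect_equal(out$from, 10L)
})

test_that("planted sponge pairs are recovered end to end", {
  co <- generate_cohort(small_cohort_config(seed = 12))
  pm <- correlate_pairs(
    co$lnc_expr[startsWith(rownames(co$lnc_expr), "lnc_sponge"), , drop = FALSE],
    co$mirna_expr
  )
  ac <- screen_anticorrelation(pm, 0.01)
  dp <- duplex_predict_pairs(co$sequences$lnc, co$sequences$mir,
                             pairs = ac[, c("feature_a", "feature_b")] |>
                               dplyr::rename(lnc = "feature_a", mirna = "feature_b"))
  sup <- supported_pairs(ac, dp, q_max = 0.05)
  planted <- paste(co$truth$duplex_sites$lnc, co$truth$duplex_sites$mirna)
  retained <- paste(ac$feature_a, ac$feature_b)
  # most planted pairs survive the correlation screen at this cohort size,
  # and every one that does is supported by its planted duplex site
  expect_gte(sum(planted %in% retained), 2)
  expect_true(all(intersect(planted, retained) %in%
                    paste(sup$lnc, sup$mirna)))
})
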