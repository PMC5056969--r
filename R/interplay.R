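#' All-pairs expression correlation between two feature sets
#'
#' Computes the correlation of every feature in `expr_a` against every
#' feature in `expr_b` over their shared samples, with p-values and a
#' Benjamini-Hochberg q across all pairs. Pearson p-values come from the
#' exact t transform; Kendall tau-b p-values use the large-sample normal
#' approximation. Zero-variance features cannot be correlated: their pairs
#' are excluded and reported in the `excluded_features` attribute.
#'
#' @param expr_a,expr_b log2 feature x sample matrices sharing >= 3 samples.
#' @param method `"pearson"` (default; the lncRNA-mRNA screen) or
#'   `"kendall"` (the lncRNA-miRNA screen).
#' @return Tibble with `feature_a`, `feature_b`, `r`, `p`, `q`; the
#'   correlation method is recorded in the `method` attribute.
#' @export
correlate_pairs <- function(expr_a, expr_b, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  check_expr(expr_a, min_samples = 3L, arg = "expr_a")
  check_expr(expr_b, min_samples = 3L, arg = "expr_b")
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  if (length(shared) < 3L) rlang::abort("Need >= 3 shared samples.")
  a <- expr_a[, shared, drop = FALSE]
  b <- expr_b[, shared, drop = FALSE]
  excl_a <- rownames(a)[row_sds(a) == 0]
  excl_b <- rownames(b)[row_sds(b) == 0]
  if (length(excl_a)) a <- a[setdiff(rownames(a), excl_a), , drop = FALSE]
  if (length(excl_b)) b <- b[setdiff(rownames(b), excl_b), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) rlang::abort("No feature with nonzero variance.")
  n <- length(shared)
  r <- cor(t(a), t(b), method = method)
  if (method == "pearson") {
    r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tt <- r_c * sqrt((n - 2) / (1 - r_c^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * pnorm(-abs(z))
  }
  out <- tibble::tibble(
    feature_a = rep(rownames(a), times = nrow(b)),
    feature_b = rep(rownames(b), each = nrow(a)),
    r = as.vector(r),
    p = pmin(as.vector(p), 1)
  )
  out$q <- bh_adjust(out$p)
  attr(out, "method") <- method
  attr(out, "excluded_features") <- c(excl_a, excl_b)
  out
}

#' Screen for strongly co-expressed pairs
#'
#' Retains pairs with correlation strictly greater than `r_min` (the
#' lncRNA-mRNA co-expression screen; a pair at exactly `r_min` is excluded).
#'
#' @param pairs Output of [correlate_pairs()].
#' @param r_min Strict lower bound on `r`.
#' @return The retained subset of `pairs`.
#' @export
screen_coexpression <- function(pairs, r_min = 0.9) {
  dplyr::filter(pairs, .data$r > r_min)
}

#' Screen for significantly anti-correlated pairs
#'
#' Retains pairs with negative correlation and BH q below `q_max` (the
#' lncRNA-miRNA anti-correlation screen).
#'
#' @param pairs Output of [correlate_pairs()].
#' @param q_max Strict upper bound on the BH q-value.
#' @return The retained subset of `pairs`.
#' @export
screen_anticorrelation <- function(pairs, q_max = 0.01) {
  dplyr::filter(pairs, .data$r < 0, .data$q < q_max)
}

# pair codes: top strand (lncRNA) base then bottom strand (miRNA) base.
# Watson-Crick: AU UA CG GC; wobble: GU UG.
.pair_code <- function(top, bottom) {
  key <- paste0(top, bottom)
  code <- c(AU = 1L, UA = 2L, CG = 3L, GC = 4L, GU = 5L, UG = 6L)[key]
  ifelse(is.na(code), 0L, code)
}

# Nearest-neighbor stack free energies (kcal/mol, 37C), indexed by the pair
# at lncRNA position i (row) and position i+1 (column); Watson-Crick block
# from the Xia et al. parameter set, wobble-involving stacks representative
# literature-range values. The table obeys the strand-flip symmetry
# S[p1,p2] == S[sym(p2),sym(p1)].
.stack_table <- local({
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  S <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  S["AU", "AU"] <- -0.93; S["UA", "UA"] <- -0.93
  S["AU", "UA"] <- -1.10
  S["UA", "AU"] <- -1.33
  S["CG", "CG"] <- -3.26; S["GC", "GC"] <- -3.26
  S["GC", "CG"] <- -3.42
  S["CG", "GC"] <- -2.36
  S["GC", "AU"] <- -2.35; S["UA", "CG"] <- -2.35
  S["GC", "UA"] <- -2.24; S["AU", "CG"] <- -2.24
  S["CG", "AU"] <- -2.11; S["UA", "GC"] <- -2.11
  S["CG", "UA"] <- -2.08; S["AU", "GC"] <- -2.08
  S["AU", "GU"] <- -1.30; S["UG", "UA"] <- -1.30
  S["AU", "UG"] <- -1.00; S["GU", "UA"] <- -1.00
  S["UA", "GU"] <- -1.00; S["UG", "AU"] <- -1.00
  S["UA", "UG"] <- -0.80; S["GU", "AU"] <- -0.80
  S["CG", "GU"] <- -2.10; S["UG", "GC"] <- -2.10
  S["CG", "UG"] <- -1.40; S["GU", "GC"] <- -1.40
  S["GC", "GU"] <- -2.50; S["UG", "CG"] <- -2.50
  S["GC", "UG"] <- -1.50; S["GU", "CG"] <- -1.50
  S["GU", "GU"] <- -0.50; S["UG", "UG"] <- -0.50
  S["GU", "UG"] <- 0.50
  S["UG", "GU"] <- -0.60
  S
})

#' Default duplex-filter parameters
#'
#' The published filter constraints of the target-prediction run the module
#' reproduces: seed of seven bases (miRNA positions 2-8) with at most one
#' mismatch and at most one G:U wobble in the seed, at least 12 paired-up
#' bases in the heteroduplex, and folding energy at most -12 kcal/mol.
#'
#' @return Named list of parameters accepted by [duplex_predict()].
#' @export
duplex_params <- function() {
  list(seed_start = 2L, seed_end = 8L, max_seed_mismatch = 1L,
       max_seed_wobble = 1L, min_paired = 12L, max_energy = -12)
}

#' Predict miRNA binding sites on an lncRNA by seed-match duplex scan
#'
#' Slides the miRNA antiparallel along the lncRNA without gaps. A window is
#' a hit when (i) the seed region (miRNA positions `seed_start..seed_end`,
#' default 2-8) is paired at all but at most `max_seed_mismatch` positions
#' with at most `max_seed_wobble` G:U wobbles among the seed pairs, (ii) the
#' whole window has at least `min_paired` Watson-Crick or wobble paired
#' bases, and (iii) the stacking energy summed over contiguous paired runs
#' (nearest-neighbor table, no loop penalties) is at most `max_energy`
#' kcal/mol. This is a standalone sliding-window filter implementing the
#' published parameter constraints; it does not reproduce the
#' pattern-discovery stage of the original predictor.
#'
#' Sequences may be given in DNA alphabet (T is converted to U with a
#' warning) or lower case; other characters raise an error.
#'
#' @param lnc_seq,mir_seq RNA sequences (single strings, 5'->3').
#' @param params Parameter list from [duplex_params()].
#' @return Tibble of hits: `from`, `to` (1-based inclusive window on the
#'   lncRNA), `seed_matched`, `seed_mismatch`, `seed_wobble`,
#'   `paired_bases`, `energy`.
#' @export
duplex_predict <- function(lnc_seq, mir_seq, params = duplex_params()) {
  lnc <- clean_rna(lnc_seq, "lnc_seq")
  mir <- clean_rna(mir_seq, "mir_seq")
  lm <- length(mir)
  if (length(lnc) < lm) {
    rlang::abort("lncRNA must be at least as long as the miRNA window.")
  }
  seed_pos <- params$seed_start:params$seed_end
  seed_len <- length(seed_pos)
  n_off <- length(lnc) - lm + 1L
  # antiparallel: miRNA position i pairs lncRNA position from + (lm - i)
  mir_on_lnc <- rev(mir)  # index w = 1..lm along the lncRNA window
  seed_w <- lm - seed_pos + 1L
  hits <- vector("list", 0L)
  for (from in seq_len(n_off)) {
    win <- lnc[from:(from + lm - 1L)]
    codes <- .pair_code(win, mir_on_lnc)
    paired <- codes > 0L
    n_paired <- sum(paired)
    if (n_paired < params$min_paired) next
    seed_codes <- codes[seed_w]
    seed_paired <- sum(seed_codes > 0L)
    seed_mis <- seed_len - seed_paired
    if (seed_mis > params$max_seed_mismatch) next
    seed_wob <- sum(seed_codes >= 5L)
    if (seed_wob > params$max_seed_wobble) next
    e <- stack_energy(codes)
    if (e > params$max_energy) next
    hits[[length(hits) + 1L]] <- tibble::tibble(
      from = from, to = from + lm - 1L,
      seed_matched = seed_paired, seed_mismatch = seed_mis,
      seed_wobble = seed_wob, paired_bases = n_paired, energy = e
    )
  }
  if (length(hits)) dplyr::bind_rows(hits) else {
    tibble::tibble(from = integer(), to = integer(), seed_matched = integer(),
                   seed_mismatch = integer(), seed_wobble = integer(),
                   paired_bases = integer(), energy = numeric())
  }
}

# stacking energy over contiguous paired runs; codes index .stack_table rows
stack_energy <- function(codes) {
  e <- 0
  for (i in seq_len(length(codes) - 1L)) {
    if (codes[i] > 0L && codes[i + 1L] > 0L) {
      e <- e + .stack_table[codes[i], codes[i + 1L]]
    }
  }
  e
}

clean_rna <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    rlang::abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  s <- toupper(seq)
  if (grepl("T", s, fixed = TRUE)) {
    rlang::warn(sprintf("`%s` looks like DNA; converting T to U.", arg))
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  if (length(bad)) {
    rlang::abort(sprintf("`%s` contains non-RNA character(s): %s.",
                         arg, paste(bad, collapse = ", ")))
  }
  chars
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string.
#' @return The reverse complement (RNA alphabet).
#' @export
rna_revcomp <- function(seq) {
  chars <- clean_rna(seq, "seq")
  comp <- c(A = "U", U = "A", G = "C", C = "G")[chars]
  paste(rev(comp), collapse = "")
}

#' Run the duplex predictor over many lncRNA-miRNA pairs
#'
#' @param lnc_seqs,mir_seqs Named character vectors of sequences.
#' @param pairs Tibble with columns `lnc` and `mirna` naming the pairs to
#'   scan; `NULL` scans all combinations.
#' @param params See [duplex_params()].
#' @return Tibble of hits with `lnc` and `mirna` columns prepended.
#' @export
duplex_predict_pairs <- function(lnc_seqs, mir_seqs, pairs = NULL,
                                 params = duplex_params()) {
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(lnc = names(lnc_seqs), mirna = names(mir_seqs))
  }
  out <- purrr::pmap(pairs[, c("lnc", "mirna")], function(lnc, mirna) {
    h <- duplex_predict(lnc_seqs[[lnc]], mir_seqs[[mirna]], params)
    if (nrow(h)) dplyr::bind_cols(tibble::tibble(lnc = lnc, mirna = mirna), h)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble::tibble(lnc = character(), mirna = character(),
                          from = integer(), to = integer(),
                          seed_matched = integer(), seed_mismatch = integer(),
                          seed_wobble = integer(), paired_bases = integer(),
                          energy = numeric())
  }
  out
}

#' Anti-correlated pairs supported by target prediction
#'
#' Intersects the anti-correlation screen with the duplex predictions on
#' (lncRNA, miRNA) identity: a pair is retained when its anti-correlation q
#' is below `q_max` and at least one duplex hit exists. The best (lowest
#' energy) hit's window is attached.
#'
#' @param anticorr Output of [screen_anticorrelation()] (columns `feature_a`
#'   = lncRNA, `feature_b` = miRNA, `r`, `q`).
#' @param predictions Output of [duplex_predict_pairs()].
#' @param q_max Anti-correlation q threshold for this stage.
#' @return Tibble: `lnc`, `mirna`, `r`, `q`, `from`, `to`, `energy`,
#'   `n_sites`.
#' @export
supported_pairs <- function(anticorr, predictions, q_max = 0.05) {
  ac <- dplyr::filter(anticorr, .data$r < 0, .data$q < q_max)
  if (!nrow(ac) || !nrow(predictions)) {
    return(tibble::tibble(lnc = character(), mirna = character(),
                          r = numeric(), q = numeric(), from = integer(),
                          to = integer(), energy = numeric(),
                          n_sites = integer()))
  }
  best <- predictions |>
    dplyr::group_by(.data$lnc, .data$mirna) |>
    dplyr::arrange(.data$energy, .data$from, .by_group = TRUE) |>
    dplyr::summarise(from = dplyr::first(.data$from),
                     to = dplyr::first(.data$to),
                     energy = dplyr::first(.data$energy),
                     n_sites = dplyr::n(), .groups = "drop")
  out <- dplyr::inner_join(
    dplyr::rename(ac, lnc = "feature_a", mirna = "feature_b"),
    best, by = c("lnc", "mirna")
  )
  dplyr::select(out, "lnc", "mirna", "r", "q", "from", "to", "energy", "n_sites")
}
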