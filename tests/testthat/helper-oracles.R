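# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by the most direct route available, sharing no
# code with the implementation they check.

# quadratic all-pairs interval overlap (0-based half-open)
oracle_overlap <- function(probes, transcripts, same_strand_only = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(transcripts))) {
      if (probes$chrom[i] != transcripts$chrom[j]) next
      ov <- min(probes$end[i], transcripts$end[j]) -
        max(probes$start[i], transcripts$start[j])
      ss <- probes$strand[i] == transcripts$strand[j]
      if (ov >= 1 && (!same_strand_only || ss)) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = probes$probe_id[i],
          transcript_id = transcripts$transcript_id[j],
          overlap_bp = as.integer(ov), same_strand = ss
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(probe_id = character(), transcript_id = character(),
               overlap_bp = integer(), same_strand = logical())
  }
  out[order(out$probe_id, out$transcript_id), , drop = FALSE]
}

# exhaustive 1-D two-cluster split: minimal within-cluster sum of squares
oracle_kmeans2 <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  best_k <- NA
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next
    lo <- v[1:k]; hi <- v[(k + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) { best <- w; best_k <- k }
  }
  list(wss = best, boundary = v[best_k])
}

# brute-force duplex scan re-deriving the filter from scratch
oracle_duplex <- function(lnc, mir, params = duplex_params()) {
  comp <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
  }
  wob <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")
  stacks <- lncsig:::.stack_table
  pair_name <- function(a, b) paste0(a, b)
  lncv <- strsplit(toupper(lnc), "")[[1]]
  mirv <- strsplit(toupper(mir), "")[[1]]
  lm <- length(mirv)
  hits <- list()
  for (from in 1:(length(lncv) - lm + 1)) {
    win <- lncv[from:(from + lm - 1)]
    mrev <- rev(mirv)
    is_wc <- comp(win, mrev)
    is_wob <- wob(win, mrev)
    paired <- is_wc | is_wob
    if (sum(paired) < params$min_paired) next
    # seed = miRNA positions 2..8 -> window indices lm-1 .. lm-7
    seed_idx <- lm - (params$seed_start:params$seed_end) + 1
    sp <- paired[seed_idx]
    if (sum(!sp) > params$max_seed_mismatch) next
    if (sum(is_wob[seed_idx]) > params$max_seed_wobble) next
    e <- 0
    for (i in 1:(lm - 1)) {
      if (paired[i] && paired[i + 1]) {
        e <- e + stacks[pair_name(win[i], mrev[i]), pair_name(win[i + 1], mrev[i + 1])]
      }
    }
    if (e > params$max_energy) next
    hits[[length(hits) + 1]] <- data.frame(
      from = from, to = from + lm - 1, paired_bases = sum(paired), energy = e
    )
  }
  if (length(hits)) do.call(rbind, hits) else {
    data.frame(from = integer(), to = integer(), paired_bases = integer(),
               energy = numeric())
  }
}

# direct-formula Pearson correlation and p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# small synthetic cohort configuration shared by pipeline tests
small_cohort_config <- function(seed, ...) {
  cohort_config(n_lnc = 300, n_mrna = 60, n_mirna = 30, n_sponge = 3,
                n_coexpr = 2, n_module = 10, seed = seed, ...)
}

# survival records with hazard driven by a single planted covariate
single_driver_records <- function(n, beta, x, baseline = 1e-4,
                                  horizon = 3650, censor_rate = 0.5) {
  tt <- rexp(n, rate = baseline * exp(beta * x))
  cc <- pmin(ifelse(runif(n) < censor_rate, runif(n, 0, horizon), Inf), horizon)
  tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                 time = pmax(pmin(tt, cc), 1e-6),
                 event = as.integer(tt <= cc))
}
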