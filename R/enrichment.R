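#' Rank genes by Pearson correlation with a continuous phenotype
#'
#' The ranking metric for continuous-phenotype enrichment: each gene's
#' Pearson correlation with the phenotype vector (typically one lncRNA's
#' expression), sorted decreasing.
#'
#' @param expr Gene log2 feature x sample matrix.
#' @param phenotype Named numeric vector (names = sample ids) or a feature
#'   id present in `phenotype_expr`.
#' @param phenotype_expr Optional matrix from which to extract `phenotype`
#'   when it is given as a feature id.
#' @return Tibble (`gene`, `score`) sorted by decreasing score.
#' @export
rank_by_correlation <- function(expr, phenotype, phenotype_expr = NULL) {
  check_expr(expr, min_samples = 3L)
  if (is.character(phenotype) && length(phenotype) == 1L) {
    if (is.null(phenotype_expr) || !phenotype %in% rownames(phenotype_expr)) {
      rlang::abort("Phenotype feature not found in `phenotype_expr`.")
    }
    phenotype <- phenotype_expr[phenotype, ]
  }
  shared <- intersect(colnames(expr), names(phenotype))
  if (length(shared) < 3L) rlang::abort("Need >= 3 shared samples.")
  ph <- phenotype[shared]
  if (sd(ph) == 0) rlang::abort("Zero-variance phenotype.")
  x <- expr[, shared, drop = FALSE]
  keep <- row_sds(x) > 0
  r <- as.vector(cor(t(x[keep, , drop = FALSE]), ph))
  out <- tibble::tibble(gene = rownames(x)[keep], score = r)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

# core weighted Kolmogorov-Smirnov running sum; genes = ranked ids,
# scores = ranking metric in the same order.
gsea_running_sum <- function(genes, scores, members, p = 1) {
  N <- length(genes)
  hit <- genes %in% members
  Nh <- sum(hit)
  if (Nh < 1L) rlang::abort("Gene set has empty intersection with the ranked list.")
  w <- abs(scores)^p
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) {
    # all hit scores zero: fall back to unweighted increments
    inc <- ifelse(hit, 1 / Nh, 0)
  } else {
    inc <- ifelse(hit, w / denom_hit, 0)
  }
  if (N == Nh) {
    # degenerate: the set is the whole list; no miss penalty is defined, so
    # the running sum is the cumulative hit gain and ES its maximum
    run <- cumsum(inc)
  } else {
    dec <- ifelse(hit, 0, 1 / (N - Nh))
    run <- cumsum(inc - dec)
  }
  i_ext <- which.max(abs(run))
  list(es = run[i_ext], running = run, at = i_ext, hit = hit)
}

#' Enrichment score of one gene set on a ranked list
#'
#' Standard weighted Kolmogorov-Smirnov enrichment: walking down the ranked
#' list, member genes increment the running sum proportionally to
#' `|score|^p` (normalized over members), non-members decrement it by
#' `1/(N - Nh)`; the enrichment score (ES) is the extremum. `p = 0` gives
#' the unweighted (classic KS) statistic; `p = 1` is the conventional
#' weighted default.
#'
#' @param ranked Tibble from [rank_by_correlation()] (`gene`, `score`).
#' @param gene_set Character vector of member gene ids.
#' @param p Weighting exponent.
#' @return A `gsea_es` list: `es`, `at` (position of the extremum),
#'   `running` (the full running sum), `leading_edge` (member genes at or
#'   before the extremum for positive ES, after it for negative).
#' @export
gsea_es <- function(ranked, gene_set, p = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  rs <- gsea_running_sum(ranked$gene, ranked$score, gene_set, p = p)
  le <- if (rs$es >= 0) {
    ranked$gene[seq_len(rs$at)][rs$hit[seq_len(rs$at)]]
  } else {
    idx <- seq(rs$at, nrow(ranked))
    ranked$gene[idx][rs$hit[idx]]
  }
  structure(list(es = rs$es, at = rs$at, running = rs$running,
                 leading_edge = le, gene_set = gene_set, p = p),
            class = "gsea_es")
}

#' @export
print.gsea_es <- function(x, ...) {
  cat(sprintf("<gsea_es> ES = %.4f at rank %d; leading edge %d genes\n",
              x$es, x$at, length(x$leading_edge)))
  invisible(x)
}

#' @describeIn gsea_es Enrichment plot (running sum + hit positions).
#' @param object A `gsea_es`.
#' @param ... Unused.
#' @method autoplot gsea_es
#' @export
autoplot.gsea_es <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$running),
                       running = object$running)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Rank in ordered gene list",
                  y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' Continuous-phenotype GSEA with permutation FDR
#'
#' For each gene set: ES on the observed correlation ranking; a null
#' distribution from `n_perm` phenotype permutations (the phenotype vector
#' is shuffled across samples and the whole ranking recomputed, preserving
#' gene-gene correlation); NES by sign-matched mean normalization; nominal
#' p against the same-sign null; FDR q by the pooled-NES positive/negative
#' procedure. Sets are flagged significant at `fdr_max`.
#'
#' @param expr Gene log2 feature x sample matrix.
#' @param phenotype Named numeric phenotype vector (see
#'   [rank_by_correlation()]).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]);
#'   sets with fewer than `min_size` members in the expression universe are
#'   dropped.
#' @param n_perm Number of phenotype permutations (warning below 100).
#' @param seed Integer seed (mandatory).
#' @param p Weighting exponent (see [gsea_es()]).
#' @param fdr_max Significance threshold on the FDR q.
#' @param min_size Minimum set size after restriction to the universe.
#' @return Tibble: `gene_set`, `size`, `es`, `nes`, `p_nominal`, `fdr`,
#'   `significant`, `leading_edge` (list column).
#' @export
gsea_fdr <- function(expr, phenotype, gene_sets, n_perm = 1000L, seed,
                     p = 1, fdr_max = 0.25, min_size = 2L) {
  if (missing(seed)) rlang::abort("`seed` is required for permutations.")
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100) rlang::warn("Fewer than 100 permutations: FDR is coarse.")
  if (is.character(phenotype)) {
    rlang::abort("Pass the phenotype as a named numeric vector here.")
  }
  ranked <- rank_by_correlation(expr, phenotype)
  shared <- intersect(colnames(expr), names(phenotype))
  ph <- phenotype[shared]
  x <- expr[, shared, drop = FALSE]
  x <- x[row_sds(x) > 0, , drop = FALSE]

  sets <- lapply(gene_sets, intersect, y = rownames(x))
  sizes <- lengths(sets)
  keep <- sizes >= min_size
  if (!any(keep)) rlang::abort("No gene set with enough members in the universe.")
  sets <- sets[keep]
  sizes <- sizes[keep]

  obs <- lapply(sets, function(s) gsea_es(ranked, s, p = p))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # permutation null: recompute the correlation ranking per shuffled phenotype
  xt <- t(x)
  es_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      php <- sample(ph)
      r <- as.vector(cor(xt, php))
      ord <- order(r, decreasing = TRUE)
      genes_o <- rownames(x)[ord]
      scores_o <- r[ord]
      vapply(sets, function(s)
        gsea_running_sum(genes_o, scores_o, s, p = p)$es, numeric(1))
    }, numeric(length(sets)))
  })
  es_null <- matrix(es_null, nrow = length(sets))

  # sign-matched normalization and nominal p
  nes <- numeric(length(sets))
  p_nom <- numeric(length(sets))
  nes_null <- matrix(NA_real_, length(sets), n_perm)
  for (i in seq_along(sets)) {
    null_i <- es_null[i, ]
    pos_mean <- mean(null_i[null_i >= 0])
    neg_mean <- mean(abs(null_i[null_i < 0]))
    nes_null[i, null_i >= 0] <- null_i[null_i >= 0] / pos_mean
    nes_null[i, null_i < 0] <- null_i[null_i < 0] / neg_mean
    if (es_obs[i] >= 0) {
      nes[i] <- es_obs[i] / pos_mean
      p_nom[i] <- (1 + sum(null_i[null_i >= 0] >= es_obs[i])) /
        (1 + sum(null_i >= 0))
    } else {
      nes[i] <- es_obs[i] / neg_mean
      p_nom[i] <- (1 + sum(null_i[null_i < 0] <= es_obs[i])) /
        (1 + sum(null_i < 0))
    }
  }
  # pooled-NES FDR
  pool <- as.vector(nes_null)
  pool <- pool[is.finite(pool)]
  fdr <- vapply(seq_along(sets), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  tibble::tibble(
    gene_set = names(sets),
    size = as.integer(sizes),
    es = unname(es_obs),
    nes = unname(nes),
    p_nominal = unname(p_nom),
    fdr = unname(fdr),
    significant = !is.na(fdr) & fdr <= fdr_max,
    leading_edge = lapply(obs, `[[`, "leading_edge")
  ) |> dplyr::arrange(.data$fdr, .data$p_nominal)
}
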