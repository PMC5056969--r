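#' Assign array probes to transcripts by genomic overlap
#'
#' Re-annotation step: a probe is assigned to every transcript whose genomic
#' interval it overlaps by at least 1 bp on the same chromosome (and, when
#' `require_same_strand = TRUE`, the same strand). Coordinates are 0-based
#' half-open throughout, so abutting intervals (`probe end == transcript
#' start`) do not overlap. Strand matching defaults to sense because array
#' probes interrogate the sense transcript, but antisense lncRNAs (for
#' example those overlapping NEAT1/MALAT1) can be captured by relaxing it.
#'
#' @param probes Tibble with `probe_id`, `chrom`, `start`, `end`, `strand`.
#' @param transcripts Tibble with `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param require_same_strand If `TRUE` (default) only sense overlaps are
#'   reported.
#' @return Tibble of assignments: `probe_id`, `transcript_id`, `overlap_bp`,
#'   `same_strand`.
#' @export
intersect_probes <- function(probes, transcripts, require_same_strand = TRUE) {
  validate_intervals(probes, id_col = "probe_id")
  validate_intervals(transcripts, id_col = "transcript_id")
  # GRanges is 1-based inclusive: shift start by +1, keep end.
  gp <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(probes$start + 1L, probes$end),
    strand = probes$strand
  )
  gt <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end),
    strand = transcripts$strand
  )
  hits <- GenomicRanges::findOverlaps(gp, gt, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gp)[qh], IRanges::ranges(gt)[sh]
  ))
  out <- tibble::tibble(
    probe_id = probes$probe_id[qh],
    transcript_id = transcripts$transcript_id[sh],
    overlap_bp = as.integer(ov),
    same_strand = probes$strand[qh] == transcripts$strand[sh]
  )
  if (isTRUE(require_same_strand)) {
    out <- dplyr::filter(out, .data$same_strand)
  }
  dplyr::arrange(out, .data$probe_id, .data$transcript_id)
}

#' Retain probes mapping unambiguously to a single lncRNA
#'
#' Specificity filter: a probe is kept only if it is assigned to exactly one
#' lncRNA-biotype transcript and to no coding-biotype transcript. Probes
#' hitting two lncRNAs, or one lncRNA plus a coding gene, are discarded.
#'
#' @param assignments Output of [intersect_probes()].
#' @param transcripts Transcript tibble carrying `transcript_id` and
#'   `biotype`.
#' @return The retained subset of `assignments` (lncRNA rows only).
#' @export
filter_unambiguous <- function(assignments, transcripts) {
  if (!all(assignments$transcript_id %in% transcripts$transcript_id)) {
    rlang::abort("Assignments reference unknown transcripts.")
  }
  bio <- transcripts$biotype[match(assignments$transcript_id,
                                   transcripts$transcript_id)]
  a <- dplyr::mutate(assignments, biotype = bio)
  keep <- a |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      n_lnc = sum(.data$biotype == "lncRNA"),
      n_coding = sum(.data$biotype == "coding"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_lnc == 1L, .data$n_coding == 0L)
  out <- dplyr::filter(a, .data$probe_id %in% keep$probe_id,
                       .data$biotype == "lncRNA")
  dplyr::select(out, -"biotype")
}

#' Summarize probe-level expression to one value per lncRNA
#'
#' Collapses the probe x sample matrix to an lncRNA x sample matrix, one row
#' per transcript, as the per-sample mean (or median) of its assigned
#' probes' log2 values. Transcripts with no assigned probe are omitted with
#' a message.
#'
#' @param expr Probe-level log2 matrix (probes x samples).
#' @param assignments Probe-to-lncRNA assignment tibble (typically after
#'   [filter_unambiguous()]).
#' @param method `"mean"` (default) or `"median"`.
#' @return lncRNA x sample log2 matrix.
#' @export
summarize_to_feature <- function(expr, assignments, method = c("mean", "median")) {
  method <- match.arg(method)
  check_expr(expr)
  missing <- setdiff(assignments$probe_id, rownames(expr))
  if (length(missing)) {
    rlang::abort(sprintf("Assignment probes absent from expression matrix: %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  split_probes <- split(assignments$probe_id, assignments$transcript_id)
  fun <- if (method == "mean") colMeans else function(m) apply(m, 2, median)
  vals <- vapply(
    split_probes,
    function(p) fun(expr[p, , drop = FALSE]),
    numeric(ncol(expr))
  )
  out <- matrix(vals, nrow = length(split_probes), ncol = ncol(expr),
                byrow = TRUE,
                dimnames = list(names(split_probes), colnames(expr)))
  out
}

#' Full probe re-annotation step
#'
#' Convenience wrapper chaining [intersect_probes()], [filter_unambiguous()]
#' and [summarize_to_feature()]: from a probe-level expression matrix plus
#' probe and transcript intervals to an lncRNA-level expression matrix.
#'
#' @inheritParams intersect_probes
#' @inheritParams summarize_to_feature
#' @return List with `expr` (lncRNA x sample matrix) and `assignments`
#'   (the retained probe assignments).
#' @export
reannotate_probes <- function(expr, probes, transcripts,
                              require_same_strand = TRUE,
                              method = "mean") {
  asn <- intersect_probes(probes, transcripts, require_same_strand)
  asn <- filter_unambiguous(asn, transcripts)
  if (!nrow(asn)) {
    rlang::abort("No probe maps unambiguously to an lncRNA.")
  }
  list(expr = summarize_to_feature(expr, asn, method = method),
       assignments = asn)
}
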