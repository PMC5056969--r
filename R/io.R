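#' Read and write expression matrices as TSV
#'
#' Expression matrices are stored as tab-separated text with features as rows,
#' a `feature_id` first column, and one column per sample. Values are log2
#' intensities.
#'
#' @param path Path to a TSV file.
#' @return For `read_expr_tsv()`, a numeric matrix (features x samples) with
#'   dimnames. For `write_expr_tsv()`, `path`, invisibly.
#' @export
read_expr_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) rlang::abort("Expression TSV needs feature_id + >=1 sample column.")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tbl[[1]])
  check_expr(m)
}

#' @rdname read_expr_tsv
#' @param expr Numeric feature x sample matrix with dimnames.
#' @export
write_expr_tsv <- function(expr, path) {
  check_expr(expr)
  tbl <- tibble::as_tibble(expr, rownames = "feature_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a sample annotation / survival table
#'
#' Tab-separated with at least `sample_id`; survival layers expect `time`
#' (days) and `event` (1 = progression/treatment, 0 = censored); any further
#' columns are treated as covariates (for example IGHV status, CD38, ZAP70,
#' cytogenetics).
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_samples_tsv
#' @param samples Data frame with a `sample_id` column.
#' @export
write_samples_tsv <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read probe intervals from BED
#'
#' BED is 0-based half-open; coordinates are kept in that convention
#' internally. Requires at least 6 columns (chrom, start, end, name, score,
#' strand).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `probe_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_probes_bed <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "probe_id", "score", "strand"),
    col_types = "ciicnc", progress = FALSE, comment = "#"
  )
  out <- tibble::tibble(
    probe_id = tbl$probe_id, chrom = tbl$chrom,
    start = tbl$start, end = tbl$end, strand = tbl$strand
  )
  validate_intervals(out, id_col = "probe_id")
  out
}

#' @rdname read_probes_bed
#' @param probes Tibble with `probe_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
write_probes_bed <- function(probes, path) {
  validate_intervals(probes, id_col = "probe_id")
  readr::write_tsv(
    tibble::tibble(
      chrom = probes$chrom, start = probes$start, end = probes$end,
      name = probes$probe_id, score = 0L, strand = probes$strand
    ),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read transcript records from GFF3 or 6-column TSV
#'
#' GFF3 coordinates are 1-based inclusive and converted to the package's
#' 0-based half-open convention on read (`start - 1`). The GFF3 attributes
#' column is parsed for `ID`, `biotype` and `alias` keys. The plain TSV form
#' has columns transcript_id, chrom, start, end, strand, biotype (already
#' 0-based half-open).
#'
#' @param path Path to a `.gff`/`.gff3` or TSV file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A tibble with `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, `alias`.
#' @export
read_transcripts <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    tbl <- readr::read_tsv(
      path, comment = "#",
      col_names = c("chrom", "source", "type", "start", "end",
                    "score", "strand", "phase", "attributes"),
      col_types = "ccciicccc", progress = FALSE
    )
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
      ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0,
             sub(paste0("^.*", key, "="), "", m), NA_character_)
    }
    ids <- vapply(tbl$attributes, function(a) {
      hit <- regmatches(a, regexpr("ID=[^;]*", a))
      if (length(hit)) sub("^ID=", "", hit) else NA_character_
    }, character(1), USE.NAMES = FALSE)
    bio <- vapply(tbl$attributes, function(a) {
      hit <- regmatches(a, regexpr("biotype=[^;]*", a))
      if (length(hit)) sub("^biotype=", "", hit) else "other"
    }, character(1), USE.NAMES = FALSE)
    ali <- vapply(tbl$attributes, function(a) {
      hit <- regmatches(a, regexpr("alias=[^;]*", a))
      if (length(hit)) sub("^alias=", "", hit) else NA_character_
    }, character(1), USE.NAMES = FALSE)
    out <- tibble::tibble(
      transcript_id = ids, chrom = tbl$chrom,
      start = tbl$start - 1L, end = tbl$end,
      strand = tbl$strand, biotype = bio, alias = ali
    )
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("transcript_id", "chrom", "start", "end", "strand", "biotype")
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      rlang::abort(paste0("Transcript TSV missing column(s): ",
                          paste(miss, collapse = ", ")))
    }
    out <- tbl
    if (!"alias" %in% names(out)) out$alias <- NA_character_
    out <- out[, c(need, "alias")]
  }
  validate_intervals(out, id_col = "transcript_id")
  out
}

#' @rdname read_transcripts
#' @param transcripts Transcript tibble as returned by `read_transcripts()`.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  readr::write_tsv(transcripts, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene identifiers, all
#' tab-separated (the MSigDB convention used for the Hallmark, KEGG and
#' Reactome collections).
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors; the `description` attribute on
#'   each element carries the second GMT field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      rlang::abort("Each GMT line needs name, description and >= 1 member.")
    }
    members <- unique(parts[-(1:2)])
    attr(members, "description") <- parts[2]
    members
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' Read or write RNA sequences in FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as plain named
#' character vectors in RNA alphabet (T converted to U).
#'
#' @param path FASTA file path.
#' @return `read_fasta_rna()`: named character vector of sequences.
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  gsub("T", "U", seqs, fixed = TRUE)
}

#' @rdname read_fasta_rna
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

validate_intervals <- function(tbl, id_col) {
  need <- c(id_col, "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("Interval table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!(tbl$start < tbl$end))
  if (length(bad)) {
    rlang::abort(sprintf(
      "Malformed interval (start >= end) for %s: %s",
      id_col, paste(tbl[[id_col]][head(bad, 5)], collapse = ", ")
    ))
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    rlang::abort("Interval strand must be '+' or '-'.")
  }
  invisible(tbl)
}
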