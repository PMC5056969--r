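#' Configure a synthetic CLL cohort
#'
#' Builds the configuration for [generate_cohort()]. Defaults emulate the
#' study design the pipeline targets: 217 early-stage (Binet A) CLL patients
#' plus 26 normal B-cell samples spread over five subtypes (peripheral
#' B-cells, germinal-center cells, a merged marginal-zone/memory/naive
#' cluster, tonsillar and bone-marrow plasma cells), with 1852 lncRNA,
#' 17788 mRNA and 286 miRNA features on a log2 scale; a 24-lncRNA
#' CLL-vs-comparator signature (10 up, 14 down); two planted prognostic
#' lncRNAs whose joint high/low dichotomy defines three risk groups with
#' hazard ratios 8.05 (high vs low) and 2.27 (intermediate vs low); and
#' planted co-expression structure (lncRNA-mRNA pairs at r = 0.95,
#' lncRNA-miRNA "sponge" pairs at r = -0.3 backed by planted seed-match
#' sites, and a 50-gene module correlated with the anchor lncRNA for
#' enrichment testing).
#'
#' Survival is exponential with proportional hazards: the baseline hazard is
#' chosen so the planted high-risk group has median progression-free survival
#' (PFS) of 862 days; censoring is uniform on `[0, censor_horizon]` for a
#' `censor_rate` fraction of patients, with administrative censoring at the
#' horizon for everyone. Clinical follow-up is generated for `n_clinical`
#' patients only.
#'
#' @param n_patients Number of CLL patients.
#' @param n_normals_per_subtype Named integer vector of normal B-cell sample
#'   counts, one entry per subtype.
#' @param n_lnc,n_mrna,n_mirna Feature counts for the three matrices.
#' @param n_signature Number of class-discriminant lncRNAs.
#' @param signature_effect Mean log2 shift of signature features in CLL
#'   versus the comparator B-cells.
#' @param n_signature_up Number of signature features upregulated in CLL
#'   (the remainder are downregulated).
#' @param subtype_markers,subtype_effect Per-subtype marker feature count and
#'   their log2 shift, giving normal subtypes distinct profiles.
#' @param planted_hr_high,planted_hr_intermediate Hazard ratios of the
#'   planted high- and intermediate-risk groups versus low risk.
#' @param prev_high_anchor,prev_high_partner Fraction of patients in the
#'   high-expression mode of the anchor / partner prognostic lncRNA.
#' @param bimodal_sep Log2 separation between the high and low expression
#'   modes of the prognostic lncRNAs.
#' @param baseline_hazard Low-risk-group hazard (events per day).
#' @param censor_rate Fraction of patients subject to random uniform
#'   censoring, in `[0, 1)`.
#' @param censor_horizon Administrative censoring time (days).
#' @param n_clinical Number of patients with survival follow-up.
#' @param noise_sd Residual log2 noise standard deviation.
#' @param corr_pairs Tibble of planted correlated pairs with columns
#'   `lnc`, `partner_type` (`"mrna"` or `"mirna"`) and `r`; `NULL` uses the
#'   defaults described above.
#' @param n_coexpr Number of planted lncRNA-mRNA pairs (used when
#'   `corr_pairs` is `NULL`).
#' @param coexpr_r Target correlation of the planted lncRNA-mRNA pairs.
#' @param n_sponge Number of planted lncRNA-miRNA anti-correlated pairs.
#' @param sponge_r Target (negative) correlation of sponge pairs.
#' @param n_module,module_r Size of the planted mRNA module and its
#'   correlation with the anchor lncRNA (the enrichment phenotype).
#' @param seed Integer RNG seed; generation is a pure function of the
#'   configuration.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 217L,
                          n_normals_per_subtype = c(pBC = 6L, GC = 4L, MZMN = 8L,
                                                    tPC = 4L, bmPC = 4L),
                          n_lnc = 1852L, n_mrna = 17788L, n_mirna = 286L,
                          n_signature = 24L,
                          signature_effect = 1.5,
                          n_signature_up = 10L,
                          subtype_markers = 10L,
                          subtype_effect = 2,
                          planted_hr_high = 8.05,
                          planted_hr_intermediate = 2.27,
                          prev_high_anchor = 0.25,
                          prev_high_partner = 0.20,
                          bimodal_sep = 5,
                          baseline_hazard = log(2) / (862 * 8.05),
                          censor_rate = 0.5,
                          censor_horizon = 3650,
                          n_clinical = min(209L, n_patients),
                          noise_sd = 1,
                          corr_pairs = NULL,
                          n_coexpr = 3L, coexpr_r = 0.95,
                          n_sponge = 11L, sponge_r = -0.3,
                          n_module = 50L, module_r = 0.5,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_normals_per_subtype = vapply(n_normals_per_subtype, check_count,
                                   integer(1), name = "n_normals_per_subtype"),
    n_lnc = check_count(n_lnc, "n_lnc"),
    n_mrna = check_count(n_mrna, "n_mrna"),
    n_mirna = check_count(n_mirna, "n_mirna"),
    n_signature = check_count(n_signature, "n_signature"),
    signature_effect = as.numeric(signature_effect),
    n_signature_up = check_count(n_signature_up, "n_signature_up", min = 0L),
    subtype_markers = check_count(subtype_markers, "subtype_markers", min = 0L),
    subtype_effect = as.numeric(subtype_effect),
    planted_hr_high = as.numeric(planted_hr_high),
    planted_hr_intermediate = as.numeric(planted_hr_intermediate),
    prev_high_anchor = check_fraction(prev_high_anchor, "prev_high_anchor",
                                      lo_open = TRUE, hi_open = TRUE),
    prev_high_partner = check_fraction(prev_high_partner, "prev_high_partner",
                                       lo_open = TRUE, hi_open = TRUE),
    bimodal_sep = as.numeric(bimodal_sep),
    baseline_hazard = as.numeric(baseline_hazard),
    censor_rate = check_fraction(censor_rate, "censor_rate", hi_open = TRUE),
    censor_horizon = as.numeric(censor_horizon),
    n_clinical = check_count(n_clinical, "n_clinical"),
    noise_sd = as.numeric(noise_sd),
    n_coexpr = check_count(n_coexpr, "n_coexpr", min = 0L),
    coexpr_r = as.numeric(coexpr_r),
    n_sponge = check_count(n_sponge, "n_sponge", min = 0L),
    sponge_r = as.numeric(sponge_r),
    n_module = check_count(n_module, "n_module", min = 0L),
    module_r = as.numeric(module_r),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(names(cfg$n_normals_per_subtype))) {
    names(cfg$n_normals_per_subtype) <-
      paste0("subtype", seq_along(cfg$n_normals_per_subtype))
  }
  if (!is.null(corr_pairs)) {
    stopifnot(is.data.frame(corr_pairs),
              all(c("partner_type", "r") %in% names(corr_pairs)))
    if (any(abs(corr_pairs$r) > 1)) {
      rlang::abort("corr_pairs target r must lie in [-1, 1].")
    }
    cfg$corr_pairs <- tibble::as_tibble(corr_pairs)
  } else {
    cfg$corr_pairs <- NULL
  }
  if (cfg$planted_hr_high <= 0 || cfg$planted_hr_intermediate <= 0) {
    rlang::abort("Planted hazard ratios must be > 0.")
  }
  if (cfg$noise_sd < 0) rlang::abort("`noise_sd` must be >= 0.")
  if (cfg$n_signature > cfg$n_lnc) {
    rlang::abort("Invalid config: n_signature exceeds n_lnc.")
  }
  n_sub <- length(cfg$n_normals_per_subtype)
  need_lnc <- cfg$n_signature + n_sub * cfg$subtype_markers + 2L +
    cfg$n_sponge + cfg$n_coexpr
  if (need_lnc > cfg$n_lnc) {
    rlang::abort(sprintf(
      "Invalid config: n_lnc = %d cannot hold %d planted lncRNA features.",
      cfg$n_lnc, need_lnc
    ))
  }
  if (cfg$n_module + cfg$n_coexpr > cfg$n_mrna) {
    rlang::abort("Invalid config: planted mRNA features exceed n_mrna.")
  }
  if (cfg$n_sponge > cfg$n_mirna) {
    rlang::abort("Invalid config: n_sponge exceeds n_mirna.")
  }
  if (cfg$n_clinical > cfg$n_patients) {
    rlang::abort("Invalid config: n_clinical exceeds n_patients.")
  }
  if (cfg$n_signature_up > cfg$n_signature) {
    rlang::abort("Invalid config: n_signature_up exceeds n_signature.")
  }
  structure(cfg, class = "cohort_config")
}

# latent-factor pair: returns n x 2 matrix of unit-variance deviates with
# correlation exactly r in expectation (shared standard-normal factor).
latent_pair <- function(n, r) {
  z <- rnorm(n)
  a <- sqrt(abs(r))
  b <- sqrt(1 - abs(r))
  cbind(a * z + b * rnorm(n),
        sign(r) * a * z + b * rnorm(n))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws lncRNA / mRNA / miRNA log2 expression matrices, sample annotations
#' with prognostic markers, and right-censored survival, planting the
#' structures described in [cohort_config()]. Generation is a pure function
#' of the configuration (identical output for identical config).
#'
#' @param config A [cohort_config()].
#' @param sequences If `TRUE` (default), also generate RNA sequences for the
#'   sponge lncRNA-miRNA pairs (with planted seed-match sites) plus random
#'   background sequences, via [generate_sequence_fixture()].
#' @return A `synthetic_cohort` list with elements `lnc_expr`, `mrna_expr`,
#'   `mirna_expr` (feature x sample matrices), `samples` (tibble with group,
#'   subtype, markers, `time`, `event`), `sequences` (`lnc`, `mir` named
#'   character vectors or `NULL`) and `truth` (planted signature, subtype
#'   markers, prognostic features, per-sample risk groups, correlated pairs,
#'   module members, duplex sites).
#' @export
generate_cohort <- function(config = cohort_config(), sequences = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ## ---- samples -----------------------------------------------------
    n_norm <- sum(cfg$n_normals_per_subtype)
    n <- cfg$n_patients + n_norm
    sample_id <- c(sprintf("CLL_%03d", seq_len(cfg$n_patients)),
                   unlist(lapply(names(cfg$n_normals_per_subtype), function(s) {
                     sprintf("%s_%02d", s, seq_len(cfg$n_normals_per_subtype[[s]]))
                   })))
    group <- rep(c("CLL", "normal"), c(cfg$n_patients, n_norm))
    subtype <- c(rep("CLL", cfg$n_patients),
                 rep(names(cfg$n_normals_per_subtype), cfg$n_normals_per_subtype))
    is_cll <- group == "CLL"

    markers <- tibble::tibble(
      ighv_um    = ifelse(is_cll, rbinom(n, 1, 85 / 216), NA_integer_),
      cd38_pos   = ifelse(is_cll, rbinom(n, 1, 0.30), NA_integer_),
      zap70_pos  = ifelse(is_cll, rbinom(n, 1, 0.30), NA_integer_),
      notch1_mut = ifelse(is_cll, rbinom(n, 1, 0.10), NA_integer_),
      del11q     = ifelse(is_cll, rbinom(n, 1, 0.10), NA_integer_),
      del17p     = ifelse(is_cll, rbinom(n, 1, 0.05), NA_integer_),
      tri12      = ifelse(is_cll, rbinom(n, 1, 0.12), NA_integer_)
    )

    ## ---- lncRNA features --------------------------------------------
    subtypes <- names(cfg$n_normals_per_subtype)
    n_sub <- length(subtypes)
    sig_ids <- sprintf("lnc_sig_%02d", seq_len(cfg$n_signature))
    sub_ids <- if (cfg$subtype_markers > 0) {
      unlist(lapply(subtypes, function(s)
        sprintf("lnc_sub_%s_%02d", s, seq_len(cfg$subtype_markers))))
    } else character(0)
    prog_ids <- c("lnc_prog_anchor", "lnc_prog_partner")
    sponge_ids <- if (cfg$n_sponge > 0) sprintf("lnc_sponge_%02d", seq_len(cfg$n_sponge)) else character(0)
    coexpr_ids <- if (cfg$n_coexpr > 0) sprintf("lnc_coexpr_%02d", seq_len(cfg$n_coexpr)) else character(0)
    n_bg <- cfg$n_lnc - length(sig_ids) - length(sub_ids) - 2L -
      length(sponge_ids) - length(coexpr_ids)
    lnc_ids <- c(sig_ids, sub_ids, prog_ids, sponge_ids, coexpr_ids,
                 if (n_bg > 0) sprintf("lnc_bg_%04d", seq_len(n_bg)))

    base_lnc <- runif(cfg$n_lnc, 4, 10)
    lnc <- matrix(rnorm(cfg$n_lnc * n, sd = cfg$noise_sd), cfg$n_lnc, n) + base_lnc
    dimnames(lnc) <- list(lnc_ids, sample_id)

    # class signature: shift in CLL relative to every normal subtype
    sig_dir <- rep(c(1, -1), c(cfg$n_signature_up,
                               cfg$n_signature - cfg$n_signature_up))
    lnc[sig_ids, is_cll] <- lnc[sig_ids, is_cll] +
      sig_dir * cfg$signature_effect
    # subtype markers: elevated in their own subtype only
    for (si in seq_along(subtypes)) {
      ids <- sub_ids[seq_len(cfg$subtype_markers) + (si - 1L) * cfg$subtype_markers]
      if (length(ids)) {
        lnc[ids, subtype == subtypes[si]] <-
          lnc[ids, subtype == subtypes[si]] + cfg$subtype_effect
      }
    }

    # prognostic anchor/partner: bimodal in patients, low mode in normals
    anchor_high <- ifelse(is_cll, rbinom(n, 1, cfg$prev_high_anchor), 0L)
    partner_high <- ifelse(is_cll, rbinom(n, 1, cfg$prev_high_partner), 0L)
    lnc["lnc_prog_anchor", ] <- lnc["lnc_prog_anchor", ] + anchor_high * cfg$bimodal_sep
    lnc["lnc_prog_partner", ] <- lnc["lnc_prog_partner", ] + partner_high * cfg$bimodal_sep

    ## ---- mRNA features ----------------------------------------------
    mod_ids <- if (cfg$n_module > 0) sprintf("mrna_mod_%03d", seq_len(cfg$n_module)) else character(0)
    cop_ids <- if (cfg$n_coexpr > 0) sprintf("mrna_coexpr_%02d", seq_len(cfg$n_coexpr)) else character(0)
    n_mbg <- cfg$n_mrna - length(mod_ids) - length(cop_ids)
    mrna_ids <- c(mod_ids, cop_ids, sprintf("mrna_bg_%05d", seq_len(n_mbg)))
    base_mrna <- runif(cfg$n_mrna, 4, 10)
    mrna <- matrix(rnorm(cfg$n_mrna * n, sd = cfg$noise_sd), cfg$n_mrna, n) + base_mrna
    dimnames(mrna) <- list(mrna_ids, sample_id)

    # module genes correlated with the anchor lncRNA (enrichment phenotype)
    if (cfg$n_module > 0) {
      z_anchor <- as.numeric(scale(lnc["lnc_prog_anchor", ]))
      a <- cfg$module_r
      for (g in mod_ids) {
        mrna[g, ] <- base_mrna[match(g, mrna_ids)] +
          cfg$noise_sd * (a * z_anchor + sqrt(1 - a^2) * rnorm(n))
      }
    }

    ## ---- miRNA features ---------------------------------------------
    msp_ids <- if (cfg$n_sponge > 0) sprintf("mir_sponge_%02d", seq_len(cfg$n_sponge)) else character(0)
    mirna_ids <- c(msp_ids, sprintf("mir_bg_%03d", seq_len(cfg$n_mirna - length(msp_ids))))
    base_mir <- runif(cfg$n_mirna, 2, 8)
    mirna <- matrix(rnorm(cfg$n_mirna * n, sd = cfg$noise_sd), cfg$n_mirna, n) + base_mir
    dimnames(mirna) <- list(mirna_ids, sample_id)

    ## ---- planted correlated pairs -----------------------------------
    pairs <- cfg$corr_pairs
    if (is.null(pairs)) {
      pairs <- dplyr::bind_rows(
        tibble::tibble(lnc = coexpr_ids, partner = cop_ids,
                       partner_type = "mrna", r = cfg$coexpr_r),
        tibble::tibble(lnc = sponge_ids, partner = msp_ids,
                       partner_type = "mirna", r = cfg$sponge_r)
      )
    } else if (!"partner" %in% names(pairs) || !"lnc" %in% names(pairs)) {
      rlang::abort("Custom corr_pairs must name `lnc` and `partner` features.")
    }
    if (nrow(pairs)) {
      for (i in seq_len(nrow(pairs))) {
        lp <- latent_pair(n, pairs$r[i])
        li <- pairs$lnc[i]
        pi <- pairs$partner[i]
        lnc[li, ] <- base_lnc[match(li, lnc_ids)] + cfg$noise_sd * lp[, 1]
        if (pairs$partner_type[i] == "mrna") {
          mrna[pi, ] <- base_mrna[match(pi, mrna_ids)] + cfg$noise_sd * lp[, 2]
        } else {
          mirna[pi, ] <- base_mir[match(pi, mirna_ids)] + cfg$noise_sd * lp[, 2]
        }
      }
    }

    ## ---- survival ----------------------------------------------------
    risk_group <- dplyr::case_when(
      !is_cll ~ NA_character_,
      anchor_high == 1 & partner_high == 1 ~ "high",
      anchor_high == 0 & partner_high == 0 ~ "low",
      TRUE ~ "intermediate"
    )
    hr_mult <- dplyr::case_when(
      risk_group == "high" ~ cfg$planted_hr_high,
      risk_group == "intermediate" ~ cfg$planted_hr_intermediate,
      risk_group == "low" ~ 1,
      TRUE ~ NA_real_
    )
    t_event <- rep(NA_real_, n)
    t_event[is_cll] <- rexp(sum(is_cll),
                            rate = cfg$baseline_hazard * hr_mult[is_cll])
    c_rand <- ifelse(runif(n) < cfg$censor_rate,
                     runif(n, 0, cfg$censor_horizon), Inf)
    c_all <- pmin(c_rand, cfg$censor_horizon)
    time <- pmin(t_event, c_all)
    event <- as.integer(t_event <= c_all)
    # follow-up available for n_clinical patients only
    has_clinical <- c(seq_len(cfg$n_patients) <= cfg$n_clinical,
                      rep(FALSE, n_norm))
    time[!has_clinical] <- NA_real_
    event[!has_clinical] <- NA_integer_
    time[has_clinical] <- pmax(time[has_clinical], 1e-6)

    samples <- dplyr::bind_cols(
      tibble::tibble(sample_id = sample_id, group = group, subtype = subtype),
      markers,
      tibble::tibble(time = time, event = event)
    )

    ## ---- sequences with planted duplex sites ------------------------
    seqs <- NULL
    duplex_sites <- tibble::tibble(lnc = character(), mirna = character(),
                                   from = integer(), to = integer())
    if (isTRUE(sequences) && cfg$n_sponge > 0) {
      fx <- generate_sequence_fixture(
        n_lnc = cfg$n_sponge * 2L, n_mir = cfg$n_mirna,
        planted_sites = cfg$n_sponge,
        seed = cfg$seed + 1031L
      )
      # rename to match the planted expression features: site i sits in
      # fixture lnc i / mir i, mapped onto sponge pair i
      lnc_names <- names(fx$lnc)
      lnc_names[seq_len(cfg$n_sponge)] <- sponge_ids
      lnc_names[-seq_len(cfg$n_sponge)] <-
        sprintf("lnc_bg_%04d", seq_len(cfg$n_sponge))
      names(fx$lnc) <- lnc_names
      mir_names <- names(fx$mir)
      mir_names[seq_len(cfg$n_sponge)] <- msp_ids
      mir_names[-seq_len(cfg$n_sponge)] <-
        mirna_ids[!mirna_ids %in% msp_ids][seq_len(cfg$n_mirna - cfg$n_sponge)]
      names(fx$mir) <- mir_names
      seqs <- list(lnc = fx$lnc, mir = fx$mir)
      # fixture site i was planted in fixture lnc i against fixture mir i
      duplex_sites <- fx$truth
      duplex_sites$lnc <- sponge_ids[seq_len(nrow(duplex_sites))]
      duplex_sites$mirna <- msp_ids[seq_len(nrow(duplex_sites))]
    }

    truth <- list(
      signature = tibble::tibble(
        feature = sig_ids,
        direction = ifelse(sig_dir > 0, "up", "down")
      ),
      subtype_markers = tibble::tibble(
        feature = sub_ids,
        subtype = rep(subtypes, each = cfg$subtype_markers)
      ),
      prognostic = tibble::tibble(
        feature = prog_ids, role = c("anchor", "partner")
      ),
      risk_groups = tibble::tibble(
        sample_id = sample_id[is_cll], group = risk_group[is_cll]
      ),
      planted_hr = c(high = cfg$planted_hr_high,
                     intermediate = cfg$planted_hr_intermediate),
      high_status = tibble::tibble(
        sample_id = sample_id,
        anchor_high = anchor_high, partner_high = partner_high
      ),
      corr_pairs = pairs,
      module = tibble::tibble(feature = mod_ids),
      duplex_sites = duplex_sites
    )

    structure(
      list(lnc_expr = lnc, mrna_expr = mrna, mirna_expr = mirna,
           samples = samples, sequences = seqs, truth = truth,
           config = cfg),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  samples : %d (%d CLL, %d normal)\n", ncol(x$lnc_expr),
              sum(x$samples$group == "CLL"), sum(x$samples$group == "normal")))
  cat(sprintf("  features: %d lncRNA, %d mRNA, %d miRNA\n",
              nrow(x$lnc_expr), nrow(x$mrna_expr), nrow(x$mirna_expr)))
  cat(sprintf("  planted : %d-feature signature, HRs %.2f/%.2f, %d corr pairs\n",
              nrow(x$truth$signature), x$truth$planted_hr[["high"]],
              x$truth$planted_hr[["intermediate"]], nrow(x$truth$corr_pairs)))
  invisible(x)
}

#' Survival records of a synthetic cohort
#'
#' Convenience accessor returning the patients with clinical follow-up as a
#' survival table suitable for the survival / risk-model layers.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble with `sample_id`, `time`, `event` and marker covariates.
#' @export
cohort_survival <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- dplyr::filter(cohort$samples, !is.na(.data$time))
  dplyr::select(out, "sample_id", "time", "event", dplyr::everything(),
                -"group", -"subtype")
}

#' Generate a probe/transcript interval fixture with overlap truth
#'
#' Random probe and transcript intervals over a small genome, with the true
#' probe-to-transcript assignment recorded by exhaustive all-pairs interval
#' overlap. Transcripts mix lncRNA, coding and other biotypes and both
#' strands, so sense/antisense overlap cases are represented; some probes
#' fall in no transcript, some in several.
#'
#' @param n_probes,n_transcripts Numbers of records (>= 1).
#' @param seed Integer RNG seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length (bp).
#' @param probe_len Probe length (bp).
#' @return List with `probes`, `transcripts` (interval tibbles, 0-based
#'   half-open) and `truth` (tibble `probe_id`, `transcript_id`,
#'   `overlap_bp`, `same_strand`; probes with no overlap are absent).
#' @export
generate_interval_fixture <- function(n_probes, n_transcripts, seed = 1L,
                                      n_chrom = 3L, chrom_len = 100000L,
                                      probe_len = 25L) {
  n_probes <- tryCatch(check_count(n_probes, "n_probes"),
                       error = function(e) rlang::abort("Invalid config: n_probes must be >= 1."))
  n_transcripts <- tryCatch(check_count(n_transcripts, "n_transcripts"),
                            error = function(e) rlang::abort("Invalid config: n_transcripts must be >= 1."))
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    tx_start <- sample.int(chrom_len - 5000L, n_transcripts, replace = TRUE)
    transcripts <- tibble::tibble(
      transcript_id = sprintf("tx_%03d", seq_len(n_transcripts)),
      chrom = sample(chroms, n_transcripts, replace = TRUE),
      start = tx_start,
      end = tx_start + sample(500:5000, n_transcripts, replace = TRUE),
      strand = sample(c("+", "-"), n_transcripts, replace = TRUE),
      biotype = sample(c("lncRNA", "coding", "other"), n_transcripts,
                       replace = TRUE, prob = c(0.5, 0.35, 0.15)),
      alias = NA_character_
    )
    # Half the probes are dropped inside a random transcript (either strand,
    # to create antisense overlap), the rest land uniformly at random.
    inside <- runif(n_probes) < 0.5
    tx_pick <- sample.int(n_transcripts, n_probes, replace = TRUE)
    p_start <- integer(n_probes)
    p_chrom <- character(n_probes)
    for (i in seq_len(n_probes)) {
      if (inside[i]) {
        tx <- transcripts[tx_pick[i], ]
        lo <- tx$start
        hi <- max(tx$start, tx$end - probe_len)
        p_start[i] <- if (hi > lo) sample(lo:hi, 1L) else lo
        p_chrom[i] <- tx$chrom
      } else {
        p_start[i] <- sample.int(chrom_len - probe_len, 1L)
        p_chrom[i] <- sample(chroms, 1L)
      }
    }
    probes <- tibble::tibble(
      probe_id = sprintf("probe_%04d", seq_len(n_probes)),
      chrom = p_chrom,
      start = p_start,
      end = p_start + probe_len,
      strand = sample(c("+", "-"), n_probes, replace = TRUE)
    )
    # truth by exhaustive all-pairs overlap
    truth <- list()
    for (i in seq_len(n_probes)) {
      for (j in seq_len(n_transcripts)) {
        if (probes$chrom[i] != transcripts$chrom[j]) next
        ov <- min(probes$end[i], transcripts$end[j]) -
          max(probes$start[i], transcripts$start[j])
        if (ov >= 1) {
          truth[[length(truth) + 1L]] <- tibble::tibble(
            probe_id = probes$probe_id[i],
            transcript_id = transcripts$transcript_id[j],
            overlap_bp = as.integer(ov),
            same_strand = probes$strand[i] == transcripts$strand[j]
          )
        }
      }
    }
    truth <- if (length(truth)) dplyr::bind_rows(truth) else {
      tibble::tibble(probe_id = character(), transcript_id = character(),
                     overlap_bp = integer(), same_strand = logical())
    }
    list(probes = probes, transcripts = transcripts, truth = truth)
  })
}

#' Generate lncRNA / miRNA sequences with planted duplex sites
#'
#' Random RNA sequences in which `planted_sites` windows of the lncRNAs are
#' replaced by the full reverse complement of a miRNA, so each planted site
#' satisfies the duplex filter by construction (perfect seed, all bases
#' paired, strongly negative stacking energy); each planted site is verified
#' against [duplex_predict()] before the fixture is returned. Site `i` is
#' planted in lncRNA `i` against miRNA `i` (indices recycled).
#'
#' @param n_lnc,n_mir Sequence counts.
#' @param planted_sites Number of planted sites (0 for background only).
#' @param seed Integer RNG seed.
#' @param lnc_len,mir_len Sequence lengths (nt); `lnc_len` must be at least
#'   `mir_len`.
#' @return List with `lnc`, `mir` (named RNA character vectors) and `truth`
#'   (tibble `lnc`, `mirna`, `from`, `to`, 1-based inclusive windows).
#' @export
generate_sequence_fixture <- function(n_lnc, n_mir, planted_sites = 0L,
                                      seed = 1L, lnc_len = 500L, mir_len = 22L) {
  n_lnc <- check_count(n_lnc, "n_lnc")
  n_mir <- check_count(n_mir, "n_mir")
  planted_sites <- check_count(planted_sites, "planted_sites", min = 0L)
  if (lnc_len < mir_len) {
    rlang::abort("lncRNA length must be >= miRNA (site) length.")
  }
  with_seed(seed, {
    alph <- c("A", "C", "G", "U")
    rand_seq <- function(len) paste(sample(alph, len, replace = TRUE), collapse = "")
    lnc <- setNames(vapply(seq_len(n_lnc), function(i) rand_seq(lnc_len),
                           character(1)),
                    sprintf("lncfx_%03d", seq_len(n_lnc)))
    mir <- setNames(vapply(seq_len(n_mir), function(i) rand_seq(mir_len),
                           character(1)),
                    sprintf("mirfx_%03d", seq_len(n_mir)))
    truth <- tibble::tibble(lnc = character(), mirna = character(),
                            from = integer(), to = integer())
    if (planted_sites > 0) {
      for (s in seq_len(planted_sites)) {
        li <- ((s - 1L) %% n_lnc) + 1L
        mi <- ((s - 1L) %% n_mir) + 1L
        site <- rna_revcomp(mir[[mi]])
        from <- sample.int(lnc_len - mir_len + 1L, 1L)
        to <- from + mir_len - 1L
        chars <- strsplit(lnc[[li]], "")[[1]]
        chars[from:to] <- strsplit(site, "")[[1]]
        lnc[[li]] <- paste(chars, collapse = "")
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          lnc = names(lnc)[li], mirna = names(mir)[mi],
          from = as.integer(from), to = as.integer(to)
        ))
      }
      # construction check: every planted window must be reported as a hit
      for (s in seq_len(nrow(truth))) {
        hits <- duplex_predict(lnc[[truth$lnc[s]]], mir[[truth$mirna[s]]])
        cover <- nrow(hits) > 0 &&
          any(hits$from <= truth$from[s] & hits$to >= truth$from[s])
        if (!cover) {
          rlang::abort("Internal error: planted duplex site fails its own filter.")
        }
      }
    }
    list(lnc = lnc, mir = mir, truth = truth)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Exports the expression matrices (TSV), sample annotation (TSV), sequences
#' (FASTA) and ground truth (JSON) of a [generate_cohort()] result.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expr_tsv(cohort$lnc_expr, file.path(dir, "lnc_expr.tsv"))
  write_expr_tsv(cohort$mrna_expr, file.path(dir, "mrna_expr.tsv"))
  write_expr_tsv(cohort$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  write_samples_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$sequences)) {
    write_fasta(cohort$sequences$lnc, file.path(dir, "lnc.fa"))
    write_fasta(cohort$sequences$mir, file.path(dir, "mir.fa"))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
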