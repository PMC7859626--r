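# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# negative-binomial counts with subject-specific sequencing depth, pathway
# gene blocks sharing a latent factor, planted outcome-associated genes with
# modest fold changes, gestational age over 23-41 weeks with an extremely
# preterm subgroup, BPD restricted to that subgroup, PRD risk increasing as
# gestational age decreases, and oxygen traces that worsen with prematurity
# and BPD. Identical config + seed gives byte-identical output.

#' Simulation configuration
#'
#' Defaults mirror the cohort the pipeline is designed for: ~13,500 genes
#' by 145 subjects, gestational age at birth (GAB) 23-41 weeks with roughly
#' half the cohort born before 29 weeks, BPD prevalence 34/72 among the
#' <29-week subgroup, PRD prevalence 70/116 with 14/130 missing PRD status,
#' and planted outcome-associated genes with fold changes below 2.
#'
#' @param n_subjects,n_genes cohort dimensions.
#' @param n_pathways number of (disjoint) pathway gene blocks.
#' @param genes_per_pathway length-2 range of block sizes.
#' @param depth_lognormal_params `c(mu, sigma)` of the log-normal
#'   subject depth multiplier.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param frac_signal_genes fraction of (non-pathway) genes carrying the
#'   planted outcome effect.
#' @param signal_log2fc planted log2 fold change in outcome-positive
#'   subjects.
#' @param n_signal_pathways number of pathway blocks whose genes all carry
#'   the planted effect.
#' @param signal_outcome `"bpd"` or `"prd"`: which outcome the planted genes
#'   track.
#' @param within_pathway_correlation target pairwise correlation of genes
#'   within a pathway block, in \[0, 1).
#' @param gab_range_weeks `c(min, max)` gestational age at birth, weeks.
#' @param bpd_prevalence_lt29 BPD prevalence among subjects born <29 weeks.
#' @param prd_prevalence marginal PRD prevalence among subjects with
#'   non-missing PRD.
#' @param prd_missing_rate fraction of subjects with missing PRD status.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 145, n_genes = 13500,
                              n_pathways = 40, genes_per_pathway = c(8, 25),
                              depth_lognormal_params = c(mu = 0, sigma = 0.35),
                              nb_dispersion = 0.3,
                              frac_signal_genes = 0.004, signal_log2fc = 0.75,
                              n_signal_pathways = 1, signal_outcome = "bpd",
                              within_pathway_correlation = 0.5,
                              gab_range_weeks = c(23, 41),
                              bpd_prevalence_lt29 = 34 / 72,
                              prd_prevalence = 70 / 116,
                              prd_missing_rate = 14 / 130,
                              seed = 1L) {
  stopifnot(
    n_subjects >= 4, n_genes >= 1, n_pathways >= 0,
    length(genes_per_pathway) == 2, genes_per_pathway[1] >= 1,
    genes_per_pathway[2] >= genes_per_pathway[1],
    nb_dispersion > 0,
    frac_signal_genes >= 0, frac_signal_genes <= 1,
    within_pathway_correlation >= 0, within_pathway_correlation < 1,
    length(gab_range_weeks) == 2,
    gab_range_weeks[1] >= 22, gab_range_weeks[2] <= 42,
    gab_range_weeks[1] < gab_range_weeks[2],
    bpd_prevalence_lt29 >= 0, bpd_prevalence_lt29 <= 1,
    prd_prevalence >= 0, prd_prevalence <= 1,
    prd_missing_rate >= 0, prd_missing_rate <= 1,
    signal_outcome %in% c("bpd", "prd")
  )
  if (round(frac_signal_genes * n_genes) + n_pathways * genes_per_pathway[2] > n_genes) {
    stop("signal genes plus pathway blocks exceed the total number of genes")
  }
  cf <- mget(names(formals(simulation_config)))
  structure(cf, class = "sim_config")
}

# Calibrate a logistic intercept so that mean(plogis(a + offset)) == target.
calibrate_intercept <- function(offset, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(a) mean(stats::plogis(a + offset)) - target,
          interval = c(-30, 30))$root
}

#' Simulate an oxygen exposure trace
#'
#' Daily noon FiO2 over 28 days follows a declining-exponential severity
#' trajectory floored at room air: more premature infants (lower GAB) and
#' BPD cases start higher and wean more slowly. Support mode, cannula flow,
#' and pressure are derived from the daily target effective FiO2. A term
#' infant without BPD yields a flat room-air trace.
#'
#' @param gab_weeks gestational age at birth (weeks).
#' @param bpd_label logical: BPD case.
#' @param seed integer seed (the trace is a pure function of its arguments).
#' @param subject_id identifier stored on the trace.
#' @param birth_weight_g birth weight; default derived from GAB.
#' @param n_days number of daily records (default 28).
#' @return an [oxygen_trace()].
#' @export
simulate_oxygen_trace <- function(gab_weeks, bpd_label, seed,
                                  subject_id = "S1", birth_weight_g = NULL,
                                  n_days = 28) {
  stopifnot(gab_weeks >= 22, gab_weeks <= 42)
  with_seed(seed, {
    if (is.null(birth_weight_g)) {
      birth_weight_g <- max(400, round(187 * gab_weeks - 4000 + rnorm(1, 0, 150)))
    }
    sev <- max(0, (32 - gab_weeks) / 9)          # 0 at >=32 wk, ~1 at 23 wk
    peak <- 0.6 * sev + 0.15 * as.numeric(bpd_label) * (sev > 0)
    tau <- 4 + 2 * sev + 8 * as.numeric(bpd_label)
    day <- seq_len(n_days)
    excess <- peak * exp(-(day - 1) / tau)
    if (peak > 0) excess <- pmax(0, excess + rnorm(n_days, 0, 0.05 * peak))
    target <- pmin(1, 0.21 + excess)
    mode <- ifelse(excess > 0.25, "vent",
            ifelse(excess > 0.10, "cpap",
            ifelse(excess > 0.02, "low_flow_cannula", "room_air")))
    fio2 <- target
    flow <- numeric(n_days)
    pressure <- ifelse(mode == "vent", 20, ifelse(mode == "cpap", 6, 0))
    lf <- mode == "low_flow_cannula"
    if (any(lf)) {
      # 100% O2 at a flow chosen so the diluted (effective) FiO2 tracks the
      # target excess
      fio2[lf] <- 1.0
      vi <- 0.9 * birth_weight_g / 1000
      flow[lf] <- pmin(2, pmax(0.03125, excess[lf] / 0.79 * vi))
    }
    fio2[mode == "room_air"] <- 0.21
    oxygen_trace(subject_id,
                 data.frame(day = day, fio2 = fio2, support_mode = mode,
                            flow_lpm = flow, pressure_cmH2O = pressure),
                 birth_weight_g = birth_weight_g)
  })
}

#' Simulate a synthetic cohort
#'
#' See [simulation_config()] for the generative model knobs. Counts are
#' drawn gene-wise from a negative binomial with per-subject log-normal
#' depth multipliers. Pathway blocks share a subject-level latent factor
#' whose loading is calibrated (against the NB sampling noise) so that the
#' observed pairwise correlation within a block approximates
#' `within_pathway_correlation`. Planted signal genes have their mean
#' multiplied by `2^signal_log2fc` in outcome-positive subjects. BPD is
#' assigned only below 29 weeks GAB; PRD risk follows a logistic decreasing
#' in GAB with the intercept calibrated to the configured marginal
#' prevalence.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `counts`
#'   (a [count_matrix()]), `subjects` (metadata data.frame), `traces`
#'   (list of [oxygen_trace()]), `gene_sets`, and `truth` (planted-signal
#'   record, versioned).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_subjects
    subject_id <- sprintf("S%03d", seq_len(n))
    gene_id <- sprintf("G%05d", seq_len(cf$n_genes))

    # --- demographics -------------------------------------------------------
    lo <- cf$gab_range_weeks[1]; hi <- cf$gab_range_weeks[2]
    if (hi > 29 && lo < 29) {
      lt29 <- runif(n) < 0.5
      gab <- ifelse(lt29, runif(n, lo, 29), runif(n, 29, hi))
    } else {
      gab <- runif(n, lo, hi)
    }
    sex <- sample(c("M", "F"), n, replace = TRUE)
    race <- sample(c("white", "black", "other"), n, replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
    bw <- pmax(400, round(187 * gab - 4000 + rnorm(n, 0, 150)))

    # --- outcomes -----------------------------------------------------------
    is_lt29 <- gab < 29
    bpd <- rep(FALSE, n)
    if (any(is_lt29) && cf$bpd_prevalence_lt29 > 0) {
      off <- 0.4 * (26.5 - gab[is_lt29])      # risk rises as GAB falls
      a <- calibrate_intercept(off, cf$bpd_prevalence_lt29)
      bpd[is_lt29] <- runif(sum(is_lt29)) < stats::plogis(a + off)
    }
    prd_off <- 0.25 * (30 - gab)
    a_prd <- calibrate_intercept(prd_off, cf$prd_prevalence)
    prd <- runif(n) < stats::plogis(a_prd + prd_off)
    prd_missing <- runif(n) < cf$prd_missing_rate

    # BPD-by-challenge mostly agrees with the birth-weight criterion
    bpd_rac <- bpd
    flip <- is_lt29 & (runif(n) < 0.15)
    bpd_rac[flip] <- !bpd_rac[flip]

    # --- gene architecture --------------------------------------------------
    base_mean <- rlnorm(cf$n_genes, meanlog = log(60), sdlog = 1.3)
    disp <- cf$nb_dispersion
    depth <- rlnorm(n, cf$depth_lognormal_params[1], cf$depth_lognormal_params[2])

    pw_sizes <- if (cf$n_pathways > 0) {
      sample(seq(cf$genes_per_pathway[1], cf$genes_per_pathway[2]),
             cf$n_pathways, replace = TRUE)
    } else integer(0)
    pw_end <- cumsum(pw_sizes)
    pw_start <- c(1L, head(pw_end, -1) + 1L)
    sets <- if (cf$n_pathways > 0) {
      stats::setNames(lapply(seq_len(cf$n_pathways), function(p) {
        gene_id[pw_start[p]:pw_end[p]]
      }), sprintf("PW%03d", seq_len(cf$n_pathways)))
    } else list()
    pathway_of <- integer(cf$n_genes)
    for (p in seq_len(cf$n_pathways)) pathway_of[pw_start[p]:pw_end[p]] <- p

    n_sig <- round(cf$frac_signal_genes * cf$n_genes)
    free_genes <- which(pathway_of == 0)
    signal_genes <- if (n_sig > 0) sort(sample(free_genes, n_sig)) else integer(0)
    signal_pathways <- seq_len(min(cf$n_signal_pathways, cf$n_pathways))
    sig_idx <- union(signal_genes,
                     which(pathway_of %in% signal_pathways))

    outcome_pos <- if (cf$signal_outcome == "bpd") bpd else prd

    # --- mean matrix and counts --------------------------------------------
    log_mu <- matrix(log(base_mean), cf$n_genes, n) +
      matrix(log(depth), cf$n_genes, n, byrow = TRUE)

    rho <- cf$within_pathway_correlation
    if (cf$n_pathways > 0 && rho > 0) {
      z <- matrix(rnorm(cf$n_pathways * n), cf$n_pathways, n)
      # latent loading calibrated per gene so the shared-factor variance is
      # rho/(1-rho) times the NB sampling variance on the log scale
      v_nb <- log(1 + disp + 1 / base_mean)
      tau <- sqrt(rho / (1 - rho) * v_nb)
      in_pw <- pathway_of > 0
      log_mu[in_pw, ] <- log_mu[in_pw, ] +
        tau[in_pw] * z[pathway_of[in_pw], , drop = FALSE] -
        tau[in_pw]^2 / 2
    }
    if (length(sig_idx) > 0 && cf$signal_log2fc != 0 && any(outcome_pos)) {
      log_mu[sig_idx, outcome_pos] <- log_mu[sig_idx, outcome_pos] +
        cf$signal_log2fc * log(2)
    }

    counts <- matrix(
      rnbinom(cf$n_genes * n, size = 1 / disp, mu = exp(log_mu)),
      cf$n_genes, n, dimnames = list(gene_id, subject_id)
    )

    # --- oxygen traces ------------------------------------------------------
    traces <- lapply(seq_len(n), function(i) {
      simulate_oxygen_trace(gab[i], bpd[i], seed = derive_seed(cf$seed, i),
                            subject_id = subject_id[i], birth_weight_g = bw[i])
    })
    names(traces) <- subject_id
    auc14 <- vapply(traces, oxygen_auc, numeric(1), through_day = 14)
    auc28 <- vapply(traces, oxygen_auc, numeric(1), through_day = 28)

    subjects <- data.frame(
      subject_id = subject_id,
      gab_weeks = gab, sex = sex, race = race, birth_weight_g = bw,
      bpd_shennan = ifelse(bw >= 1500, "not-applicable", ifelse(bpd, "yes", "no")),
      bpd_rac = ifelse(is_lt29, ifelse(bpd_rac, "yes", "no"), "no"),
      prd = ifelse(prd_missing, NA_character_, ifelse(prd, "yes", "no")),
      prd_missing = prd_missing,
      oxygen_auc14 = auc14, oxygen_auc28 = auc28,
      stringsAsFactors = FALSE
    )

    truth <- list(
      version = "1.0",
      seed = cf$seed,
      signal_genes = gene_id[sort(sig_idx)],
      planted_free_genes = gene_id[signal_genes],
      signal_pathways = if (length(signal_pathways) > 0 && cf$signal_log2fc != 0)
        sprintf("PW%03d", signal_pathways) else character(0),
      signal_log2fc = cf$signal_log2fc,
      signal_outcome = cf$signal_outcome
    )

    structure(list(
      counts = count_matrix(counts),
      subjects = subjects,
      traces = traces,
      gene_sets = if (length(sets) > 0)
        gene_sets(sets, source = "synthetic") else NULL,
      truth = truth,
      config = cf
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d subjects, %d pathways, %d signal genes\n",
              nrow(x$counts), ncol(x$counts),
              length(x$gene_sets), length(x$truth$signal_genes)))
  invisible(x)
}

#' Write a cohort to disk as plain-text fixtures
#'
#' Emits counts (TSV and MatrixMarket), subject metadata TSV, the oxygen
#' flowsheet TSV, gene sets GMT, the planted-truth record as versioned JSON,
#' and a manifest listing every file with its MD5 checksum.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest (also written as `manifest.json`).
#' @export
write_fixture_set <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)

  write_counts_tsv(cohort$counts, p("counts.tsv"))
  write_counts_mtx(cohort$counts, p("counts"))

  meta <- cohort$subjects
  write.table(meta, p("metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  fs <- do.call(rbind, lapply(cohort$traces, function(tr) {
    cbind(subject_id = tr$subject_id, tr$days)
  }))
  write.table(fs, p("flowsheet.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(cohort$gene_sets)) write_gmt(cohort$gene_sets, p("gene_sets.gmt"))

  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- setdiff(list.files(directory), "manifest.json")
  manifest <- list(
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(p(f))), bytes = file.size(p(f)))
    }),
    n_genes = nrow(cohort$counts), n_subjects = ncol(cohort$counts),
    seed = cohort$config$seed
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param directory fixture directory.
#' @return list with `counts`, `subjects`, `traces`, `gene_sets`, `truth`.
#' @export
read_fixture_set <- function(directory) {
  p <- function(f) file.path(directory, f)
  counts <- read_counts_tsv(p("counts.tsv"))
  subjects <- read.delim(p("metadata.tsv"), stringsAsFactors = FALSE, na.strings = "")
  bw <- stats::setNames(subjects$birth_weight_g, subjects$subject_id)
  traces <- read_flowsheet(p("flowsheet.tsv"), bw)
  gs <- if (file.exists(p("gene_sets.gmt"))) read_gmt(p("gene_sets.gmt")) else NULL
  truth <- if (file.exists(p("truth.json"))) jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(counts = counts, subjects = subjects, traces = traces,
       gene_sets = gs, truth = truth)
}
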