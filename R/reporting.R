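# Pipeline orchestration, run manifests, and qPCR cross-validation.

#' Correlate RNA-seq expression with qPCR measurements
#'
#' Per gene, the Spearman rank correlation between log2 UQ-normalized
#' expression and qPCR expression on the -dCt scale (dCt = Ct_gene -
#' Ct_GAPDH; higher expression means lower Ct, so -dCt orients the
#' correlation positive for agreement — noted in the output header when
#' written). Genes absent from either source are skipped with a warning.
#'
#' @param norm a `uq_norm` object.
#' @param qpcr data.frame with columns `subject_id`, `gene`, `ct_gene`,
#'   `ct_gapdh` (positive Ct values).
#' @param genes genes to test (default: all in `qpcr`).
#' @param alpha validation significance threshold (default 0.05).
#' @return data.frame (`gene`, `n`, `rho`, `p_value`, `validated`).
#' @export
correlate_qpcr <- function(norm, qpcr, genes = unique(qpcr$gene), alpha = 0.05) {
  stopifnot(inherits(norm, "uq_norm"),
            all(c("subject_id", "gene", "ct_gene", "ct_gapdh") %in% names(qpcr)))
  if (any(qpcr$ct_gene <= 0 | qpcr$ct_gapdh <= 0)) stop("Ct values must be positive")
  x <- norm$log2_values
  rows <- lapply(genes, function(g) {
    if (!(g %in% rownames(x)) || !(g %in% qpcr$gene)) {
      warning("gene absent from expression or qPCR data, skipped: ", g)
      return(NULL)
    }
    q <- qpcr[qpcr$gene == g, ]
    common <- intersect(q$subject_id, colnames(x))
    if (length(common) < 5) {
      warning("fewer than 5 overlapping subjects for gene ", g, ", skipped")
      return(NULL)
    }
    q <- q[match(common, q$subject_id), ]
    dct <- q$ct_gene - q$ct_gapdh
    sp <- spearman_cor(x[g, common], -dct)
    data.frame(gene = g, n = length(common), rho = sp$rho,
               p_value = sp$p_value, validated = sp$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0), n = integer(0),
                                      rho = numeric(0), p_value = numeric(0),
                                      validated = logical(0))
  rownames(out) <- NULL
  out
}

#' qPCR group-difference test (Wilcoxon on dCt by outcome)
#'
#' Companion diagnostic: two-sided Wilcoxon rank-sum test of dCt between
#' case and control subjects, per gene.
#'
#' @inheritParams correlate_qpcr
#' @param outcome named logical vector (by subject_id).
#' @return data.frame (`gene`, `p_value`).
#' @export
qpcr_group_test <- function(qpcr, outcome, genes = unique(qpcr$gene)) {
  out <- do.call(rbind, lapply(genes, function(g) {
    q <- qpcr[qpcr$gene == g, ]
    q <- q[q$subject_id %in% names(outcome), ]
    if (nrow(q) < 4) return(NULL)
    dct <- q$ct_gene - q$ct_gapdh
    grp <- outcome[q$subject_id]
    if (length(unique(grp)) < 2) return(NULL)
    p <- wilcoxon_row_p(matrix(dct, 1), as.logical(grp))
    data.frame(gene = g, p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(gene = character(0), p_value = numeric(0))
  rownames(out) <- NULL
  out
}

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  required <- c("recipe", "out_dir", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) stop("pipeline config missing fields: ",
                                paste(missing, collapse = ", "))
  recipes <- c("bpd_spca", "prd_pathways", "oxygen_screen", "samseq", "lrt")
  if (!config$recipe %in% recipes) {
    stop("unknown recipe: ", config$recipe, " (expected one of ",
         paste(recipes, collapse = ", "), ")")
  }
  if (config$recipe == "prd_pathways" && is.null(config$gmt) && is.null(config$cohort)) {
    stop("recipe 'prd_pathways' requires a 'gmt' input")
  }
  if (is.null(config$counts) && is.null(config$cohort)) {
    stop("config must name a 'counts' input (or embed a 'cohort')")
  }
  invisible(config)
}

#' Run the end-to-end pipeline
#'
#' Stages: read inputs -> preprocess (filters + UQ normalization) -> oxygen
#' metrics/outcome labels -> the requested analysis recipe -> artifacts and
#' a run manifest. Config validation happens before any computation.
#'
#' @param config either a YAML file path or a list with fields:
#'   `recipe` (one of `bpd_spca`, `prd_pathways`, `oxygen_screen`,
#'   `samseq`, `lrt`), `out_dir`, `seed`, and inputs — either file paths
#'   (`counts`, `metadata`, `flowsheet`, `gmt`) or an in-memory `cohort`
#'   from [simulate_cohort()]. Optional: `fdr` (default 0.1),
#'   `alpha_grid`, `k_grid`, `outer_folds`, `inner_folds`, `inner_repeats`,
#'   `include_gab`, `plot` (default TRUE).
#' @return list with the analysis `result`, the `manifest`, and output
#'   paths. All artifacts are also written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  fdr <- config$fdr %||% 0.1
  seed <- config$seed

  input_checksums <- list()
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    counts <- cohort$counts
    meta <- cohort$subjects
    traces <- cohort$traces
    sets <- cohort$gene_sets
  } else {
    for (f in c("counts", "metadata", "flowsheet", "gmt")) {
      if (!is.null(config[[f]])) input_checksums[[f]] <- unname(tools::md5sum(config[[f]]))
    }
    counts <- read_counts_tsv(config$counts)
    meta <- read.delim(config$metadata, stringsAsFactors = FALSE, na.strings = "")
    bw <- stats::setNames(meta$birth_weight_g, meta$subject_id)
    traces <- if (!is.null(config$flowsheet)) read_flowsheet(config$flowsheet, bw)
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  }

  # --- preprocess -----------------------------------------------------------
  norm <- preprocess_counts(counts)
  kept <- colnames(norm$log2_values)
  meta <- meta[match(kept, meta$subject_id), ]

  # --- oxygen metrics -------------------------------------------------------
  if (!is.null(traces)) {
    auc14 <- vapply(traces[kept], oxygen_auc, numeric(1), through_day = 14)
    auc28 <- vapply(traces[kept], function(tr)
      oxygen_auc(tr, min(28, max(tr$days$day))), numeric(1))
    meta$oxygen_auc14 <- unname(auc14)
    meta$oxygen_auc28 <- unname(auc28)
  }
  write.table(meta, p("metadata_labeled.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  bpd <- yn_to_logical(meta$bpd_shennan)
  prd <- yn_to_logical(meta$prd)
  lt29 <- meta$gab_weeks < 29

  subset_norm <- function(keep) {
    out <- norm
    out$log2_values <- norm$log2_values[, keep, drop = FALSE]
    out$norm_factors <- norm$norm_factors[keep]
    out$conditional_uq <- norm$conditional_uq[keep]
    out
  }

  result <- switch(config$recipe,
    oxygen_screen = {
      keep <- lt29 & !is.na(meta$oxygen_auc14)
      res <- correlate_oxygen(subset_norm(keep), meta$oxygen_auc14[keep],
                              fdr = fdr,
                              group = if (all(!is.na(bpd[keep]))) bpd[keep])
      write_de_result(res, p("oxygen_screen.tsv"))
      res
    },
    samseq = {
      keep <- lt29 & !is.na(bpd)
      res <- samseq_test(counts[rownames(norm$log2_values), kept[keep]],
                         bpd[keep],
                         n_resamples = config$n_resamples %||% 20,
                         n_perms = config$n_perms %||% 1000,
                         mfdr_threshold = fdr, seed = seed)
      write_de_result(res, p("samseq.tsv"))
      res
    },
    lrt = {
      keep <- lt29 & !is.na(bpd)
      res <- lrt_adjusted(subset_norm(keep), bpd[keep], meta$gab_weeks[keep],
                          fdr = fdr)
      write_de_result(res, p("lrt.tsv"))
      res
    },
    bpd_spca = {
      keep <- lt29 & !is.na(bpd)
      ev <- evaluate_nested(subset_norm(keep), bpd[keep],
                            gab_weeks = meta$gab_weeks[keep],
                            alpha_grid = config$alpha_grid %||% c(0.001, 0.005, 0.01, 0.05, 0.10),
                            outer_folds = config$outer_folds %||% 10,
                            inner_folds = config$inner_folds %||% 10,
                            inner_repeats = config$inner_repeats %||% 3,
                            include_gab = isTRUE(config$include_gab),
                            seed = seed)
      write_roc_result(ev, p("spca_roc.tsv"))
      write_model_json(ev$model, p("spca_model.json"))
      maybe_plot_roc(ev, p("spca_roc.png"), isTRUE(config$plot %||% TRUE))
      ev
    },
    prd_pathways = {
      keep <- !is.na(prd)
      ev <- evaluate_nested_pathways(subset_norm(keep), sets, prd[keep],
                                     gab_weeks = meta$gab_weeks[keep],
                                     alpha_grid = config$alpha_grid %||% c(0.01, 0.05, 0.10),
                                     k_grid = config$k_grid %||% 1:5,
                                     method = config$method %||% "forward",
                                     outer_folds = config$outer_folds %||% 10,
                                     inner_folds = config$inner_folds %||% 10,
                                     inner_repeats = config$inner_repeats %||% 1,
                                     include_gab = isTRUE(config$include_gab),
                                     seed = seed)
      write_roc_result(ev, p("pathway_roc.tsv"))
      write_model_json(ev$model, p("pathway_model.json"))
      write_pathway_table(ev$model, p("pathway_table.tsv"))
      maybe_plot_roc(ev, p("pathway_roc.png"), isTRUE(config$plot %||% TRUE))
      ev
    }
  )

  manifest <- list(
    package_version = as.character(packageVersion("preemiexpr")),
    recipe = config$recipe,
    seed = seed,
    thresholds = list(fdr = fdr),
    config = config[setdiff(names(config), "cohort")],
    input_checksums = input_checksums,
    stages = list(
      input = list(genes = nrow(counts), subjects = ncol(counts)),
      preprocess = norm$filter_report[c("output_genes", "output_subjects")]
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(result = result, manifest = manifest, out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ROC points (held-out, naive, and any baseline) as TSV
#' @param ev a `roc_result`.
#' @param path output TSV.
#' @export
write_roc_result <- function(ev, path) {
  stopifnot(inherits(ev, "roc_result"))
  tab <- rbind(
    cbind(curve = "cv", ev$roc),
    cbind(curve = "naive", ev$naive_roc),
    if (!is.null(ev$baseline_roc)) cbind(curve = "gab_baseline", ev$baseline_roc)
  )
  header <- sprintf("# naive_auc=%.6f cv_auc=%.6f%s", ev$naive_auc, ev$cv_auc,
                    if (!is.null(ev$baseline_auc))
                      sprintf(" gab_baseline_auc=%.6f", ev$baseline_auc) else "")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

write_model_json <- function(model, path) {
  obj <- if (inherits(model, "spca_model")) {
    list(type = "spca", alpha = model$alpha, genes = model$genes,
         pc1_loadings = as.list(model$pc1$loadings),
         coefficients = unname(model$coef),
         include_gab = model$include_gab, seed = model$seed)
  } else {
    list(type = paste0("pathway_", model$method),
         alpha = model$alpha, k = model$k,
         pathways = model$pathways,
         loadings = lapply(model$loadings, as.list),
         coefficients = unname(model$coef),
         gene_or = as.list(model$gene_or),
         include_gab = model$include_gab, seed = model$seed)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

maybe_plot_roc <- function(ev, path, enabled) {
  if (!enabled) return(invisible(NULL))
  tryCatch({
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(1 - ev$roc$specificity, ev$roc$sensitivity, type = "l", lwd = 2,
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("naive AUC = %.2f, CV-AUC = %.2f",
                        ev$naive_auc, ev$cv_auc))
    graphics::lines(1 - ev$naive_roc$specificity, ev$naive_roc$sensitivity,
                    lty = 2)
    if (!is.null(ev$baseline_roc)) {
      graphics::lines(1 - ev$baseline_roc$specificity,
                      ev$baseline_roc$sensitivity, lty = 3)
    }
    graphics::abline(0, 1, col = "grey")
    graphics::legend("bottomright",
                     legend = c("nested CV", "naive (in-sample)",
                                if (!is.null(ev$baseline_roc)) "GAB only"),
                     lty = 1:3, bty = "n")
  }, error = function(e) message("ROC plot skipped: ", conditionMessage(e)))
  invisible(path)
}
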