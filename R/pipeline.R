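# End-to-end orchestration: read stage inputs, run every stage with the
# configured thresholds, write stage TSVs plus a JSON summary and run log.

#' Read per-run identification tables from one TSV
#'
#' @param path TSV with columns accession, run_id, unused_score,
#'   n_unique_peptides_conf, coverage, is_decoy.
#' @param decoy_prefix accessions with this prefix are forced to decoy
#'   status (default "DECOY_").
#' @return list of per-run data.frames, ordered by run id.
#' @export
read_identification_tables <- function(path, decoy_prefix = "DECOY_") {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab$is_decoy <- as.logical(tab$is_decoy) |
    startsWith(tab$accession, decoy_prefix)
  split(tab, tab$run_id)
}

#' Read long-format iTRAQ ratios into per-run matrices
#'
#' @param path TSV with columns accession, run_id, channel, ratio.
#' @param design a [channel_design()].
#' @return list of accession x channel matrices, ordered by run id.
#' @export
read_quant_long <- function(path, design = channel_design()) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(channel = "character"))
  lapply(split(tab, tab$run_id), function(d) {
    accs <- unique(d$accession)
    m <- matrix(NA_real_, nrow = length(accs), ncol = length(design$channels),
                dimnames = list(accs, design$channels))
    m[cbind(match(d$accession, accs), match(d$channel, design$channels))] <-
      d$ratio
    m
  })
}

#' Pipeline configuration
#'
#' @param inputs named list of input TSV paths (identifications, quant,
#'   annotations, votes, plasma, survival); any may be NULL to skip that
#'   stage. When `simulate` is TRUE they are generated instead.
#' @param simulate generate all inputs with [write_synthetic_inputs()].
#' @param synthetic a [synthetic_config()] used when simulating.
#' @param target_fdr protein-level FDR for the score threshold (default
#'   0.01).
#' @param min_unique_peptides peptide-evidence rule (default 2).
#' @param require_in_n_runs runs in which acceptance must hold (default 1).
#' @param fc_min,alpha enrichment-call thresholds (defaults 2, 0.05).
#' @param up_min,down_max vote-screen thresholds (defaults 15, 1).
#' @param ihc_cutoff IHC positivity cutoff on mean IOD/area (default 0.043).
#' @param design a [channel_design()].
#' @param seed RNG seed for simulation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), simulate = FALSE,
                            synthetic = synthetic_config(seed = seed),
                            target_fdr = 0.01, min_unique_peptides = 2,
                            require_in_n_runs = 1, fc_min = 2, alpha = 0.05,
                            up_min = 15, down_max = 1, ihc_cutoff = 0.043,
                            design = channel_design(), seed = 1L) {
  stopifnot(target_fdr > 0, target_fdr < 1, fc_min >= 1,
            alpha > 0, alpha < 1, up_min >= 1, down_max >= 0,
            ihc_cutoff >= 0, min_unique_peptides >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: target-decoy identification filtering, run merging,
#' per-run iTRAQ enrichment with replicate-consistent calls, localization
#' classification, the vote-count screen, and the biomarker evaluation
#' statistics (median-split log-rank survival comparison and plasma ROC).
#' Stages whose inputs are absent are skipped. Deterministic given the
#' inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for stage TSVs, `summary.json` and `run_log.txt`.
#' @return the summary list, invisibly written as JSON.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs
  if (isTRUE(config$simulate)) {
    sim_dir <- file.path(out_dir, "simulated_inputs")
    paths <- write_synthetic_inputs(config$synthetic, sim_dir)
    inputs <- as.list(paths)
  }
  summary <- list(parameters = list(
    target_fdr = config$target_fdr,
    min_unique_peptides = config$min_unique_peptides,
    require_in_n_runs = config$require_in_n_runs,
    fc_min = config$fc_min, alpha = config$alpha,
    up_min = config$up_min, down_max = config$down_max,
    ihc_cutoff = config$ihc_cutoff, seed = config$seed))
  log_lines <- c(sprintf("pipeline run %s", format(Sys.time())),
                 sprintf("  %s = %s", names(summary$parameters),
                         unlist(summary$parameters)))
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  accepted <- NULL
  quantified <- NULL
  if (!is.null(inputs$identifications)) {
    runs <- read_identification_tables(inputs$identifications)
    thresholds <- vapply(runs, estimate_fdr_threshold, numeric(1),
                         target_fdr = config$target_fdr)
    acc <- accept_proteins(runs, thresholds,
                           min_unique_peptides = config$min_unique_peptides,
                           require_in_n_runs = config$require_in_n_runs)
    accepted <- acc$accepted_accessions
    summary$identification <- list(
      per_run_thresholds = unname(thresholds),
      accepted_count = length(accepted),
      residual_decoys = acc$residual_decoys,
      overall_fdr = acc$overall_fdr)
    log_lines <- c(log_lines, sprintf(
      "identification: %d accepted at thresholds [%s], %d residual decoys",
      length(accepted), paste(signif(thresholds, 4), collapse = ", "),
      acc$residual_decoys))
    if (!is.null(inputs$quant)) {
      qruns <- read_quant_long(inputs$quant, config$design)
      quantified <- lapply(qruns, rownames)
      merged <- merge_runs(runs, quantified = quantified,
                           accessions = accepted)
      wt(merged$catalog, "catalog.tsv")
      summary$identification$quant_partition <-
        as.list(merged$quant_partition)
    }
  }

  if (!is.null(inputs$quant)) {
    qruns <- read_quant_long(inputs$quant, config$design)
    if (!is.null(accepted)) {
      qruns <- lapply(qruns, function(m)
        m[rownames(m) %in% accepted, , drop = FALSE])
    }
    per_run <- lapply(qruns, per_run_enrichment, design = config$design)
    calls <- call_enrichment(per_run, fc_min = config$fc_min,
                             alpha = config$alpha)
    wt(calls, "enrichment_calls.tsv")
    summary$enrichment <- list(
      fibroblast_enriched = sum(calls$call == "fibroblast_enriched"),
      epithelial_enriched = sum(calls$call == "epithelial_enriched"),
      neither = sum(calls$call == "neither"))
    log_lines <- c(log_lines, sprintf(
      "enrichment: %d fibroblast-enriched, %d epithelial-enriched",
      summary$enrichment$fibroblast_enriched,
      summary$enrichment$epithelial_enriched))
  }

  if (!is.null(inputs$annotations)) {
    ann <- utils::read.delim(inputs$annotations, sep = "\t",
                             stringsAsFactors = FALSE)
    calls <- classify_catalog(ann)
    wt(calls, "localization_calls.tsv")
    summ <- summarize_localization(calls)
    ov <- exosome_overlap(calls)
    summary$localization <- list(
      counts = stats::setNames(as.list(summ$count), summ$klass),
      percents = stats::setNames(as.list(summ$percent), summ$klass),
      exosome_overlap = ov$overall)
    log_lines <- c(log_lines, sprintf(
      "localization: %s", paste(summ$klass, summ$count, collapse = ", ")))
  }

  if (!is.null(inputs$votes)) {
    votes <- read_vote_table(inputs$votes)
    scr <- screen_catalog(votes, up_min = config$up_min,
                          down_max = config$down_max)
    wt(scr$calls, "screen_calls.tsv")
    summary$screen <- as.list(scr$counts)
    log_lines <- c(log_lines, sprintf(
      "screen: %d cancer-up, %d cancer-down",
      scr$counts["cancer_up"], scr$counts["cancer_down"]))
  }

  if (!is.null(inputs$survival)) {
    surv <- utils::read.delim(inputs$survival, sep = "\t",
                              stringsAsFactors = FALSE)
    lr <- logrank_test(surv$time_months, surv$event, surv$group)
    km <- lapply(split(surv, surv$group),
                 function(d) km_curve(d$time_months, d$event))
    for (g in names(km)) wt(km[[g]], sprintf("km_%s.tsv", g))
    summary$survival <- list(logrank_statistic = lr$statistic,
                             logrank_df = lr$df, logrank_p = lr$p_value)
    log_lines <- c(log_lines, sprintf("survival: log-rank %.3f (p = %.4g)",
                                      lr$statistic, lr$p_value))
  }

  if (!is.null(inputs$plasma)) {
    pl <- utils::read.delim(inputs$plasma, sep = "\t",
                            stringsAsFactors = FALSE)
    roc <- roc_analysis(pl$concentration_ng_ml, pl$is_case)
    wt(roc$curve, "roc_curve.tsv")
    summary$plasma <- list(auc = roc$auc, cutoff_ng_ml = roc$cutoff,
                           sensitivity = roc$sensitivity,
                           specificity = roc$specificity)
    log_lines <- c(log_lines, sprintf(
      "plasma ROC: AUC %.3f, cutoff %.1f ng/mL (sens %.1f%%, spec %.1f%%)",
      roc$auc, roc$cutoff, 100 * roc$sensitivity, 100 * roc$specificity))
  }

  if (!is.null(inputs$ihc)) {
    ihc <- utils::read.delim(inputs$ihc, sep = "\t", stringsAsFactors = FALSE)
    key <- interaction(ihc$sample, ihc$region, drop = TRUE)
    scored <- do.call(rbind, lapply(split(ihc, key), function(d) {
      s <- ihc_score(d$IOD, d$area, cutoff = config$ihc_cutoff)
      data.frame(sample = d$sample[1], region = d$region[1],
                 intensity = s$intensity, positive = s$positive,
                 stringsAsFactors = FALSE)
    }))
    wt(scored, "ihc_scores.tsv")
    summary$ihc <- lapply(split(scored, scored$region), function(d)
      list(positive = sum(d$positive), negative = sum(!d$positive)))
    log_lines <- c(log_lines, sprintf(
      "ihc: %d sample-regions scored", nrow(scored)))
  }

  summary$schema_version <- "1.0"
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
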