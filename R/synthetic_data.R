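# Synthetic-data generators with planted ground truth for every pipeline
# input: identification tables with decoys, iTRAQ ratio matrices,
# localization annotations, vote tables, plasma concentrations and
# survival records.

#' Synthetic study configuration
#'
#' Bundles every knob of the generators with defaults mirroring the study
#' design the pipeline targets: three LC-MS runs of an 8-plex iTRAQ
#' experiment with five fibroblast and three cancer channels (reference
#' 113), 116 planted fibroblast-enriched and 44 epithelial-enriched
#' proteins, a 53/16/31 secreted/membrane/intracellular localization mix
#' with 95% exosome-catalog membership, and a plasma marker with group
#' means 45.0 (48 controls) and 61.6 ng/mL (42 cases).
#'
#' @param seed integer RNG seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param n_proteins catalog size.
#' @param n_runs number of LC-MS runs.
#' @param fraction_decoy decoy fraction added to each run table.
#' @param id_thresholds planted per-run 1%-FDR score thresholds.
#' @param score_grid score resolution of the identification generator.
#' @param target_fdr FDR level at which the thresholds are planted.
#' @param planted_fibro_enriched,planted_epi_enriched planted counts.
#' @param fc_effect true fibroblast/cancer ratio of planted proteins.
#' @param ratio_cv coefficient of variation of the log-normal ratio noise.
#' @param localization_mix fractions (secreted, plasma_membrane,
#'   intracellular), summing to 1.
#' @param exosome_rate probability a protein appears in exosome catalogs.
#' @param n_genes,vote_up_min,vote_down_max,n_vote_up,n_vote_down vote-table
#'   shape: catalog size, screen thresholds the planted genes satisfy, and
#'   planted counts per direction.
#' @param n_case,n_control,mean_case,mean_control,sd_case,sd_control plasma
#'   two-group model (ng/mL); concentrations are normal truncated at 0.
#' @param n_survival,hazard_ratio,median_months,censor_max survival model:
#'   exponential event times with group-ratio hazards and uniform censoring.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins = 1000L,
                             n_runs = 3L,
                             fraction_decoy = 0.10,
                             id_thresholds = c(2, 1.62, 2.01),
                             score_grid = 0.01,
                             target_fdr = 0.01,
                             planted_fibro_enriched = 116L,
                             planted_epi_enriched = 44L,
                             fc_effect = 8,
                             ratio_cv = 0.2,
                             localization_mix = c(secreted = 0.53,
                                                  plasma_membrane = 0.16,
                                                  intracellular = 0.31),
                             exosome_rate = 0.95,
                             n_genes = 150L,
                             vote_up_min = 15L,
                             vote_down_max = 1L,
                             n_vote_up = 20L,
                             n_vote_down = 8L,
                             n_case = 42L,
                             n_control = 48L,
                             mean_case = 61.6,
                             mean_control = 45.0,
                             sd_case = 12,
                             sd_control = 8,
                             n_survival = 90L,
                             hazard_ratio = 2,
                             median_months = 51,
                             censor_max = 85) {
  if (abs(sum(localization_mix) - 1) > 1e-8) {
    stop("localization_mix must sum to 1")
  }
  if (fraction_decoy < 0 || fraction_decoy > 1) {
    stop("fraction_decoy must lie in [0, 1]")
  }
  if (fc_effect <= 0 || ratio_cv <= 0) stop("effect and CV must be positive")
  if (planted_fibro_enriched + planted_epi_enriched > n_proteins) {
    stop("planted counts exceed catalog size")
  }
  if (n_vote_up + n_vote_down > n_genes) {
    stop("planted vote genes exceed n_genes")
  }
  if (length(id_thresholds) < n_runs) {
    id_thresholds <- rep_len(id_thresholds, n_runs)
  }
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# run generator code under a derived, restorable RNG state so generators
# are pure functions of (cfg, offset)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

round_grid <- function(x, grid) round(x / grid) * grid

#' Generate per-run identification tables with planted FDR thresholds
#'
#' For each run, target scores are drawn on a fixed grid with a block above
#' the planted threshold; decoy scores are drawn from a lower null with
#' exactly enough contamination at and above the threshold that the simple
#' target-decoy estimator's 1%-FDR crossing sits at the planted value.
#' Decoys carry the "DECOY_" accession prefix and mostly single-peptide
#' evidence.
#'
#' @param cfg a [synthetic_config()].
#' @return list: `runs` (list of identification data.frames) and `truth`
#'   (planted thresholds plus, per run, the accession sets passing the
#'   score-and-peptide rule).
#' @export
generate_identifications <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_proteins
    grid <- cfg$score_grid
    accs <- sprintf("P%05d", seq_len(n))
    runs <- vector("list", cfg$n_runs)
    truth_pass <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      tau <- round_grid(cfg$id_thresholds[r], grid)
      n_hi <- round(0.7 * n)
      hi <- sample(accs, n_hi)
      score <- stats::setNames(numeric(n), accs)
      score[hi] <- tau + grid + round_grid(stats::rexp(n_hi, rate = 0.25), grid)
      lo <- setdiff(accs, hi)
      score[lo] <- pmin(round_grid(stats::runif(length(lo), 0.05, tau - grid),
                                   grid), tau - grid)
      peps <- stats::setNames(integer(n), accs)
      peps[hi] <- ifelse(stats::runif(n_hi) < 0.9,
                         2L + stats::rpois(n_hi, 4), 1L)
      peps[lo] <- 1L + stats::rpois(length(lo), 1)

      n_decoy <- round(cfg$fraction_decoy * n)
      drow <- NULL
      if (n_decoy > 0) {
        d_hi <- min(floor(cfg$target_fdr * n_hi), n_decoy)
        d_near <- min(max(3L, ceiling(2 * cfg$target_fdr * n_hi)),
                      n_decoy - d_hi)
        d_lo <- n_decoy - d_hi - d_near
        # one contaminating decoy sits exactly at tau so the planted
        # threshold is itself an observed candidate score
        dscore <- c(
          tau + c(if (d_hi > 0) 0,
                  round_grid(stats::runif(max(0, d_hi - 1), 0, 0.4), grid)),
          rep(tau - grid, d_near),
          pmin(round_grid(stats::runif(d_lo, 0.05, tau - 2 * grid), grid),
               tau - 2 * grid)
        )
        drow <- data.frame(
          accession = sprintf("DECOY_%05d_r%d", seq_len(n_decoy), r),
          run_id = r,
          unused_score = dscore,
          n_unique_peptides_conf =
            ifelse(stats::runif(n_decoy) < 0.85, 1L,
                   2L + stats::rpois(n_decoy, 1)),
          coverage = stats::runif(n_decoy, 0.01, 0.2),
          is_decoy = TRUE, stringsAsFactors = FALSE)
      }
      trow <- data.frame(accession = accs, run_id = r,
                         unused_score = unname(score),
                         n_unique_peptides_conf = unname(peps),
                         coverage = stats::runif(n, 0.02, 0.8),
                         is_decoy = FALSE, stringsAsFactors = FALSE)
      tab <- rbind(trow, drow)
      runs[[r]] <- tab[sample(nrow(tab)), , drop = FALSE]
      rownames(runs[[r]]) <- NULL
      truth_pass[[r]] <- tab$accession[
        tab$unused_score > tau & tab$n_unique_peptides_conf >= 2 &
          !tab$is_decoy]
    }
    list(runs = runs,
         truth = list(thresholds = round_grid(cfg$id_thresholds[seq_len(cfg$n_runs)],
                                              grid),
                      pass_by_run = truth_pass,
                      accessions = accs))
  })
}

#' Generate per-run iTRAQ ratio matrices with planted enrichment
#'
#' Ratios are log-normal around 1 (reference channel identically 1) with
#' coefficient of variation `ratio_cv`. Planted fibroblast-enriched
#' proteins have cancer channels centered at 1/fc_effect in every run;
#' planted epithelial-enriched proteins at fc_effect; the rest are null.
#'
#' @param cfg a [synthetic_config()].
#' @param design a [channel_design()].
#' @return list: `runs` (list of accession x channel matrices) and `truth`
#'   (data.frame accession / true_class).
#' @export
generate_quant <- function(cfg, design = channel_design()) {
  with_seed(cfg$seed + 202L, {
    n <- cfg$n_proteins
    accs <- sprintf("P%05d", seq_len(n))
    n_fib <- cfg$planted_fibro_enriched
    n_epi <- cfg$planted_epi_enriched
    if (n_fib + n_epi > n) stop("planted counts exceed catalog size")
    true_class <- c(rep("fibroblast_enriched", n_fib),
                    rep("epithelial_enriched", n_epi),
                    rep("neither", n - n_fib - n_epi))
    sdlog <- sqrt(log(1 + cfg$ratio_cv^2))
    # cancer-channel log-mean per protein (fibroblast channels stay at 0)
    mu_cancer <- c(rep(-log(cfg$fc_effect), n_fib),
                   rep(log(cfg$fc_effect), n_epi),
                   rep(0, n - n_fib - n_epi))
    runs <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      qm <- matrix(NA_real_, nrow = n, ncol = length(design$channels),
                   dimnames = list(accs, design$channels))
      for (j in seq_along(design$channels)) {
        ch <- design$channels[j]
        if (ch == design$reference) {
          qm[, j] <- 1
        } else if (design$groups[j] == "fibroblast") {
          qm[, j] <- exp(stats::rnorm(n, 0, sdlog))
        } else {
          qm[, j] <- exp(stats::rnorm(n, mu_cancer, sdlog))
        }
      }
      runs[[r]] <- qm
    }
    list(runs = runs,
         truth = data.frame(accession = accs, true_class = true_class,
                            stringsAsFactors = FALSE))
  })
}

#' Generate annotation records consistent with planted localization classes
#'
#' Secreted-class proteins receive secreted-tier annotation terms and/or
#' predictor flags; membrane-class proteins receive membrane-tier terms and
#' no secreted-tier evidence; intracellular proteins receive neutral terms
#' only. Exosome-catalog hits are Bernoulli(exosome_rate) times a positive
#' experiment count, independent of class.
#'
#' @param cfg a [synthetic_config()].
#' @return list: `annotations` data.frame and `truth` (accession /
#'   true_class).
#' @export
generate_annotations <- function(cfg) {
  with_seed(cfg$seed + 303L, {
    n <- cfg$n_proteins
    accs <- sprintf("P%05d", seq_len(n))
    classes <- sample(names(cfg$localization_mix), n, replace = TRUE,
                      prob = cfg$localization_mix)
    sec_terms <- c("secreted", "extracellular region", "extracellular space",
                   "extracellular matrix")
    mem_terms <- c("plasma membrane", "cell membrane", "cell junction")
    neutral <- c("cytoplasm", "nucleus", "cytosol", "mitochondrion")
    cc <- character(n); sigp <- logical(n); ncsec <- logical(n)
    for (i in seq_len(n)) {
      base <- sample(neutral, sample(1:2, 1))
      if (classes[i] == "secreted") {
        mode <- sample(c("term", "signalp", "nonclassical"), 1,
                       prob = c(0.6, 0.3, 0.1))
        if (mode == "term") {
          cc[i] <- paste(c(sample(sec_terms, 1), base), collapse = ";")
        } else {
          cc[i] <- paste(base, collapse = ";")
          if (mode == "signalp") sigp[i] <- TRUE else ncsec[i] <- TRUE
        }
      } else if (classes[i] == "plasma_membrane") {
        cc[i] <- paste(c(sample(mem_terms, 1), base), collapse = ";")
      } else {
        cc[i] <- paste(base, collapse = ";")
      }
    }
    hits <- ifelse(stats::runif(n) < cfg$exosome_rate,
                   1L + stats::rpois(n, 8), 0L)
    list(annotations = data.frame(accession = accs, cc_terms = cc,
                                  has_signal_peptide = sigp,
                                  nonclassical_secreted = ncsec,
                                  exosome_hits = hits,
                                  stringsAsFactors = FALSE),
         truth = data.frame(accession = accs, true_class = classes,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a vote table with planted cancer-up/-down genes
#'
#' Planted up genes draw supporting counts at or above the screen's up_min
#' with at most down_max contradictions; planted down genes mirror them;
#' null genes draw modest counts in both directions.
#'
#' @param cfg a [synthetic_config()].
#' @return list: `votes` data.frame (gene, n_up, n_down, n_total) and
#'   `truth` (gene / true_status).
#' @export
generate_votes <- function(cfg) {
  with_seed(cfg$seed + 404L, {
    n <- cfg$n_genes
    if (cfg$n_vote_up + cfg$n_vote_down > n) stop("planted genes exceed n_genes")
    genes <- sprintf("GENE%04d", seq_len(n))
    status <- c(rep("cancer_up", cfg$n_vote_up),
                rep("cancer_down", cfg$n_vote_down),
                rep("unclassified", n - cfg$n_vote_up - cfg$n_vote_down))
    n_total <- sample(23:27, n, replace = TRUE)
    n_up <- n_down <- integer(n)
    for (i in seq_len(n)) {
      if (status[i] == "cancer_up") {
        n_up[i] <- min(cfg$vote_up_min + stats::rpois(1, 4), n_total[i] - 1)
        n_down[i] <- stats::rbinom(1, 1, 0.3) * cfg$vote_down_max
      } else if (status[i] == "cancer_down") {
        n_down[i] <- min(cfg$vote_up_min + stats::rpois(1, 4), n_total[i] - 1)
        n_up[i] <- stats::rbinom(1, 1, 0.3) * cfg$vote_down_max
      } else {
        repeat {
          n_up[i] <- stats::rbinom(1, n_total[i], 0.15)
          n_down[i] <- stats::rbinom(1, n_total[i] - n_up[i], 0.15)
          # keep nulls genuinely unclassifiable at the design thresholds
          if (n_up[i] < cfg$vote_up_min && n_down[i] < cfg$vote_up_min) break
        }
      }
    }
    list(votes = data.frame(gene = genes, n_up = n_up, n_down = n_down,
                            n_total = n_total, stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, true_status = status,
                            stringsAsFactors = FALSE))
  })
}

#' Generate two-group plasma marker concentrations
#'
#' Normal concentrations truncated at zero around the configured case and
#' control means (defaults 61.6 and 45.0 ng/mL).
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame: id, concentration_ng_ml, is_case.
#' @export
generate_plasma <- function(cfg) {
  with_seed(cfg$seed + 505L, {
    rtnorm <- function(n, mean, sd) {
      x <- stats::rnorm(n, mean, sd)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
      x
    }
    data.frame(
      id = sprintf("S%03d", seq_len(cfg$n_case + cfg$n_control)),
      concentration_ng_ml = c(rtnorm(cfg$n_case, cfg$mean_case, cfg$sd_case),
                              rtnorm(cfg$n_control, cfg$mean_control,
                                     cfg$sd_control)),
      is_case = rep(c(TRUE, FALSE), c(cfg$n_case, cfg$n_control)),
      stringsAsFactors = FALSE)
  })
}

#' Generate right-censored survival records with a planted hazard ratio
#'
#' Exponential event times; the baseline hazard puts the low-risk group's
#' median at `median_months`, the high-risk group's hazard is
#' `hazard_ratio` times larger; censoring times are uniform on
#' (0, censor_max).
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame: id, time_months, event, group ("high"/"low").
#' @export
generate_survival <- function(cfg) {
  with_seed(cfg$seed + 606L, {
    n <- cfg$n_survival
    group <- rep(c("high", "low"), length.out = n)
    lambda0 <- log(2) / cfg$median_months
    lambda <- ifelse(group == "high", lambda0 * cfg$hazard_ratio, lambda0)
    t_event <- stats::rexp(n, lambda)
    t_cens <- stats::runif(n, 0, cfg$censor_max)
    data.frame(id = sprintf("PT%03d", seq_len(n)),
               time_months = pmin(t_event, t_cens),
               event = t_event <= t_cens,
               group = group, stringsAsFactors = FALSE)
  })
}

#' Write every synthetic input as the TSV dialects the pipeline reads
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  ids <- generate_identifications(cfg)
  paths <- c(identifications = wt(do.call(rbind, ids$runs),
                                  "identifications.tsv"))
  q <- generate_quant(cfg)
  long <- do.call(rbind, lapply(seq_along(q$runs), function(r) {
    m <- q$runs[[r]]
    data.frame(accession = rep(rownames(m), ncol(m)),
               run_id = r,
               channel = rep(colnames(m), each = nrow(m)),
               ratio = as.vector(m), stringsAsFactors = FALSE)
  }))
  paths["quant"] <- wt(long[!is.na(long$ratio), ], "quant_ratios.tsv")
  paths["annotations"] <- wt(generate_annotations(cfg)$annotations,
                             "annotations.tsv")
  paths["votes"] <- wt(generate_votes(cfg)$votes, "votes.tsv")
  paths["plasma"] <- wt(generate_plasma(cfg), "plasma.tsv")
  paths["survival"] <- wt(generate_survival(cfg), "survival.tsv")
  invisible(paths)
}
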