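# Per-run fold changes and replicate-consistent enrichment calls from
# 8-plex iTRAQ channel ratios.

#' Construct an iTRAQ channel design
#'
#' Maps reporter channels to samples and to the two biological groups
#' (fibroblast vs cancer epithelium) and names the reference channel whose
#' ratio is identically 1. The default mirrors an 8-plex layout with five
#' fibroblast channels (113-117, reference 113) and three cancer channels
#' (118, 119, 121).
#'
#' @param channels character vector of reporter tags.
#' @param groups character vector (same length), each "fibroblast" or
#'   "cancer".
#' @param reference the reference channel tag; must belong to `channels`.
#' @param samples optional sample names per channel.
#' @return list of class `channel_design`.
#' @export
channel_design <- function(channels = c("113", "114", "115", "116", "117",
                                        "118", "119", "121"),
                           groups = c(rep("fibroblast", 5), rep("cancer", 3)),
                           reference = "113",
                           samples = NULL) {
  channels <- as.character(channels)
  if (length(groups) != length(channels)) {
    stop("groups must align with channels")
  }
  if (!all(groups %in% c("fibroblast", "cancer"))) {
    stop("groups must be 'fibroblast' or 'cancer'")
  }
  if (!reference %in% channels) stop("reference channel not in design")
  if (!all(c("fibroblast", "cancer") %in% groups)) {
    stop("both groups must be represented")
  }
  if (is.null(samples)) samples <- paste0("sample_", channels)
  structure(list(channels = channels, groups = groups,
                 reference = as.character(reference), samples = samples),
            class = "channel_design")
}

#' Two-sample Student's t test
#'
#' Thin wrapper over [stats::t.test()] returning the statistic and p value.
#' Pooled-variance ("Student") by default; Welch available via
#' `var_equal = FALSE`.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param two_tailed logical; two-sided p when TRUE (default).
#' @param var_equal pooled variance when TRUE (default).
#' @return list with `statistic` and `p_value`.
#' @export
two_sample_ttest <- function(a, b, two_tailed = TRUE, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 observations per group")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate constants: identical means give no evidence, else infinite t
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0))
  }
  alt <- if (two_tailed) "two.sided" else "greater"
  res <- stats::t.test(a, b, alternative = alt, var.equal = var_equal)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Validate a per-run quantitation matrix
#'
#' @param qm numeric matrix, proteins x channels, of iTRAQ ratios to the
#'   reference channel; NA marks missing values.
#' @param design a [channel_design()].
#' @keywords internal
validate_quant_matrix <- function(qm, design) {
  if (!is.matrix(qm)) qm <- as.matrix(qm)
  if (is.null(colnames(qm))) stop("quant matrix needs channel column names")
  miss <- setdiff(design$channels, colnames(qm))
  if (length(miss) > 0) {
    stop("quant matrix lacks channels: ", paste(miss, collapse = ", "))
  }
  if (any(qm <= 0, na.rm = TRUE)) stop("iTRAQ ratios must be positive")
  ref <- qm[, design$reference]
  if (any(abs(ref[!is.na(ref)] - 1) > 1e-8)) {
    stop("reference channel ratios must equal 1")
  }
  qm[, design$channels, drop = FALSE]
}

#' Per-run enrichment statistics from one iTRAQ run
#'
#' For every protein, averages the ratios of the fibroblast channels and the
#' cancer channels and reports their ratio as the fold change
#' (fibroblast/cancer), plus a two-sample Student's t test p value comparing
#' the two channel sets. The test runs on log2 ratios by default since
#' isobaric ratios are multiplicative; the fold change itself always uses
#' raw ratio means. The reference channel's constant ratio of 1 is a member
#' of its group's sample set. Proteins with fewer than 2 usable ratios in
#' either group are returned with NA and flagged unquantifiable.
#'
#' The statistics are computed vectorized over proteins with the classical
#' pooled-variance formulas; they agree with [two_sample_ttest()] row by
#' row.
#'
#' @param qm proteins x channels ratio matrix (rownames = accessions).
#' @param design a [channel_design()].
#' @param log_scale test on log2 ratios (default TRUE).
#' @param var_equal pooled variance (default TRUE).
#' @return data.frame: accession, fc, p_value, quantifiable.
#' @export
per_run_enrichment <- function(qm, design, log_scale = TRUE,
                               var_equal = TRUE) {
  qm <- validate_quant_matrix(qm, design)
  fib <- qm[, design$channels[design$groups == "fibroblast"], drop = FALSE]
  can <- qm[, design$channels[design$groups == "cancer"], drop = FALSE]
  n_f <- rowSums(!is.na(fib))
  n_c <- rowSums(!is.na(can))
  ok <- n_f >= 2 & n_c >= 2
  fc <- rowMeans(fib, na.rm = TRUE) / rowMeans(can, na.rm = TRUE)

  tf <- if (log_scale) log2(fib) else fib
  tc <- if (log_scale) log2(can) else can
  mf <- rowMeans(tf, na.rm = TRUE)
  mc <- rowMeans(tc, na.rm = TRUE)
  vf <- apply(tf, 1, stats::var, na.rm = TRUE)
  vc <- apply(tc, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((n_f - 1) * vf + (n_c - 1) * vc) / (n_f + n_c - 2)
    se <- sqrt(sp2 * (1 / n_f + 1 / n_c))
    df <- n_f + n_c - 2
  } else {
    se <- sqrt(vf / n_f + vc / n_c)
    df <- (vf / n_f + vc / n_c)^2 /
      ((vf / n_f)^2 / (n_f - 1) + (vc / n_c)^2 / (n_c - 1))
  }
  tstat <- (mf - mc) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero pooled variance: identical constants => p = 1, else p -> 0
  degen <- ok & !is.na(se) & se == 0
  p[degen] <- ifelse(abs(mf[degen] - mc[degen]) < 1e-12, 1, 0)
  fc[!ok] <- NA_real_
  p[!ok] <- NA_real_
  data.frame(accession = rownames(qm) %||% as.character(seq_len(nrow(qm))),
             fc = unname(fc), p_value = unname(p),
             quantifiable = unname(ok),
             stringsAsFactors = FALSE)
}

#' Replicate-consistent enrichment calls across runs
#'
#' A protein is called fibroblast-enriched when its fold change is at least
#' `fc_min` with p below `alpha` in every run (or in at least one run when
#' `require_all = FALSE`); epithelial-enriched symmetrically with fold
#' change at most `1/fc_min`. The reported average fold change is the
#' arithmetic mean of per-run fold changes (fibroblast/cancer orientation)
#' over the runs where it is defined. An accession unquantifiable in any
#' run cannot be called enriched when `require_all` is TRUE.
#'
#' @param per_run_list list of data.frames from [per_run_enrichment()], one
#'   per run, covering the same accessions.
#' @param fc_min minimum fold change (default 2).
#' @param alpha significance level (default 0.05).
#' @param require_all demand the rule in all runs (default TRUE).
#' @return data.frame: accession, average_fc, call in
#'   {fibroblast_enriched, epithelial_enriched, neither}, plus per-run
#'   fc_run_<r> / p_run_<r> columns.
#' @export
call_enrichment <- function(per_run_list, fc_min = 2, alpha = 0.05,
                            require_all = TRUE) {
  if (length(per_run_list) < 1) stop("need at least one run")
  accs <- per_run_list[[1]]$accession
  for (d in per_run_list) {
    if (nrow(d) != length(accs) || !setequal(d$accession, accs)) {
      stop("runs cover inconsistent accession sets")
    }
  }
  R <- length(per_run_list)
  fc <- vapply(per_run_list,
               function(d) d$fc[match(accs, d$accession)], numeric(length(accs)))
  p <- vapply(per_run_list,
              function(d) d$p_value[match(accs, d$accession)],
              numeric(length(accs)))
  fc <- matrix(fc, ncol = R); p <- matrix(p, ncol = R)

  fib_run <- !is.na(fc) & !is.na(p) & fc >= fc_min & p < alpha
  epi_run <- !is.na(fc) & !is.na(p) & fc <= 1 / fc_min & p < alpha
  if (require_all) {
    fib <- rowSums(fib_run) == R & rowSums(is.na(fc)) == 0
    epi <- rowSums(epi_run) == R & rowSums(is.na(fc)) == 0
  } else {
    fib <- rowSums(fib_run) >= 1
    epi <- rowSums(epi_run) >= 1
  }
  call <- ifelse(fib, "fibroblast_enriched",
                 ifelse(epi, "epithelial_enriched", "neither"))
  out <- data.frame(accession = accs,
                    average_fc = rowMeans(fc, na.rm = TRUE),
                    call = call, stringsAsFactors = FALSE)
  out$average_fc[!is.finite(out$average_fc)] <- NA_real_
  for (r in seq_len(R)) {
    out[[paste0("fc_run_", r)]] <- fc[, r]
    out[[paste0("p_run_", r)]] <- p[, r]
  }
  out
}
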