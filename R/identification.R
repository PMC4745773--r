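# Target-decoy acceptance of proteins from per-run identification tables.

#' Validate a per-run identification table
#'
#' An identification table holds one row per protein per LC-MS run with the
#' protein-level confidence score ("unused score"), the number of distinct
#' peptides identified at the configured confidence level, sequence coverage
#' and a decoy flag.
#'
#' @param records data.frame with columns `accession`, `run_id`,
#'   `unused_score`, `n_unique_peptides_conf`, `coverage`, `is_decoy`.
#' @return the validated data.frame (invisibly coerced types).
#' @keywords internal
validate_id_records <- function(records) {
  required <- c("accession", "run_id", "unused_score",
                "n_unique_peptides_conf", "is_decoy")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("identification table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) stop("identification table is empty")
  if (any(records$unused_score < 0)) stop("unused_score must be nonnegative")
  if (any(records$n_unique_peptides_conf < 0)) {
    stop("n_unique_peptides_conf must be nonnegative")
  }
  records$is_decoy <- as.logical(records$is_decoy)
  key <- paste(records$accession, records$run_id)
  if (anyDuplicated(key)) {
    stop("(accession, run_id) pairs must be unique within a run table")
  }
  records
}

#' Estimate the protein score threshold at a target FDR
#'
#' Scans every observed score `t` in one run and returns the smallest `t`
#' such that, among records with `unused_score >= t`, the ratio of decoy to
#' target matches is at most `target_fdr` (the simple target-decoy
#' estimator). With no decoy records the run's minimum score is returned
#' with a warning, since the empirical FDR is already zero everywhere.
#'
#' @param records one run's identification records (see
#'   [validate_id_records()]).
#' @param target_fdr desired protein-level FDR, in (0, 1). Default 0.01.
#' @return numeric score threshold.
#' @examples
#' recs <- data.frame(accession = c("P1", "P2", "DECOY_1"), run_id = 1,
#'                    unused_score = c(3, 2.5, 1.4),
#'                    n_unique_peptides_conf = c(3, 2, 1),
#'                    is_decoy = c(FALSE, FALSE, TRUE))
#' estimate_fdr_threshold(recs, 0.01)
#' @export
estimate_fdr_threshold <- function(records, target_fdr = 0.01) {
  records <- validate_id_records(records)
  if (!(target_fdr > 0 && target_fdr < 1)) {
    stop("target_fdr must lie in (0, 1)")
  }
  if (all(records$is_decoy)) {
    stop("run contains only decoy records; cannot estimate an FDR threshold")
  }
  if (!any(records$is_decoy)) {
    warning("run contains no decoy records; returning the minimum score")
    return(min(records$unused_score))
  }
  # candidate thresholds are the observed scores; at each, FDR = D/T above it
  cand <- sort(unique(records$unused_score))
  score <- records$unused_score
  decoy <- records$is_decoy
  for (t in cand) {
    above <- score >= t
    n_target <- sum(above & !decoy)
    n_decoy <- sum(above & decoy)
    if (n_target > 0 && n_decoy / n_target <= target_fdr) return(t)
  }
  # no threshold attains the target FDR: everything would be rejected
  stop("no score threshold attains the target FDR in this run")
}

#' Accept proteins across runs by score threshold and peptide evidence
#'
#' A protein is accepted when, in at least `require_in_n_runs` runs, its
#' unused score lies strictly above that run's threshold and it carries at
#' least `min_unique_peptides` distinct peptides at the configured
#' confidence. Decoy records surviving the same rule are counted as residual
#' decoys and reported as an overall empirical FDR.
#'
#' @param run_tables list of per-run identification tables.
#' @param thresholds numeric vector, one score threshold per run.
#' @param min_unique_peptides minimum distinct peptides (default 2).
#' @param require_in_n_runs number of runs in which the rule must hold
#'   (default 1).
#' @return list of class `acceptance_result` with elements
#'   `accepted_accessions`, `per_run_thresholds`, `residual_decoys`,
#'   `overall_fdr`, and `decoy_accessions` (the surviving decoys).
#' @export
accept_proteins <- function(run_tables, thresholds, min_unique_peptides = 2,
                            require_in_n_runs = 1) {
  if (length(run_tables) != length(thresholds)) {
    stop("need exactly one threshold per run table")
  }
  if (min_unique_peptides < 0) stop("min_unique_peptides must be >= 0")
  if (require_in_n_runs < 1) stop("require_in_n_runs must be >= 1")
  run_tables <- lapply(run_tables, validate_id_records)

  # per accession, count runs where both rules hold
  pass_runs <- list()
  decoy_of <- list()
  for (r in seq_along(run_tables)) {
    tab <- run_tables[[r]]
    ok <- tab$unused_score > thresholds[[r]] &
      tab$n_unique_peptides_conf >= min_unique_peptides
    for (acc in tab$accession[ok]) {
      pass_runs[[acc]] <- (pass_runs[[acc]] %||% 0L) + 1L
    }
    for (i in seq_len(nrow(tab))) {
      decoy_of[[tab$accession[i]]] <- isTRUE(tab$is_decoy[i])
    }
  }
  n_pass <- unlist(pass_runs)
  survivors <- names(n_pass)[n_pass >= require_in_n_runs]
  is_dec <- vapply(survivors, function(a) decoy_of[[a]], logical(1))
  accepted <- survivors[!is_dec]
  residual <- survivors[is_dec]
  structure(list(
    accepted_accessions = accepted,
    per_run_thresholds = as.numeric(thresholds),
    residual_decoys = length(residual),
    decoy_accessions = residual,
    overall_fdr = length(residual) / max(1L, length(accepted))
  ), class = "acceptance_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge per-run identification tables into one catalog
#'
#' Combines run tables by protein accession into a single catalog with one
#' row per accession, a presence flag per run, and the best (maximum) score,
#' peptide count and coverage over the runs where the protein was seen.
#' When per-run quantitation availability is supplied, the catalog is
#' partitioned into proteins quantified in all runs, in some runs, and in
#' none.
#'
#' @param run_tables list of per-run identification tables.
#' @param quantified optional list (same length) of accession character
#'   vectors quantified in each run.
#' @param accessions optional character vector restricting the catalog
#'   (e.g. to accepted target proteins); default is every accession seen.
#' @return list with `catalog` (data.frame: accession, present_run_<r>,
#'   max_unused_score, max_peptides, n_runs_present, n_runs_quantified,
#'   quant_class) and `quant_partition` (named counts: all_runs, some_runs,
#'   no_runs) when `quantified` is given.
#' @export
merge_runs <- function(run_tables, quantified = NULL, accessions = NULL) {
  run_tables <- lapply(run_tables, validate_id_records)
  n_runs <- length(run_tables)
  if (!is.null(quantified) && length(quantified) != n_runs) {
    stop("quantified must have one accession vector per run")
  }
  all_acc <- unique(unlist(lapply(run_tables, `[[`, "accession")))
  if (!is.null(accessions)) all_acc <- intersect(all_acc, accessions)
  catalog <- data.frame(accession = all_acc, stringsAsFactors = FALSE)
  score <- pep <- matrix(NA_real_, nrow = length(all_acc), ncol = n_runs)
  present <- matrix(FALSE, nrow = length(all_acc), ncol = n_runs)
  for (r in seq_len(n_runs)) {
    tab <- run_tables[[r]]
    idx <- match(all_acc, tab$accession)
    hit <- !is.na(idx)
    present[hit, r] <- TRUE
    score[hit, r] <- tab$unused_score[idx[hit]]
    pep[hit, r] <- tab$n_unique_peptides_conf[idx[hit]]
    catalog[[paste0("present_run_", r)]] <- present[, r]
  }
  catalog$n_runs_present <- rowSums(present)
  catalog$max_unused_score <- apply(score, 1, max, na.rm = TRUE)
  catalog$max_peptides <- apply(pep, 1, max, na.rm = TRUE)

  quant_partition <- NULL
  if (!is.null(quantified)) {
    qmat <- vapply(seq_len(n_runs),
                   function(r) all_acc %in% quantified[[r]],
                   logical(length(all_acc)))
    qmat <- matrix(qmat, nrow = length(all_acc))
    nq <- rowSums(qmat)
    catalog$n_runs_quantified <- nq
    catalog$quant_class <- ifelse(nq == n_runs, "all_runs",
                                  ifelse(nq == 0, "no_runs", "some_runs"))
    quant_partition <- c(
      all_runs = sum(nq == n_runs),
      some_runs = sum(nq > 0 & nq < n_runs),
      no_runs = sum(nq == 0)
    )
  }
  list(catalog = catalog, quant_partition = quant_partition)
}
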