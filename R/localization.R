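# Priority-ordered secretome localization classification.

#' Default localization term dictionaries
#'
#' The tiers are applied in order: any secreted-tier evidence (annotation
#' term, classical signal-peptide consensus, or non-classical secretion
#' prediction) classifies a protein as secreted; otherwise a membrane-tier
#' term classifies it as plasma membrane; everything else is intracellular.
#' The shipped defaults can be overridden with a YAML file holding
#' `secreted_terms` and `membrane_terms` lists.
#'
#' @param path optional YAML file path.
#' @return list with `secreted_terms` and `membrane_terms` (lower case).
#' @export
localization_terms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "localization_terms.yaml",
                        package = "stromascreen")
  }
  raw <- yaml::read_yaml(path)
  list(secreted_terms = tolower(unlist(raw$secreted_terms)),
       membrane_terms = tolower(unlist(raw$membrane_terms)))
}

#' Classify one protein's subcellular localization
#'
#' Applies the priority rule over annotation and predictor evidence:
#' secreted first, then plasma membrane, then intracellular. Exosome-catalog
#' hits are reported as supporting evidence but never change the class.
#' Term matching is case-insensitive and order-independent.
#'
#' @param cc_terms character vector of localization annotation terms.
#' @param has_signal_peptide classical-secretion predictor consensus
#'   (missing treated as FALSE).
#' @param nonclassical_secreted non-classical secretion prediction
#'   (missing treated as FALSE).
#' @param exosome_hits nonnegative count of exosome-catalog experiments
#'   containing the protein.
#' @param terms dictionaries from [localization_terms()].
#' @return list with `klass` in {secreted, plasma_membrane, intracellular}
#'   and `evidence`, the character vector of fired sources.
#' @export
classify_localization <- function(cc_terms = character(),
                                  has_signal_peptide = FALSE,
                                  nonclassical_secreted = FALSE,
                                  exosome_hits = 0,
                                  terms = localization_terms()) {
  cc <- tolower(trimws(cc_terms))
  has_signal_peptide <- isTRUE(as.logical(has_signal_peptide))
  nonclassical_secreted <- isTRUE(as.logical(nonclassical_secreted))
  evidence <- character()
  sec_hit <- intersect(cc, terms$secreted_terms)
  if (length(sec_hit) > 0) {
    evidence <- c(evidence, paste0("annotation:", sec_hit))
  }
  if (has_signal_peptide) evidence <- c(evidence, "predictor:signal_peptide")
  if (nonclassical_secreted) evidence <- c(evidence, "predictor:nonclassical")
  if (length(evidence) > 0) {
    klass <- "secreted"
  } else {
    mem_hit <- intersect(cc, terms$membrane_terms)
    if (length(mem_hit) > 0) {
      klass <- "plasma_membrane"
      evidence <- paste0("annotation:", mem_hit)
    } else {
      klass <- "intracellular"
    }
  }
  if (exosome_hits >= 1) {
    evidence <- c(evidence, sprintf("exosome:%d_experiments",
                                    as.integer(exosome_hits)))
  }
  list(klass = klass, evidence = evidence)
}

#' Classify a table of annotation records
#'
#' @param annotations data.frame with columns `accession`, `cc_terms`
#'   (';'-joined string), `has_signal_peptide`, `nonclassical_secreted`,
#'   `exosome_hits`.
#' @param terms dictionaries from [localization_terms()].
#' @return data.frame: accession, klass, evidence (';'-joined),
#'   exosome_hits.
#' @export
classify_catalog <- function(annotations, terms = localization_terms()) {
  n <- nrow(annotations)
  klass <- character(n); evid <- character(n)
  for (i in seq_len(n)) {
    cc <- strsplit(annotations$cc_terms[i] %||% "", ";", fixed = TRUE)[[1]]
    res <- classify_localization(
      cc_terms = cc,
      has_signal_peptide = annotations$has_signal_peptide[i],
      nonclassical_secreted = annotations$nonclassical_secreted[i],
      exosome_hits = annotations$exosome_hits[i] %||% 0,
      terms = terms
    )
    klass[i] <- res$klass
    evid[i] <- paste(res$evidence, collapse = ";")
  }
  data.frame(accession = annotations$accession, klass = klass,
             evidence = evid, exosome_hits = annotations$exosome_hits,
             stringsAsFactors = FALSE)
}

#' Summarize localization calls into counts and rounded percentages
#'
#' @param calls data.frame with a `klass` column, or a character vector of
#'   classes.
#' @return data.frame with one row per class (secreted, plasma_membrane,
#'   intracellular): count and percent (percent = round(100 * count/total)).
#' @export
summarize_localization <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$klass
  if (length(calls) == 0) stop("no localization calls to summarize")
  classes <- c("secreted", "plasma_membrane", "intracellular")
  bad <- setdiff(unique(calls), classes)
  if (length(bad) > 0) stop("unknown class: ", paste(bad, collapse = ", "))
  count <- vapply(classes, function(k) sum(calls == k), integer(1))
  data.frame(klass = classes, count = unname(count),
             percent = round(100 * unname(count) / length(calls)),
             stringsAsFactors = FALSE)
}

#' Fraction of the catalog seen in exosome catalogs
#'
#' @param calls data.frame from [classify_catalog()] (needs `klass` and
#'   `exosome_hits`).
#' @param min_hits minimum number of catalog experiments to count a protein
#'   (default 1).
#' @return list with `overall` fraction and `per_class` named fractions.
#' @export
exosome_overlap <- function(calls, min_hits = 1) {
  hit <- calls$exosome_hits >= min_hits
  per_class <- vapply(c("secreted", "plasma_membrane", "intracellular"),
                      function(k) {
                        sel <- calls$klass == k
                        if (!any(sel)) return(NA_real_)
                        mean(hit[sel])
                      }, numeric(1))
  list(overall = if (nrow(calls) == 0) NA_real_ else mean(hit),
       per_class = per_class)
}
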