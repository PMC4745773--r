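# Vote-count screen over independent microarray analyses.

#' Read a vote table
#'
#' A vote table holds, per gene, the number of independent microarray
#' analyses that called it significantly up- or downregulated in cancer
#' (at each source analysis's p < 0.05). "-" or empty count cells parse
#' as 0.
#'
#' @param path TSV file with at least columns `gene`, `n_up`, `n_down`
#'   (and optionally `n_total`).
#' @return data.frame with integer count columns.
#' @export
read_vote_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in intersect(c("n_up", "n_down", "n_total"), names(tab))) {
    v <- as.character(tab[[col]])
    v[v %in% c("-", "–", "", "NA")] <- "0"
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' Bundled vote-count fixture of dysregulated stroma-enriched genes
#'
#' Loads the packaged table of 28 fibroblast-enriched proteins with their
#' up/down vote counts across public colon-cancer microarray analyses.
#'
#' @return data.frame as from [read_vote_table()], plus a `table_group`
#'   column recording the table's own up/down sectioning.
#' @export
stromal_vote_table <- function() {
  read_vote_table(system.file("extdata", "table1_votes.tsv",
                              package = "stromascreen"))
}

#' Classify one gene by vote counts
#'
#' A gene is called cancer-up when at least `up_min` analyses called it up
#' and at most `down_max` called it down; cancer-down by the mirrored rule;
#' anything else is unclassified.
#'
#' @param n_up,n_down nonnegative analysis counts.
#' @param up_min minimum supporting analyses (default 15).
#' @param down_max maximum contradicting analyses (default 1).
#' @return one of "cancer_up", "cancer_down", "unclassified".
#' @export
screen_gene <- function(n_up, n_down, up_min = 15, down_max = 1) {
  if (is.na(n_up) || is.na(n_down) || n_up < 0 || n_down < 0) {
    stop("vote counts must be nonnegative")
  }
  if (n_up >= up_min && n_down <= down_max) return("cancer_up")
  if (n_down >= up_min && n_up <= down_max) return("cancer_down")
  "unclassified"
}

#' Screen a whole vote table
#'
#' @param votes data.frame with columns `gene`, `n_up`, `n_down`.
#' @inheritParams screen_gene
#' @return list with `calls` (data.frame gene/status) and `counts` (named
#'   integer vector over the three statuses).
#' @export
screen_catalog <- function(votes, up_min = 15, down_max = 1) {
  status <- if (nrow(votes) == 0) character(0) else
    vapply(seq_len(nrow(votes)),
           function(i) screen_gene(votes$n_up[i], votes$n_down[i],
                                   up_min, down_max),
           character(1))
  calls <- data.frame(gene = votes$gene %||% character(0), status = status,
                      stringsAsFactors = FALSE)
  counts <- c(cancer_up = sum(status == "cancer_up"),
              cancer_down = sum(status == "cancer_down"),
              unclassified = sum(status == "unclassified"))
  list(calls = calls, counts = counts)
}
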