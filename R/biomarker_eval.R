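# Biomarker evaluation statistics: Kaplan-Meier survival, log-rank test,
# IHC positivity scoring, Fisher's exact association, ROC cutoff selection.
# Implemented from first principles with the risk-set bookkeeping exposed;
# the test suite cross-checks each against an independent route.

#' Kaplan-Meier product-limit survival curve
#'
#' Computes the product-limit estimator for one group of right-censored
#' survival records. At each distinct event time the estimator multiplies
#' by (1 - d/n) where d is the number of deaths and n the risk set; tied
#' censorings at an event time are handled after the events (standard
#' Mantel-Cox convention), i.e. subjects censored at time t are still at
#' risk for events at t.
#'
#' @param time positive follow-up times (months).
#' @param event logical/0-1; TRUE when death was observed.
#' @return data.frame of class `km_curve`: time (distinct event times),
#'   n_risk, n_event, n_censor (censorings in (previous time, time]),
#'   survival. S(0) = 1 implicitly; the curve is right-continuous and
#'   non-increasing.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("empty survival group")
  if (any(time <= 0)) stop("survival times must be positive")
  event <- as.logical(event)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  etimes <- sort(unique(time[event]))
  surv <- 1
  out <- data.frame(time = numeric(0), n_risk = integer(0),
                    n_event = integer(0), n_censor = integer(0),
                    survival = numeric(0))
  prev <- 0
  for (t in etimes) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    cens <- sum(time > prev & time < t & !event) + sum(time == t & !event)
    surv <- surv * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, n_risk = n_risk, n_event = d,
                                 n_censor = cens, survival = surv))
    prev <- t
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [km_curve()].
#' @param t numeric times.
#' @return S(t), right-continuous.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(x) {
    below <- curve$time <= x
    if (!any(below)) 1 else curve$survival[max(which(below))]
  }, numeric(1))
}

#' Log-rank (Mantel-Cox) test
#'
#' Unweighted Mantel-Cox test comparing survival between k groups. For
#' each distinct pooled event time, observed and expected events per group
#' are accumulated with the hypergeometric variance-covariance; the
#' chi-square statistic has k - 1 degrees of freedom.
#'
#' @param time positive follow-up times over all subjects.
#' @param event logical/0-1 death indicator.
#' @param group group labels (factor/character/numeric); at least 2 levels.
#' @return list: statistic, df, p_value, observed, expected (per group).
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups")
  if (any(table(group) == 0)) stop("empty group")
  if (!any(event)) stop("no events observed in any group")
  etimes <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    d <- sum(time == t & event)
    dj <- vapply(levels(group), function(g) sum(time == t & event & group == g),
                 numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (g in seq_len(k)) {
        for (l in seq_len(k)) {
          V[g, l] <- V[g, l] +
            d * (nj[g] / n) * ((g == l) - nj[l] / n) * (n - d) / (n - 1)
        }
      }
    }
  }
  u <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vsub, u)),
                   error = function(e) NA_real_)
  if (is.na(stat)) {
    # singular covariance (e.g. a group with no one at risk at event times)
    stat <- if (all(abs(u) < 1e-12)) 0 else
      drop(t(u) %*% MASSlike_ginv(Vsub) %*% u)
  }
  df <- k - 1
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}

# Moore-Penrose pseudoinverse via SVD for singular covariance corner cases.
MASSlike_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Split subjects at the median
#'
#' Divides subjects into higher-than-median and lower-than-median groups.
#' Values tied with the median go to the lower group (the default,
#' deterministic rule); `ties = "exclude"` drops them instead.
#'
#' @param values numeric vector, length >= 2.
#' @param ties "lower" (default) or "exclude".
#' @return character vector of labels "higher_than_median" /
#'   "lower_than_median" (NA for excluded ties).
#' @export
dichotomize_by_median <- function(values, ties = c("lower", "exclude")) {
  ties <- match.arg(ties)
  if (length(values) < 2) stop("need at least 2 subjects")
  med <- stats::median(values)
  lab <- ifelse(values > med, "higher_than_median", "lower_than_median")
  if (ties == "exclude") lab[values == med] <- NA_character_
  if (all(values == med)) {
    warning("all values equal the median; every subject is in the lower group")
  }
  lab
}

#' Score immunohistochemistry staining intensity
#'
#' Averages IOD/area (integrated optical density per unit area) over the
#' images of one sample region and calls the region positive when the mean
#' intensity strictly exceeds the cutoff.
#'
#' @param iod nonnegative integrated optical densities, one per image.
#' @param area positive region areas, aligned with `iod`.
#' @param cutoff positivity cutoff on mean IOD/area (default 0.043).
#' @return list: intensity (mean IOD/area), positive (logical).
#' @export
ihc_score <- function(iod, area, cutoff = 0.043) {
  if (length(iod) == 0) stop("need at least one image")
  if (length(iod) != length(area)) stop("iod and area must align")
  if (any(area <= 0)) stop("image areas must be positive")
  if (any(iod < 0)) stop("IOD must be nonnegative")
  intensity <- mean(iod / area)
  list(intensity = intensity, positive = intensity > cutoff)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test: under the hypergeometric null with the table's
#' margins fixed, sums the probabilities of all tables no more probable
#' than the observed one (the same convention as [stats::fisher.test()]).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list: p_value, odds_ratio (sample cross-product ratio).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be nonnegative integers")
  }
  if (sum(tab) == 0) stop("all-zero table")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(x, m, n, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(1, p), odds_ratio = or)
}

#' ROC curve over every observed concentration cutoff
#'
#' Sweeps each observed concentration as a threshold, calling a sample
#' positive when its concentration is at or above the threshold (cases are
#' assumed to run higher; if the resulting AUC is below 0.5 a warning
#' suggests the orientation is reversed). Endpoints (0,0) and (1,1) are
#' included.
#'
#' @param concentration numeric marker values (e.g. ng/mL), >= 0.
#' @param is_case logical disease status.
#' @return data.frame of class `roc_curve`: threshold, sensitivity,
#'   specificity, fpr, ordered by increasing fpr.
#' @export
roc_points <- function(concentration, is_case) {
  is_case <- as.logical(is_case)
  if (!any(is_case) || all(is_case)) {
    stop("need at least one case and one control")
  }
  if (any(concentration < 0)) stop("concentrations must be nonnegative")
  cases <- concentration[is_case]
  ctrls <- concentration[!is_case]
  thr <- c(Inf, sort(unique(concentration), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(ctrls < t), numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec)
  out <- out[order(out$fpr, out$sensitivity), ]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve (trapezoid rule)
#'
#' Equals the Mann-Whitney probability that a random case exceeds a random
#' control, with half credit for ties.
#'
#' @param curve a [roc_points()] curve.
#' @return AUC in [0, 1].
#' @export
auc <- function(curve) {
  x <- curve$fpr; y <- curve$sensitivity
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Optimal ROC cutoff by the Youden criterion
#'
#' Chooses the threshold maximizing sensitivity + specificity; ties are
#' broken toward the lower cutoff concentration.
#'
#' @param curve a [roc_points()] curve.
#' @return list: cutoff, sensitivity, specificity, youden_j.
#' @export
optimal_cutoff <- function(curve) {
  finite <- is.finite(curve$threshold)
  cand <- curve[finite, , drop = FALSE]
  j <- cand$sensitivity + cand$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(cand$threshold[best])]
  list(cutoff = cand$threshold[pick],
       sensitivity = cand$sensitivity[pick],
       specificity = cand$specificity[pick],
       youden_j = j[pick])
}

#' Full ROC analysis of a plasma marker
#'
#' @param concentration marker values.
#' @param is_case logical disease status.
#' @return list: curve, auc, cutoff, sensitivity, specificity. Warns when
#'   AUC < 0.5 (cases appear to run lower than controls).
#' @export
roc_analysis <- function(concentration, is_case) {
  curve <- roc_points(concentration, is_case)
  a <- auc(curve)
  if (a < 0.5) {
    warning("AUC below 0.5: cases appear to have lower marker values; ",
            "consider flipping the orientation")
  }
  opt <- optimal_cutoff(curve)
  list(curve = curve, auc = a, cutoff = opt$cutoff,
       sensitivity = opt$sensitivity, specificity = opt$specificity)
}
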