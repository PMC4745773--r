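# Independent brute-force oracles used to cross-check the implementations.

# smallest observed score t with decoys/targets at score >= t below the
# target FDR, by exhaustive scan
oracle_fdr_threshold <- function(score, decoy, target_fdr) {
  for (t in sort(unique(score))) {
    nt <- sum(score >= t & !decoy)
    nd <- sum(score >= t & decoy)
    if (nt > 0 && nd / nt <= target_fdr) return(t)
  }
  NA_real_
}

# product-limit survival at time t by direct product over event times
oracle_km_at <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event & time <= t]))) {
    s <- s * (1 - sum(time == u & event) / sum(time >= u))
  }
  s
}

# two-group Mantel-Cox chi-square via the scalar U^2/V event-table form
oracle_logrank2 <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  U <- V <- 0
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# AUC as the Mann-Whitney pairwise comparison count with tie half-credit
oracle_auc <- function(concentration, is_case) {
  cases <- concentration[is_case]
  ctrls <- concentration[!is_case]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# two-sided Fisher exact p by full enumeration over the hypergeometric
# support, with binomial coefficients only
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# best Youden cutoff by exhaustive scan over observed thresholds
oracle_best_cutoff <- function(concentration, is_case) {
  cases <- concentration[is_case]
  ctrls <- concentration[!is_case]
  thr <- sort(unique(concentration))
  j <- vapply(thr, function(t) mean(cases >= t) + mean(ctrls < t) - 1,
              numeric(1))
  thr[min(which(j == max(j)))]
}

random_survival <- function(n, seed) {
  set.seed(seed)
  data.frame(time = round(rexp(n, 0.05) + 0.5, 1),
             event = runif(n) < 0.7,
             group = sample(c("a", "b"), n, replace = TRUE))
}
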