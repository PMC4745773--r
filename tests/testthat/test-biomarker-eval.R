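test_that("Kaplan-Meier estimator handles closed-form cases", {
  all_cens <- km_curve(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(all_cens), 0)
  expect_equal(km_survival_at(all_cens, c(0, 5, 100)), c(1, 1, 1))

  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  expect_error(km_curve(numeric(0), logical(0)), "empty")
  expect_error(km_curve(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("Kaplan-Meier matches the direct product oracle and survfit", {
  skip_if_not_installed("survival")
  for (seed in 1:30) {
    d <- random_survival(sample(5:25, 1), seed)
    km <- km_curve(d$time, d$event)
    for (t in c(d$time, max(d$time) + 1)) {
      expect_equal(km_survival_at(km, t), oracle_km_at(d$time, d$event, t),
                   tolerance = 1e-12)
    }
    if (any(d$event)) {
      sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
      expect_equal(km_survival_at(km, sf$time[sf$n.event > 0]),
                   sf$surv[sf$n.event > 0], tolerance = 1e-10)
    }
  }
})

test_that("Kaplan-Meier is order-invariant and non-increasing", {
  d <- random_survival(40, 99)
  km1 <- km_curve(d$time, d$event)
  perm <- sample(nrow(d))
  km2 <- km_curve(d$time[perm], d$event[perm])
  expect_equal(km1, km2)
  expect_true(all(diff(km1$survival) <= 1e-12))
  # with no censoring the estimator is the empirical survival function
  e <- random_survival(30, 100); e$event <- TRUE
  km <- km_curve(e$time, e$event)
  expect_equal(km$survival, vapply(km$time, function(t) mean(e$time > t),
                                   numeric(1)))
})

test_that("log-rank statistic is zero for identical groups and symmetric", {
  d <- random_survival(20, 2)
  dup <- rbind(transform(d, group = "x"), transform(d, group = "y"))
  lr <- logrank_test(dup$time, dup$event, dup$group)
  expect_equal(lr$statistic, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)

  e <- random_survival(40, 3)
  a <- logrank_test(e$time, e$event, e$group)
  flipped <- ifelse(e$group == "a", "b", "a")
  b <- logrank_test(e$time, e$event, flipped)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
})

test_that("log-rank grows with group separation", {
  early <- data.frame(time = 1:10, event = TRUE, group = "early")
  late <- data.frame(time = 101:110, event = TRUE, group = "late")
  mid <- data.frame(time = 51:60, event = TRUE, group = "late")
  far <- logrank_test(c(early$time, late$time), TRUE,
                      c(early$group, late$group))$statistic
  near <- logrank_test(c(early$time, mid$time), TRUE,
                       c(early$group, mid$group))$statistic
  expect_gte(far, near)
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")),
               "no events")
})

test_that("log-rank matches the event-table oracle and survdiff", {
  skip_if_not_installed("survival")
  for (seed in 1:30) {
    d <- random_survival(sample(10:40, 1), seed + 500)
    if (!any(d$event) || length(unique(d$group)) < 2) next
    lr <- logrank_test(d$time, d$event, d$group)
    expect_equal(lr$statistic, oracle_logrank2(d$time, d$event, d$group),
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
})

test_that("k-group log-rank agrees with survdiff on four groups", {
  skip_if_not_installed("survival")
  set.seed(77)
  d <- data.frame(time = round(rexp(80, 0.04) + 0.5, 1),
                  event = runif(80) < 0.6,
                  group = sample(paste0("g", 1:4), 80, replace = TRUE))
  lr <- logrank_test(d$time, d$event, d$group)
  expect_equal(lr$df, 3)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
})

test_that("median split sends ties to the lower group", {
  expect_equal(dichotomize_by_median(c(1, 2, 3, 4)),
               rep(c("lower_than_median", "higher_than_median"), each = 2))
  lab <- dichotomize_by_median(c(1, 2, 2, 3))
  expect_equal(sum(lab == "lower_than_median"), 3)
  expect_warning(dichotomize_by_median(c(5, 5, 5)), "all values equal")
  excl <- dichotomize_by_median(c(1, 2, 2, 3), ties = "exclude")
  expect_true(all(is.na(excl[c(2, 3)])))
  # with median ties excluded, group imbalance is bounded by the tie count
  set.seed(4)
  for (i in 1:10) {
    v <- sample(1:8, 21, replace = TRUE)
    lab <- dichotomize_by_median(v, ties = "exclude")
    ties <- sum(v == median(v))
    expect_lte(abs(sum(lab == "higher_than_median", na.rm = TRUE) -
                     sum(lab == "lower_than_median", na.rm = TRUE)), ties)
  }
})

test_that("IHC intensity averages IOD/area with a strict cutoff", {
  s <- ihc_score(iod = 5, area = 100)
  expect_equal(s$intensity, 0.05)
  expect_true(s$positive)
  expect_false(ihc_score(iod = 4.3, area = 100)$positive)
  multi <- ihc_score(iod = c(2, 6, 4), area = c(50, 100, 80))
  expect_equal(multi$intensity, mean(c(2 / 50, 6 / 100, 4 / 80)))
  # scale consistency: doubling IOD and area changes nothing
  expect_equal(ihc_score(c(4, 12), c(100, 200))$intensity,
               ihc_score(c(2, 6), c(50, 100))$intensity)
  expect_error(ihc_score(1, 0), "positive")
})

test_that("Fisher's exact test matches enumeration and fisher.test", {
  p <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 7, 7), 2))$p_value, 1)
  set.seed(19)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab)$p_value
    expect_equal(mine, oracle_fisher(tab), tolerance = 1e-10)
    expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
})

test_that("ROC curve spans its endpoints and separates perfect groups", {
  conc <- c(10, 11, 12, 20, 21, 22)
  case <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  curve <- roc_points(conc, case)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$sensitivity[nrow(curve)], 1)
  expect_true(any(curve$fpr == 0 & curve$sensitivity == 1))
  expect_equal(auc(curve), 1)
  opt <- optimal_cutoff(curve)
  expect_equal(opt$cutoff, 20)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  expect_error(roc_points(c(1, 2), c(TRUE, TRUE)), "case and one control")
})

test_that("AUC equals the Mann-Whitney pairwise oracle, ties included", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    conc <- sample(1:8, n, replace = TRUE)  # coarse grid forces ties
    case <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    curve <- roc_points(conc, case)
    expect_equal(auc(curve), oracle_auc(conc, case), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(24)
  conc <- rlnorm(40, 3, 0.5)
  case <- runif(40) < 0.5
  case[1] <- TRUE; case[2] <- FALSE
  a <- auc(roc_points(conc, case))
  expect_equal(auc(roc_points(sqrt(conc), case)), a, tolerance = 1e-12)
  expect_equal(auc(roc_points(conc, !case)), 1 - a, tolerance = 1e-12)
})

test_that("random labels give a near-diagonal curve", {
  set.seed(25)
  conc <- rnorm(4000, 50, 10)
  case <- rep(c(TRUE, FALSE), 2000)
  expect_equal(auc(roc_points(conc, case)), 0.5, tolerance = 0.03)
})

test_that("optimal cutoff matches the exhaustive threshold scan", {
  set.seed(26)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    conc <- round(rnorm(n, 50, 10), 1)
    case <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    conc[case] <- conc[case] + 8
    conc <- pmax(conc, 0)
    opt <- optimal_cutoff(roc_points(conc, case))
    expect_equal(opt$cutoff, oracle_best_cutoff(conc, case))
  }
})

test_that("ROC analysis warns when cases run lower than controls", {
  set.seed(27)
  conc <- c(rnorm(30, 30, 3), rnorm(30, 60, 3))
  case <- rep(c(TRUE, FALSE), each = 30)
  expect_warning(roc_analysis(conc, case), "below 0.5")
})

test_that("AUC agrees with pROC on a moderate sample", {
  skip_if_not_installed("pROC")
  set.seed(28)
  conc <- c(rnorm(40, 60, 12), rnorm(50, 45, 8))
  case <- rep(c(TRUE, FALSE), c(40, 50))
  mine <- auc(roc_points(conc, case))
  ref <- as.numeric(pROC::auc(pROC::roc(case, conc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
})
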