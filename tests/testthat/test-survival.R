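test_that("product-limit estimate matches hand computation", {
  rec <- data.frame(time = c(1, 2, 3), event = 1)
  km <- km_estimate(rec)
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)
  # all censored: flat curve, undefined median
  kmc <- km_estimate(data.frame(time = c(5, 8), event = 0))
  expect_length(kmc$time, 0)
  expect_true(is.na(kmc$median))
  # single event
  km1 <- km_estimate(data.frame(time = 5, event = 1))
  expect_equal(km1$surv, 0)
  expect_equal(km1$median, 5)
  # censoring at an event time keeps the censored subject at risk
  km2 <- km_estimate(data.frame(time = c(2, 2, 3), event = c(1, 0, 1)))
  expect_equal(km2$surv, c(2/3, 0))
  expect_error(km_estimate(data.frame(time = numeric(0),
                                      event = integer(0))), "no survival")
  expect_error(km_estimate(data.frame(time = c(1, -1), event = 1)),
               "positive")
})

test_that("KM agrees with the reference implementation to 1e-8", {
  set.seed(61)
  for (i in 1:25) {
    rec <- random_survival_records(sample(10:80, 1))
    rec$time <- round(rec$time, 1) + 0.1 # force ties
    km <- km_estimate(rec)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
    ref_t <- sf$time[sf$n.event > 0]
    ref_s <- sf$surv[sf$n.event > 0]
    expect_equal(km$time, ref_t, tolerance = 1e-10)
    expect_equal(km$surv, ref_s, tolerance = 1e-8)
    med <- unname(summary(sf)$table["median"])
    expect_equal(km$median, med, tolerance = 1e-8)
  }
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  set.seed(62)
  for (i in 1:50) {
    t <- rexp(sample(5:100, 1), 0.02)
    km <- km_estimate(data.frame(time = t, event = 1))
    ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical groups and matches survdiff", {
  rec <- data.frame(time = rep(c(1, 3, 7, 9), 2), event = 1,
                    group = rep(c("a", "b"), each = 4))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)
  # separated groups, against the reference implementation
  rec2 <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1,
                     group = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(rec2)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = rec2)
  expect_equal(lr2$statistic, unname(sd2$chisq), tolerance = 1e-8)
  set.seed(63)
  for (i in 1:30) {
    rec <- random_survival_records(sample(20:80, 1))
    rec$time <- round(rec$time, 1) + 0.1
    k <- sample(2:4, 1)
    rec$group <- sample(letters[1:k], nrow(rec), replace = TRUE)
    if (length(unique(rec$group)) < 2) next
    lr <- logrank_test(rec)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = rec)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
    expect_equal(lr$df, length(unique(rec$group)) - 1L)
  }
})

test_that("list-of-groups input and group relabeling leave the statistic unchanged", {
  set.seed(64)
  g1 <- data.frame(time = rexp(20, 0.02) + 0.1, event = rbinom(20, 1, 0.8))
  g2 <- data.frame(time = rexp(25, 0.04) + 0.1, event = rbinom(25, 1, 0.8))
  g3 <- data.frame(time = rexp(15, 0.01) + 0.1, event = rbinom(15, 1, 0.8))
  lr <- logrank_test(list(g1, g2, g3))
  expect_equal(lr$df, 2L)
  lr_perm <- logrank_test(list(g3, g1, g2))
  expect_equal(lr$statistic, lr_perm$statistic, tolerance = 1e-10)
  expect_error(logrank_test(list(g1)), "at least 2")
})

test_that("optimal binning enforces the minimum group size", {
  set.seed(65)
  rec <- random_survival_records(19)
  cov <- stats::setNames(runif(19), rec$patient_id)
  expect_error(optimal_binning(cov, rec), "no admissible split")
  # constant covariate can never split
  rec2 <- random_survival_records(40)
  cov2 <- stats::setNames(rep(1, 40), rec2$patient_id)
  expect_error(optimal_binning(cov2, rec2), "no admissible split")
  expect_error(optimal_binning(unname(cov), rec), "named")
  expect_error(optimal_binning(cov[1:5], rec), "undefined for patient")
})

test_that("optimal binning equals the exhaustive oracle", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(24:60, 1)
    rec <- random_survival_records(n)
    cov <- stats::setNames(round(runif(n), 2), rec$patient_id)
    got <- tryCatch(optimal_binning(cov, rec), error = function(e) NULL)
    want <- oracle_binning(cov, rec)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$p.value, want$p, tolerance = 1e-8)
    }
  }
  # covariate equal to survival time, all events: strongest separation
  n <- 24
  rec <- data.frame(patient_id = sprintf("q%02d", 1:n),
                    time = seq_len(n) + 0.5, event = 1)
  cov <- stats::setNames(rec$time, rec$patient_id)
  got <- optimal_binning(cov, rec)
  want <- oracle_binning(cov, rec)
  expect_equal(got$threshold, want$threshold)
  expect_equal(got$p.value, want$p, tolerance = 1e-8)
})

test_that("binning landscape reports sizes and admissibility per threshold", {
  set.seed(67)
  rec <- random_survival_records(30)
  cov <- stats::setNames(sample(1:5, 30, replace = TRUE),
                         rec$patient_id)
  br <- optimal_binning(cov, rec, min_group = 5L)
  expect_equal(nrow(br$landscape), length(unique(cov)))
  expect_true(all(br$landscape$n_low + br$landscape$n_high == 30))
  # the largest observed value is never admissible (empty high group)
  top <- br$landscape[which.max(br$landscape$threshold), ]
  expect_false(top$admissible)
  expect_true(all(table(br$groups) >= 5))
  # group assignment matches the chosen threshold
  expect_identical(unname(br$groups),
                   unname(ifelse(cov[rec$patient_id] <= br$threshold,
                                 "low", "high")))
})

test_that("display capping never alters the computed statistics", {
  set.seed(68)
  rec <- random_survival_records(40, rate = 0.004)
  rec$group <- rep(c("a", "b"), 20)
  lr_before <- logrank_test(rec)
  km_before <- km_estimate(rec)
  # display copy capped at 500 days is for plotting only; the analysis
  # path keeps the uncapped records
  pdf(NULL)
  plot(km_estimate(rec), xlim = c(0, 500))
  dev.off()
  expect_identical(logrank_test(rec), lr_before)
  expect_identical(km_estimate(rec), km_before)
})

test_that("bivariate stratification assigns quadrants and tests the groups", {
  rec <- data.frame(patient_id = c("a", "b", "c", "d"),
                    time = c(10, 20, 30, 40), event = 1)
  c1 <- c(a = 1, b = 1, c = 5, d = 5)
  c2 <- c(a = 1, b = 5, c = 1, d = 5)
  bi <- bivariate_stratify(c1, c2, 2, 2, rec)
  expect_equal(sort(unname(bi$groups)), c("HH", "HL", "LH", "LL"))
  expect_equal(unname(bi$groups[c("a", "b", "c", "d")]),
               c("LL", "LH", "HL", "HH"))
  expect_equal(bi$logrank$df, 3L)
  # all below the first threshold: only LL/LH remain, df = 1
  bi2 <- bivariate_stratify(c1, c2, 10, 2, rec)
  expect_setequal(unique(unname(bi2$groups)), c("LL", "LH"))
  expect_equal(bi2$logrank$df, 1L)
  # all patients in one quadrant: no contrast left
  expect_error(bivariate_stratify(c1, c2, 0, 0, rec),
               "at least 2 non-empty groups")
})

test_that("planted interaction puts the HH quadrant on top at n = 400", {
  cfg <- cohort_config(n_patients = 400, censoring_rate = 0, seed = 69L)
  co <- generate_cohort(cfg)
  med <- quadrant_medians(co)
  expect_equal(names(which.max(med)), "HH")
  expect_gt(med[["HL"]], max(med[["LH"]], med[["LL"]]))
})
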