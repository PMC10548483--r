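test_that("Welch test matches its closed form and the reference oracle", {
  # hand evaluation: equal variances 1, difference -1
  wt <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(wt$statistic), -1.224745, tolerance = 1e-6)
  expect_equal(unname(wt$parameter), 4, tolerance = 1e-10)
  expect_equal(wt$p.value, 0.2881, tolerance = 1e-3)
  # identical samples: no difference
  x <- c(0.1, 0.5, 0.9)
  wt0 <- welch_test(x, x)
  expect_equal(unname(wt0$statistic), 0)
  expect_equal(wt0$p.value, 1)
  set.seed(71)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), 1, sd = runif(1, 0.5, 3))
    ref <- t.test(a, b)
    got <- welch_test(a, b)
    expect_equal(unname(got$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(got$parameter), unname(ref$parameter),
                 tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch test is antisymmetric and handles one-sided zero variance", {
  set.seed(72)
  a <- rnorm(10); b <- rnorm(15, 1)
  expect_equal(unname(welch_test(a, b)$statistic),
               -unname(welch_test(b, a)$statistic))
  expect_equal(welch_test(a, b)$p.value, welch_test(b, a)$p.value)
  wt <- welch_test(rep(2, 5), rnorm(10))
  expect_true(is.finite(unname(wt$statistic)))
  expect_true(is.finite(unname(wt$parameter)))
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Spearman correlation matches the rank definition and oracle", {
  expect_equal(unname(spearman_correlation(1:10, (1:10)^3)$estimate), 1)
  expect_equal(unname(spearman_correlation(1:10, -(1:10))$estimate), -1)
  set.seed(73)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)  # heavy ties
    y <- x + rnorm(n, sd = 2)
    got <- spearman_correlation(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(unname(got$estimate), unname(ref$estimate),
                 tolerance = 1e-10)
  }
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(74)
  x <- rlnorm(30); y <- rnorm(30)
  base <- unname(spearman_correlation(x, y)$estimate)
  expect_equal(unname(spearman_correlation(log(x), y)$estimate), base)
  expect_equal(unname(spearman_correlation(x, exp(y))$estimate), base)
  expect_equal(unname(spearman_correlation(rank(x), y)$estimate), base)
})

test_that("response-group comparisons pool top-10 scores per group", {
  clin <- data.frame(patient_id = c("p1", "p2", "p3", "p4"),
                     response = c("R", "PD", "SD", "PD"),
                     stringsAsFactors = FALSE)
  cand <- do.call(rbind, lapply(1:4, function(i)
    data.frame(patient_id = paste0("p", i),
               ap_score = seq(0.1, 0.9, length.out = 12) + i / 100,
               stringsAsFactors = FALSE)))
  tab <- compare_response_groups(cand, clin)
  # each patient contributes exactly its top 10 scores
  expect_equal(tab$n1[tab$comparison == "R vs PD"], 10)
  expect_equal(tab$n2[tab$comparison == "R vs PD"], 20)
  expect_equal(tab$n1[tab$comparison == "PD vs nonPD"], 20)
  expect_equal(tab$n2[tab$comparison == "PD vs nonPD"], 20)
  expect_setequal(tab$comparison,
                  c("R vs PD", "R vs SD", "SD vs PD", "PD vs nonPD"))
  # identical constant scores give p = 1 everywhere
  cand0 <- cand
  cand0$ap_score <- 0.5
  tab0 <- compare_response_groups(cand0, clin)
  expect_true(all(tab0$p == 1))
  # per-patient pooling collapses each patient to one mean; singleton
  # groups drop out of their pairwise comparisons
  tabm <- suppressWarnings(
    compare_response_groups(cand, clin, per_patient = TRUE))
  expect_equal(tabm$n1[tabm$comparison == "PD vs nonPD"], 2)
  expect_equal(tabm$n2[tabm$comparison == "PD vs nonPD"], 2)
})

test_that("unlabeled patients and empty groups are handled with warnings", {
  clin <- data.frame(patient_id = c("p1", "p2", "p3"),
                     response = c("PD", "PD", NA),
                     stringsAsFactors = FALSE)
  cand <- data.frame(patient_id = rep(c("p1", "p2", "p3"), each = 5),
                     ap_score = runif(15), stringsAsFactors = FALSE)
  expect_warning(tab <- suppressWarnings(
    compare_response_groups(cand, clin)) , NA)
  out <- withCallingHandlers(
    compare_response_groups(cand, clin),
    warning = function(w) {
      expect_match(conditionMessage(w), "excluded|skipped")
      invokeRestart("muffleWarning")
    })
  expect_equal(nrow(out), 0L)
})

test_that("a planted non-PD quality shift is detected at cohort scale", {
  # power check at the study's group sizes: AP scores of responders and
  # stable-disease patients shifted up by 0.15
  set.seed(75)
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(seed = 7000L + s,
                                        response_quality_shift = 0.15))
    tab <- suppressWarnings(
      compare_response_groups(co$candidates, co$clinical))
    p <- tab$p[tab$comparison == "PD vs nonPD"]
    if (length(p) == 1 && p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("covariate correlation table reports rho and p per pair", {
  set.seed(76)
  cov <- data.frame(tmb = runif(20), nal = rpois(20, 30),
                    n_fusions = rpois(20, 4))
  cov$nal <- cov$nal + cov$n_fusions * 10
  tab <- correlate_covariates(cov, list(c("tmb", "nal"),
                                        c("n_fusions", "nal")))
  expect_equal(nrow(tab), 2L)
  ref <- suppressWarnings(cor.test(cov$n_fusions, cov$nal,
                                   method = "spearman"))
  expect_equal(tab$rho[2], unname(ref$estimate), tolerance = 1e-10)
})
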