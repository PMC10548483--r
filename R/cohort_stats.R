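# Response-group comparisons of pooled top-10 AP score distributions and
# rank correlations between immunogenomic covariates, implemented against
# the closed-form definitions.

#' Welch's unequal-variance t-test
#'
#' t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2) with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param x,y Numeric samples, each with at least two values; at least
#'   one must have positive variance.
#' @return List of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop_config("welch_test needs at least 2 values per sample")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0)
    stop_config("welch_test undefined: both samples have zero variance")
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = p,
                 estimate = c(mean.x = mean(x), mean.y = mean(y)),
                 method = "Welch two-sample t-test",
                 alternative = "two.sided",
                 data.name = "x and y"),
            class = "htest")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties); the
#' two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs, neither
#'   constant.
#' @return List of class `htest` with `estimate` (rho) and `p.value`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_config("spearman_correlation needs at least 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop_config("rho undefined: a vector is constant")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(estimate = c(rho = rho), p.value = p,
                 parameter = c(n = n),
                 method = "Spearman rank correlation (t approximation)",
                 alternative = "two.sided",
                 data.name = "x and y"),
            class = "htest")
}

#' Pool a patient's top-ranked AP scores
#'
#' @param candidates Candidate table for one patient.
#' @param top_n Scores per patient, default 10; patients with fewer
#'   contribute all they have.
#' @return Numeric vector of the top `top_n` AP scores.
#' @export
top_ap_scores <- function(candidates, top_n = 10L) {
  if (nrow(candidates) == 0) return(numeric(0))
  s <- sort(candidates$ap_score, decreasing = TRUE)
  s[seq_len(min(top_n, length(s)))]
}

#' Welch comparisons of AP score distributions across response groups
#'
#' Each patient contributes its top-10 AP scores as separate pooled
#' observations per response group (`per_patient = TRUE` instead pools
#' one mean per patient).  Runs Welch tests for R vs PD, R vs SD,
#' SD vs PD and PD vs pooled non-PD (SD + R); comparisons touching an
#' empty group are skipped with a warning, as are patients without a
#' response label.
#'
#' @param candidates Candidate table with `patient_id` and `ap_score`.
#' @param clinical Clinical table with `patient_id` and `response`
#'   (`R`, `SD`, `PD` or `NA`).
#' @param top_n Scores pooled per patient, default 10.
#' @param per_patient Pool per-patient means instead of raw scores.
#' @return Data frame: comparison, n1, n2, mean1, mean2, t, df, p.
#' @export
compare_response_groups <- function(candidates, clinical, top_n = 10L,
                                    per_patient = FALSE) {
  assert_columns(clinical, c("patient_id", "response"), "clinical table")
  assert_columns(candidates, c("patient_id", "ap_score"),
                 "candidate table")
  unlabeled <- clinical$patient_id[is.na(clinical$response)]
  if (length(unlabeled) > 0)
    warning(sprintf("%d patient(s) without response label excluded",
                    length(unlabeled)), call. = FALSE)
  lab <- clinical[!is.na(clinical$response), , drop = FALSE]
  pooled <- lapply(split(lab$patient_id, lab$response), function(pids) {
    scores <- lapply(pids, function(p)
      top_ap_scores(candidates[candidates$patient_id == p, ,
                               drop = FALSE], top_n))
    if (per_patient)
      unlist(lapply(scores, function(s)
        if (length(s) > 0) mean(s) else NULL))
    else unlist(scores)
  })
  pooled <- pooled[vapply(pooled, length, integer(1)) > 0]
  pooled$nonPD <- c(pooled[["R"]], pooled[["SD"]])
  pairs <- list(c("R", "PD"), c("R", "SD"), c("SD", "PD"),
                c("PD", "nonPD"))
  rows <- lapply(pairs, function(pr) {
    a <- pooled[[pr[1]]]; b <- pooled[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("comparison %s vs %s skipped (empty or singleton group)",
                      pr[1], pr[2]), call. = FALSE)
      return(NULL)
    }
    wt <- if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: both groups constant; identical means carry no
      # evidence of a difference, distinct means are complete separation
      list(statistic = c(t = 0),
           parameter = c(df = NA_real_),
           p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    } else welch_test(a, b)
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               n1 = length(a), n2 = length(b),
               mean1 = mean(a), mean2 = mean(b),
               t = unname(wt$statistic), df = unname(wt$parameter),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(comparison = character(0))
  out
}

#' Spearman correlations between covariate columns
#'
#' @param covariates Data frame of per-patient covariates.
#' @param pairs List of 2-vectors of column names to correlate.
#' @return Data frame: x, y, rho, p, n.
#' @export
correlate_covariates <- function(covariates,
                                 pairs = list(c("tmb", "nal"))) {
  rows <- lapply(pairs, function(pr) {
    ct <- spearman_correlation(covariates[[pr[1]]], covariates[[pr[2]]])
    data.frame(x = pr[1], y = pr[2], rho = unname(ct$estimate),
               p = ct$p.value, n = unname(ct$parameter),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
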