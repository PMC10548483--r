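# Survival machinery built from first principles: product-limit
# estimation, the k-sample log-rank test, supervised optimal binning of a
# numeric covariate, and bivariate four-group stratification.
#
# Conventions (documented, since the source analyses leave them open):
# at tied times events precede censorings (both count as at risk at that
# time); the median is the smallest time with S(t) <= 0.5, undefined
# (NA) when the curve never reaches 0.5; binning splits low = {value <=
# threshold}; ties at the minimal p-value resolve to the smallest
# threshold.

as_records <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, is.data.frame, logical(1)))) {
    records <- do.call(rbind, Map(function(df, g) {
      df$group <- g; df
    }, records, seq_along(records)))
  }
  assert_columns(records, c("time", "event"), "survival records")
  if (nrow(records) == 0) stop_config("no survival records supplied")
  if (any(is.na(records$time)) || any(records$time <= 0))
    stop_config("survival times must be positive")
  if (!all(records$event %in% c(0, 1)))
    stop_config("event indicator must be 0 (censored) or 1 (event)")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with d_i
#' events among n_i at risk.  Subjects censored at an event time are at
#' risk for that event (events precede censorings at ties).
#'
#' @param records Data frame with columns `time` (> 0) and `event`
#'   (1 = observed, 0 = censored); alternatively `time` and `event`
#'   vectors via `km_estimate(data.frame(time=, event=))`.
#' @return Object of class `km_curve`: distinct event times, numbers at
#'   risk, event and censoring counts, the survival steps, `n` and
#'   `median` (NA when the curve stays above 0.5).
#' @export
km_estimate <- function(records) {
  records <- as_records(records)
  time <- records$time
  event <- records$event
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1),
                    numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5 + 1e-12)) ut[which(surv <= 0.5 + 1e-12)[1]]
  else NA_real_
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, surv = surv, n = n,
                 n_events_total = sum(event), median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events_total,
              if (is.na(x$median)) "not reached" else
                format(x$median, digits = 6)))
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  data.frame(time = object$time, n_risk = object$n_risk,
             n_event = object$n_event, n_censor = object$n_censor,
             surv = object$surv)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (days)",
                          ylab = "Survival probability", col = 1,
                          add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv[-length(x$surv)], each = 2), x$surv[length(x$surv)])
  if (length(x$time) == 0) { tt <- c(0, x$n); ss <- c(1, 1) }
  if (add) graphics::lines(tt, ss, col = col, ...)
  else graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                      ylab = ylab, col = col, ...)
  invisible(x)
}

#' k-sample log-rank test
#'
#' The standard observed-minus-expected chi-square: at every distinct
#' event time the per-group expected events are allocated by the at-risk
#' proportions, the covariance is the multivariate hypergeometric one,
#' and the statistic is the quadratic form over any k-1 groups, with
#' k - 1 degrees of freedom.  With more than two groups this is the
#' k-sample ("multivariate") generalization.
#'
#' @param records Data frame with `time`, `event` and `group`, or a list
#'   of per-group data frames with `time` and `event`.
#' @return Object of class `logrank_test` (also usable as a list):
#'   `statistic`, `df`, `p.value`, per-group observed and expected
#'   counts.
#' @export
logrank_test <- function(records) {
  records <- as_records(records)
  assert_columns(records, "group", "survival records")
  g <- factor(records$group)
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2) stop_config("log-rank test needs at least 2 non-empty groups")
  time <- records$time
  event <- records$event
  ut <- sort(unique(time[event == 1]))
  gi <- as.integer(g)
  # n_{ij}: at risk per group at each event time; d_{ij}: events
  nrisk <- vapply(ut, function(t)
    tabulate(gi[time >= t], nbins = k), numeric(k))
  devent <- vapply(ut, function(t)
    tabulate(gi[time == t & event == 1], nbins = k), numeric(k))
  if (length(ut) == 0)
    return(structure(list(statistic = 0, df = k - 1L, p.value = 1,
                          observed = rep(0, k), expected = rep(0, k),
                          groups = levels(g)), class = "logrank_test"))
  nrisk <- matrix(nrisk, nrow = k)
  devent <- matrix(devent, nrow = k)
  Nj <- colSums(nrisk)
  Dj <- colSums(devent)
  O <- rowSums(devent)
  E <- rowSums(sweep(nrisk, 2, Dj / Nj, "*"))
  # covariance of (O - E): sum_j D_j (N_j - D_j)/(N_j - 1) *
  #   [diag(p_ij) - p_ij p_i'j], p_ij = n_ij / N_j
  V <- matrix(0, k, k)
  for (j in seq_along(ut)) {
    if (Nj[j] <= 1) next
    p <- nrisk[, j] / Nj[j]
    cj <- Dj[j] * (Nj[j] - Dj[j]) / (Nj[j] - 1)
    V <- V + cj * (diag(p, k) - tcrossprod(p))
  }
  d <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  Vinv <- tryCatch(solve(Vk), error = function(e) pseudo_inverse(Vk))
  stat <- max(0, as.numeric(t(d) %*% Vinv %*% d))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(g)),
                 expected = stats::setNames(E, levels(g)),
                 groups = levels(g)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  tab <- data.frame(group = x$groups, observed = x$observed,
                    expected = round(x$expected, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Supervised optimal binning of a numeric covariate against survival
#'
#' Evaluates, for every covariate value observed in the data, the
#' two-group log-rank p-value of the split low = {value <= t} versus
#' high = {value > t}; only splits leaving at least `min_group` patients
#' on each side are admissible, and the admissible threshold with the
#' smallest p-value is chosen (ties resolve to the smallest threshold).
#' Only observed values are tried because they are the only thresholds
#' that change group composition.
#'
#' @param covariate Named numeric vector (patient id to value).
#' @param records Data frame with `patient_id`, `time`, `event`.
#' @param min_group Minimum patients per bin, default 10.
#' @return Object of class `binning_result`: `threshold`, `p.value`, the
#'   full `landscape` (threshold, p, n_low, n_high, admissible) and the
#'   `groups` assignment.
#' @export
optimal_binning <- function(covariate, records, min_group = 10L) {
  records <- as_records(records)
  assert_columns(records, "patient_id", "survival records")
  if (is.null(names(covariate)))
    stop_config("covariate must be named by patient id")
  miss <- setdiff(records$patient_id, names(covariate))
  if (length(miss) > 0)
    stop_config("covariate undefined for patient(s): %s",
                paste(miss, collapse = ", "))
  value <- covariate[records$patient_id]
  thresholds <- sort(unique(value))
  landscape <- do.call(rbind, lapply(thresholds, function(t) {
    low <- value <= t
    n_low <- sum(low); n_high <- sum(!low)
    p <- if (n_low > 0 && n_high > 0) {
      rec <- records
      rec$group <- ifelse(low, "low", "high")
      logrank_test(rec)$p.value
    } else NA_real_
    data.frame(threshold = t, p = p, n_low = n_low, n_high = n_high,
               admissible = n_low >= min_group & n_high >= min_group)
  }))
  adm <- landscape[landscape$admissible & !is.na(landscape$p), ,
                   drop = FALSE]
  if (nrow(adm) == 0)
    stop_config(paste0("no admissible split: every threshold leaves a ",
                       "group below %d patients (n = %d%s)"),
                min_group, nrow(records),
                if (length(thresholds) == 1) ", covariate is constant"
                else "")
  best <- adm[order(adm$p, adm$threshold), ][1, ]
  groups <- stats::setNames(ifelse(value <= best$threshold, "low", "high"),
                            records$patient_id)
  structure(list(threshold = best$threshold, p.value = best$p,
                 n_low = best$n_low, n_high = best$n_high,
                 landscape = landscape, groups = groups,
                 min_group = min_group),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  cat(sprintf(paste0("Supervised optimal binning: threshold = %g ",
                     "(low n = %d, high n = %d)\n"),
              x$threshold, x$n_low, x$n_high))
  cat(sprintf("  minimal log-rank p = %.4g over %d thresholds (%d admissible, min group %d)\n",
              x$p.value, nrow(x$landscape), sum(x$landscape$admissible),
              x$min_group))
  invisible(x)
}

#' @export
plot.binning_result <- function(x, xlab = "Threshold",
                                ylab = "Log-rank p-value (log10)", ...) {
  ls <- x$landscape[!is.na(x$landscape$p), ]
  graphics::plot(ls$threshold, log10(ls$p), pch = ifelse(ls$admissible,
                                                         19, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::points(x$threshold, log10(x$p.value), col = "orange",
                   pch = 19, cex = 1.6)
  graphics::legend("bottomright",
                   legend = c("admissible", "inadmissible", "chosen"),
                   pch = c(19, 1, 19), col = c(1, 1, "orange"), bty = "n")
  invisible(x)
}

#' Bivariate four-group stratification
#'
#' Crosses two thresholded covariates (typically at their univariate
#' optimal-binning thresholds) into the four groups LL, LH, HL, HH
#' (first letter: covariate 1 low/high; second: covariate 2), runs the
#' k-sample log-rank test over the non-empty groups and reports the
#' per-group KM medians.
#'
#' @param cov1,cov2 Named numeric vectors (patient id to value).
#' @param thr1,thr2 Split thresholds (low = value <= threshold).
#' @param records Data frame with `patient_id`, `time`, `event`.
#' @return Object of class `bivariate_km`: `groups` assignment,
#'   `logrank` result, per-group `medians` and `curves`.
#' @export
bivariate_stratify <- function(cov1, cov2, thr1, thr2, records) {
  records <- as_records(records)
  assert_columns(records, "patient_id", "survival records")
  v1 <- cov1[records$patient_id]
  v2 <- cov2[records$patient_id]
  if (anyNA(v1) || anyNA(v2))
    stop_config("both covariates must be defined for every patient")
  lab <- paste0(ifelse(v1 <= thr1, "L", "H"),
                ifelse(v2 <= thr2, "L", "H"))
  rec <- records
  rec$group <- lab
  lr <- logrank_test(rec)
  curves <- lapply(split(rec, rec$group), km_estimate)
  medians <- vapply(curves, function(cv) cv$median, numeric(1))
  structure(list(groups = stats::setNames(lab, records$patient_id),
                 thresholds = c(thr1 = thr1, thr2 = thr2),
                 logrank = lr, medians = medians, curves = curves),
            class = "bivariate_km")
}

#' @export
print.bivariate_km <- function(x, ...) {
  cat("Bivariate four-group survival stratification\n")
  cat(sprintf("  thresholds: cov1 <= %g, cov2 <= %g\n",
              x$thresholds[["thr1"]], x$thresholds[["thr2"]]))
  for (g in names(x$medians))
    cat(sprintf("  %s: n = %d, median PFS = %s\n", g, x$curves[[g]]$n,
                if (is.na(x$medians[[g]])) "not reached" else
                  format(x$medians[[g]], digits = 6)))
  cat(sprintf("  log-rank chi-square = %.4f on %d df, p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p.value))
  invisible(x)
}

#' @export
plot.bivariate_km <- function(x, xlab = "Time (days)",
                              ylab = "Survival probability", ...) {
  cols <- stats::setNames(seq_along(x$curves) + 1, names(x$curves))
  first <- TRUE
  for (g in names(x$curves)) {
    plot(x$curves[[g]], col = cols[[g]], add = !first, xlab = xlab,
         ylab = ylab, ...)
    first <- FALSE
  }
  graphics::legend("topright", legend = names(x$curves),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
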