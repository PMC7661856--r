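#' Read a clinical survival table
#'
#' Tab-separated, columns `sample_id`, `time` (positive, cohort units),
#' `event` (0 = censored, 1 = death), plus any covariate columns.
#'
#' @param path Path to the TSV.
#' @return Data frame with `event` coerced to logical.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss) > 0) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(cl$time <= 0)) stop("survival times must be positive")
  cl$event <- as.logical(cl$event)
  cl
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored observations leave the risk set without producing a drop in the
#' survival curve.
#'
#' @param time Positive event/censoring times.
#' @param event Logical (or 0/1): `TRUE` = death observed.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv` (one row per observed time point, survival non-increasing).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("no observations")
  if (any(time <= 0)) stop("survival times must be positive")
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

# Two-group log-rank building block: observed/expected events and
# hypergeometric variance for group 1 across all distinct event times.
# g1 is logical (TRUE = group 1). O(n log n), used by the cutpoint scan.
.logrank_stat <- function(time, event, g1) {
  o <- order(time)
  tt <- time[o]; ee <- event[o]; z <- g1[o]
  ut <- unique(tt)                       # sorted distinct times
  idx <- match(tt, ut)
  ones <- rep(1, length(tt))
  d <- as.vector(rowsum(ee + 0, idx))    # events at each distinct time
  d1 <- as.vector(rowsum((ee & z) + 0, idx))
  cnt <- as.vector(rowsum(ones, idx))    # observations at each time
  c1 <- as.vector(rowsum(z + 0, idx))
  n <- rev(cumsum(rev(cnt)))             # at risk at each distinct time
  n1 <- rev(cumsum(rev(c1)))
  k <- d > 0
  n_k <- n[k]; n1_k <- n1[k]; d_k <- d[k]; d1_k <- d1[k]
  obs <- sum(d1_k)
  expct <- sum(d_k * n1_k / n_k)
  vterm <- ifelse(n_k > 1,
                  d_k * (n1_k / n_k) * (1 - n1_k / n_k) *
                    (n_k - d_k) / (n_k - 1),
                  0)
  v <- sum(vterm)
  list(obs = obs, expected = expct, var = v,
       z = if (v > 0) (obs - expct) / sqrt(v) else NA_real_)
}

#' Two-group log-rank test
#'
#' Chi-square form of the log-rank test with hypergeometric variance at
#' each distinct event time; p-value from the chi-square distribution with
#' one degree of freedom.
#'
#' @param time Positive times for all subjects.
#' @param event Logical event indicators.
#' @param group Two-level group labels (factor, character or logical).
#' @return List of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (for the first group level), `n`.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("logrank_test requires exactly two non-empty groups")
  }
  if (sum(event) == 0) stop("no events observed; log-rank test degenerate")
  s <- .logrank_stat(time, event, group == levels(droplevels(group))[1])
  if (s$var <= 0) stop("zero log-rank variance; degenerate input")
  chi <- (s$obs - s$expected)^2 / s$var
  res <- list(chi_square = chi, df = 1L,
              p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
              observed = s$obs, expected = s$expected, n = length(time))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (df = 1), p = %.4g, n = %d\n",
              x$chi_square, x$p_value, x$n))
  invisible(x)
}

# Approximate p-value for the maximally selected standardized log-rank
# statistic (supremum of a standardized Brownian bridge over
# [minprop, 1 - minprop]; Miller-Siegmund improved Bonferroni form).
.maxsel_p <- function(b, minprop) {
  if (!is.finite(b) || b <= 0) return(1)
  e1 <- minprop; e2 <- 1 - minprop
  p <- 4 * stats::dnorm(b) / b +
    stats::dnorm(b) * (b - 1 / b) * log((e2 * (1 - e1)) / ((1 - e2) * e1))
  min(1, max(stats::pchisq(b^2, 1, lower.tail = FALSE), min(p, 1)))
}

#' Optimal survival cutpoint by the maximally selected log-rank statistic
#'
#' Scans every admissible dichotomisation of a continuous marker and
#' returns the threshold maximising the absolute standardized two-group
#' log-rank statistic. Candidate thresholds are midpoints between
#' consecutive distinct marker values; a split is admissible when both
#' groups contain at least `ceil(minprop * n)` subjects. The "high" group
#' is `marker > threshold`. Ties in the maximal statistic resolve to the
#' smallest threshold.
#'
#' Two p-values are reported: `naive_logrank_p`, the plain log-rank p at
#' the selected threshold (biased low, because the threshold was chosen to
#' maximise the statistic), and `adjusted_p`, an approximate
#' selection-corrected p for the maximally selected statistic.
#'
#' @param marker Numeric marker values, optionally named by sample.
#' @param time,event Survival outcome, parallel to `marker`.
#' @param minprop Minimum fraction of subjects per group (default 0.1).
#' @return List of class `cutpoint_result`: `threshold`, `statistic`
#'   (maximal |standardized log-rank|), `naive_logrank_p`, `adjusted_p`,
#'   `n_high`, `n_low`, `group_assignment` (factor low/high, named when
#'   `marker` is named), `minprop`, `n_candidates`.
#' @export
find_optimal_cutpoint <- function(marker, time, event, minprop = 0.1) {
  stopifnot(length(marker) == length(time), length(time) == length(event),
            minprop > 0, minprop < 0.5)
  if (any(is.na(marker))) stop("marker contains missing values")
  event <- as.logical(event)
  n <- length(marker)
  if (sum(event) == 0) stop("no events observed; cutpoint undefined")
  sv <- sort(unique(marker))
  if (length(sv) < 2) stop("all marker values identical; no admissible split")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  min_size <- ceiling(minprop * n)
  stat <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    hi <- marker > cand[i]
    if (sum(hi) < min_size || (n - sum(hi)) < min_size) next
    s <- .logrank_stat(time, event, hi)
    if (!is.na(s$z)) stat[i] <- abs(s$z)
  }
  if (all(is.na(stat))) stop("no admissible split under minprop = ", minprop)
  best <- which.max(stat)   # first maximum = smallest threshold
  thr <- cand[best]
  hi <- marker > thr
  grp <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  names(grp) <- names(marker)
  lr <- logrank_test(time, event, grp)
  res <- list(threshold = thr,
              statistic = stat[best],
              naive_logrank_p = lr$p_value,
              adjusted_p = .maxsel_p(stat[best], minprop),
              n_high = sum(hi), n_low = n - sum(hi),
              group_assignment = grp,
              minprop = minprop,
              n_candidates = sum(!is.na(stat)))
  class(res) <- "cutpoint_result"
  res
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Maximally selected log-rank cutpoint\n",
    "  threshold: %.4g  (high: n = %d, low: n = %d)\n",
    "  max standardized statistic: %.3f\n",
    "  naive log-rank p: %.4g   selection-adjusted p: %.4g\n"),
    x$threshold, x$n_high, x$n_low, x$statistic,
    x$naive_logrank_p, x$adjusted_p))
  invisible(x)
}

#' Dichotomise a marker at a threshold
#'
#' @param marker Numeric vector, optionally named.
#' @param threshold Cut value; "high" is strictly greater.
#' @return Factor with levels `low`, `high`, names preserved.
#' @export
dichotomize <- function(marker, threshold) {
  g <- factor(ifelse(marker > threshold, "high", "low"),
              levels = c("low", "high"))
  names(g) <- names(marker)
  g
}

#' Multivariate Cox proportional hazards fit
#'
#' Fits a Cox model (partial likelihood, Efron tie handling) of
#' `Surv(time, event)` on the requested covariates and tabulates hazard
#' ratios with Wald 95% confidence intervals and p-values. Covariates with
#' no variation are dropped with a warning; non-convergence and singular
#' fits are flagged through `convergence`, never silently.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param reference Optional named list giving the reference level of
#'   categorical covariates, e.g. `list(score_group = "high")`.
#' @return List of class `cox_fit`: `table` (term, coef, hr, ci_low,
#'   ci_high, se, p_value), `convergence`, `reference`, `n`, `n_events`,
#'   and the underlying `model`.
#' @export
cox_fit <- function(data, covariates, reference = NULL) {
  stopifnot(all(c("time", "event") %in% names(data)),
            length(covariates) > 0,
            all(covariates %in% names(data)))
  d <- data
  d$event <- as.logical(d$event)
  keep <- character(0)
  for (cv in covariates) {
    if (is.character(d[[cv]]) || is.logical(d[[cv]])) {
      d[[cv]] <- factor(d[[cv]])
    }
    if (!is.null(reference[[cv]])) {
      d[[cv]] <- stats::relevel(factor(d[[cv]]), ref = reference[[cv]])
    }
    vals <- d[[cv]][!is.na(d[[cv]])]
    if (length(unique(vals)) < 2) {
      warning("covariate '", cv, "' has no variation; dropped from the model")
    } else {
      keep <- c(keep, cv)
    }
  }
  if (length(keep) == 0) stop("no identifiable covariates left to fit")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(keep, collapse = " + ")))
  converged <- TRUE
  diagnostics <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    converged <- FALSE
    diagnostics <- c(diagnostics, "singular fit: NA coefficient(s)")
  }
  se <- sqrt(diag(fit$var))
  zq <- stats::qnorm(0.975)
  tab <- data.frame(
    term = names(cf),
    coef = as.numeric(cf),
    hr = exp(as.numeric(cf)),
    ci_low = exp(as.numeric(cf) - zq * se),
    ci_high = exp(as.numeric(cf) + zq * se),
    se = se,
    p_value = 2 * stats::pnorm(-abs(as.numeric(cf) / se)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  res <- list(table = tab, convergence = converged,
              diagnostics = diagnostics,
              reference = reference,
              n = fit$n, n_events = fit$nevent, model = fit)
  class(res) <- "cox_fit"
  res
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards fit (Efron ties): n = %d, events = %d\n",
              x$n, x$n_events))
  tab <- x$table
  tab$ci95 <- sprintf("%.*f-%.*f", digits, tab$ci_low, digits, tab$ci_high)
  print(tab[, c("term", "hr", "ci95", "p_value")], digits = digits,
        row.names = FALSE)
  if (!x$convergence) {
    cat("WARNING: fit did not converge cleanly:\n  ",
        paste(x$diagnostics, collapse = "\n  "), "\n")
  }
  invisible(x)
}
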