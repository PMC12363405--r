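# Clinical outcome statistics, implemented from first principles:
# product-limit (Kaplan-Meier) estimation, the log-rank test,
# Mantel-Haenszel-style hazard ratios from observed/expected event counts,
# reverse-censor follow-up, the exact Fisher 2x2 test and Pearson
# correlation. Ties are handled with the standard convention that events
# precede censorings at equal times.

# shared O/E/V machinery over pooled event times -------------------------------

km_compute <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (!length(times)) abort("Empty survival input.")
  if (any(times < 0)) abort("Survival times must be >= 0.")
  events <- as.logical(events)
  ut <- sort(unique(times[events]))
  n_risk <- vapply(ut, function(t) sum(times >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), integer(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  steps <- tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                          n_censor = n_censor, surv = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  list(steps = steps, n = length(times), n_events = sum(events),
       median = med, max_time = max(times))
}

logrank_compute <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("Exactly two groups are required.")
  events <- as.logical(events)
  lv <- levels(g)
  ut <- sort(unique(times[events]))
  o_a <- e_a <- v <- mh_num <- mh_den <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at)
    n_a <- sum(at & g == lv[1])
    d <- sum(times == t & events)
    d_a <- sum(times == t & events & g == lv[1])
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    mh_num <- mh_num + d_a * (n - n_a) / n
    mh_den <- mh_den + (d - d_a) * n_a / n
  }
  o_b <- sum(events & g == lv[2])
  e_b <- (o_a + o_b) - e_a
  list(levels = lv, o_a = o_a, e_a = e_a, o_b = o_b, e_b = e_b, v = v,
       mh_num = mh_num, mh_den = mh_den)
}

# Kaplan-Meier ----------------------------------------------------------------

#' Kaplan-Meier product-limit survival fit
#'
#' @param data A data frame.
#' @param time,event Columns (tidy-eval) holding follow-up time and the
#'   event indicator (`TRUE`/1 = event, `FALSE`/0 = censored). Events
#'   precede censorings at tied times.
#' @return A `km_fit` object: step table, `n`, `n_events`, `median` (first
#'   time the estimate drops to 0.5 or below; `NA` if never reached).
#' @export
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3), e = c(TRUE, TRUE, FALSE))
#' km_fit(d, t, e)
km_fit <- function(data, time, event) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  out <- km_compute(t, e)
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n =", x$n, ", events =", x$n_events, ", median =",
      if (is.na(x$median)) "not reached" else format(x$median), "\n")
  invisible(x)
}

#' Survival estimate at given times
#'
#' @param fit A [km_fit()] object.
#' @param t Query times.
#' @return Step-function survival estimates (1 before the first event; `NA`
#'   beyond the last observed time).
#' @export
surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  s <- c(1, fit$steps$surv)
  idx <- findInterval(t, fit$steps$time)
  out <- s[idx + 1L]
  out[t > fit$max_time] <- NA_real_
  out
}

#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) x$steps

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, median_survival = x$median)
}

# log-rank and hazard ratio ---------------------------------------------------

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over pooled event times with
#' hypergeometric variance, referred to chi-square on 1 df. With no events
#' the statistic is undefined and p = 1 is returned with a warning.
#'
#' @param data A data frame.
#' @param time,event,group Columns (tidy-eval); `group` must have two
#'   levels.
#' @return A `logrank_test` object with `statistic`, `p_value`, per-group
#'   observed and expected event counts and the variance.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- dplyr::pull(data, {{ group }})
  oe <- logrank_compute(t, e, g)
  if (oe$o_a + oe$o_b == 0 || oe$v == 0) {
    warn("No events (or no variance): log-rank p set to 1.")
    stat <- NA_real_
    p <- 1
  } else {
    stat <- (oe$o_a - oe$e_a)^2 / oe$v
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(c(oe, list(statistic = stat, p_value = p)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  %s: O = %d, E = %.3g | %s: O = %d, E = %.3g\n",
              x$levels[1], x$o_a, x$e_a, x$levels[2], x$o_b, x$e_b))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 observed_a = x$o_a, expected_a = x$e_a,
                 observed_b = x$o_b, expected_b = x$e_b)
}

#' Mantel-Haenszel hazard ratio
#'
#' Stratifies follow-up into the 2x2 table at each distinct event time and
#' combines them with the Mantel-Haenszel estimator
#' HR = sum(d_A n_B / n) / sum(d_B n_A / n) (first group level as
#' numerator), which is consistent under proportional hazards even for
#' extreme ratios. `method = "oe"` gives the log-rank-style ratio of
#' observed over expected events, (O_A/E_A)/(O_B/E_B); the two agree near
#' HR = 1 but the O/E ratio is attenuated toward 1 for strong effects. The
#' log-scale confidence interval uses SE = sqrt(1/E_A + 1/E_B). A group
#' with zero events yields a degenerate HR and a one-sided interval with a
#' warning.
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level.
#' @param method `"mh"` (Mantel-Haenszel, default) or `"oe"`
#'   (observed/expected ratio).
#' @return One-row tibble: `group_a`, `group_b`, `hr`, `conf_low`,
#'   `conf_high`, `o_a`, `e_a`, `o_b`, `e_b`.
#' @export
mh_hazard_ratio <- function(data, time, event, group, conf_level = 0.95,
                            method = c("mh", "oe")) {
  method <- match.arg(method)
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- dplyr::pull(data, {{ group }})
  oe <- logrank_compute(t, e, g)
  z <- qnorm(1 - (1 - conf_level) / 2)
  eps <- .Machine$double.eps
  degenerate <- oe$o_a == 0 || oe$o_b == 0
  if (degenerate) {
    warn("Zero events in one group: hazard ratio degenerate, one-sided CI.")
  }
  hr <- if (method == "mh") {
    (oe$mh_num / max(oe$mh_den, eps))
  } else {
    (oe$o_a / oe$e_a) / max(oe$o_b / oe$e_b, eps)
  }
  se <- sqrt(1 / max(oe$e_a, eps) + 1 / max(oe$e_b, eps))
  lo <- if (oe$o_a == 0) 0 else exp(log(max(hr, eps)) - z * se)
  hi <- if (oe$o_b == 0) Inf else exp(log(max(hr, eps)) + z * se)
  tibble::tibble(group_a = oe$levels[1], group_b = oe$levels[2], hr = hr,
                 conf_low = lo, conf_high = hi, o_a = oe$o_a, e_a = oe$e_a,
                 o_b = oe$o_b, e_b = oe$e_b)
}

#' Median potential follow-up by reverse Kaplan-Meier
#'
#' Inverts the censoring indicator (censorings become events) and returns
#' the median of that curve; with no censored observations the median
#' potential follow-up is undefined.
#'
#' @inheritParams km_fit
#' @return A list with `median_followup` and the underlying `km_fit`.
#' @export
reverse_km_followup <- function(data, time, event) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  fit <- km_compute(t, !as.logical(e))
  class(fit) <- "km_fit"
  list(median_followup = fit$median, fit = fit)
}

# exact tests and correlation -------------------------------------------------

#' Exact Fisher test for a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration: the sum of probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (up to a 1e-7 relative tolerance, the usual
#' convention).
#'
#' @param x A 2x2 matrix of non-negative integer counts.
#' @return List of class `fisher_exact` with `p_value`, `odds_ratio`
#'   (sample odds ratio, ad/bc) and the table.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(8, 1, 0, 7), 2))$p_value  # 0.0014
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort("`x` must be a 2x2 matrix.")
  if (any(x < 0) || any(x != round(x))) abort("Counts must be non-negative integers.")
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    # a degenerate margin admits a single table
    return(structure(list(p_value = 1, odds_ratio = NA_real_, table = x),
                     class = "fisher_exact"))
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(x[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  structure(list(p_value = min(1, p), odds_ratio = or, table = x),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat(sprintf("<fisher_exact> two-sided p = %.4g, odds ratio = %.4g\n",
              x$p_value, x$odds_ratio))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation of two columns; errors on fewer than three
#' complete pairs or zero variance.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @return A single numeric correlation.
#' @export
pearson_r <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("Pearson correlation needs n >= 3 complete pairs.")
  dx <- xv - mean(xv); dy <- yv - mean(yv)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) abort("Pearson correlation undefined at zero variance.")
  sum(dx * dy) / sqrt(sx * sy)
}
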