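#' Kaplan-Meier product-limit survival estimate
#'
#' Standard product-limit estimator over the distinct observed event times
#' with Greenwood variance. At tied times, deaths are processed before
#' censorings (both are counted in the risk set at that time; censored
#' subjects leave afterwards).
#'
#' @param data `data.frame` with columns `time` (>= 0) and `event`
#'   (1 = death observed, 0 = right-censored).
#' @return `data.frame` of class `km_curve`, one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `n_censor` (censorings in
#'   `[time, next event time)`), `surv`, `greenwood_var`, `std_err`.
#' @examples
#' kaplan_meier(data.frame(time = c(1, 2, 2, 3), event = c(1, 1, 0, 1)))
#' @export
kaplan_meier <- function(data) {
  check_survival_data(data)
  if (nrow(data) < 1L)
    mrdam_stop("need at least one subject", "mrdam_validation_error")
  tt <- sort(unique(data$time[data$event == 1]))
  surv <- 1
  gw <- 0
  rows <- lapply(tt, function(t) {
    n_risk <- sum(data$time >= t)
    n_event <- sum(data$time == t & data$event == 1)
    surv <<- surv * (1 - n_event / n_risk)
    gw <<- gw + n_event / (n_risk * (n_risk - n_event))
    data.frame(time = t, n_risk = n_risk, n_event = n_event,
               n_censor = NA_integer_, surv = surv,
               greenwood_var = surv^2 * gw,
               std_err = surv * sqrt(gw))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
               n_censor = integer(0), surv = numeric(0),
               greenwood_var = numeric(0), std_err = numeric(0))
  if (nrow(out)) {
    bounds <- c(out$time[-1], Inf)
    out$n_censor <- vapply(seq_len(nrow(out)), function(i)
      sum(data$time >= out$time[i] & data$time < bounds[i] & data$event == 0),
      numeric(1))
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", nrow(x), "event time(s)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

check_survival_data <- function(data) {
  if (!all(c("time", "event") %in% names(data)))
    mrdam_stop("survival data needs columns time and event", "mrdam_format_error")
  if (any(data$time < 0))
    mrdam_stop("negative survival times", "mrdam_validation_error")
  if (!all(data$event %in% c(0, 1)))
    mrdam_stop("event must be 0 (censored) or 1 (death)", "mrdam_validation_error")
  invisible(data)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct pooled event time, the expected number of deaths in
#' group A comes from the hypergeometric mean `d_j * n_Aj / n_j`, with
#' hypergeometric variance
#' `d_j (n_Aj/n_j)(1 - n_Aj/n_j)(n_j - d_j)/(n_j - 1)`; the statistic is
#' `(O_A - E_A)^2 / V` on 1 degree of freedom. Symmetric in the group
#' labels and invariant under strictly monotone time transformations.
#'
#' @param a,b `data.frame`s with columns `time`, `event` (both non-empty;
#'   at least one event overall).
#' @return List of class `logrank_result`: `chisq`, `df`, `pval`,
#'   `observed` and `expected` per group.
#' @examples
#' a <- data.frame(time = 1:3, event = 1)
#' b <- data.frame(time = 4:6, event = 1)
#' logrank_test(a, b)
#' @export
logrank_test <- function(a, b) {
  check_survival_data(a); check_survival_data(b)
  if (nrow(a) < 1L || nrow(b) < 1L)
    mrdam_stop("both groups must be non-empty", "mrdam_validation_error")
  if (sum(a$event) + sum(b$event) == 0)
    mrdam_stop("log-rank undefined with no events", "mrdam_validation_error")
  times <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  O <- E <- V <- 0
  for (t in times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t)
    d1 <- sum(a$time == t & a$event == 1)
    d2 <- sum(b$time == t & b$event == 1)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  total_d <- sum(a$event) + sum(b$event)
  structure(list(chisq = chisq, df = 1L,
                 pval = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 observed = c(a = O, b = total_d - O),
                 expected = c(a = E, b = total_d - E)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$pval))
  cat(sprintf("  observed: a=%g b=%g; expected: a=%.3g b=%.3g\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}
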