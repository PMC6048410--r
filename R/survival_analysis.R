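#' @title Survival analysis
#' @name survival_analysis
#' @description
#' Product-limit (Kaplan-Meier) estimation, the k-sample log-rank test and
#' univariate Cox proportional-hazards regression (Newton iterations on the
#' partial likelihood with Efron handling of tied event times). All three
#' are implemented directly so that their agreement with the standard
#' `survival` package can serve as an independent cross-check in the test
#' suite.
NULL

validate_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  drop <- time == 0 & event == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " record(s) censored at time 0 (uninformative)")
  }
  list(time = time[!drop], event = as.integer(event[!drop]))
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i). Subjects
#' censored exactly at an event time are counted at risk for that time
#' (standard convention).
#'
#' @param time follow-up in days, >= 0.
#' @param event 1 = death (any cause), 0 = censored.
#' @return data.frame (class `km_curve`) with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event) {
  v <- validate_surv(time, event)
  if (length(v$time) == 0L) stop("no records")
  etimes <- sort(unique(v$time[v$event == 1L]))
  if (length(etimes) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    class(out) <- c("km_curve", class(out))
    return(out)
  }
  n_risk <- vapply(etimes, function(t) sum(v$time >= t), integer(1L))
  n_event <- vapply(etimes, function(t) sum(v$time == t & v$event == 1L), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = etimes, n_risk = n_risk, n_event = n_event, surv = surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' k-sample log-rank test
#'
#' Observed-minus-expected event counts with hypergeometric variance at each
#' distinct event time, combined into a chi-square statistic with k - 1 df.
#'
#' @param time,event as in [km_estimate()].
#' @param group stratum labels (>= 2 non-empty strata, >= 1 event overall).
#' @return list `statistic`, `df`, `p_value`, `observed`, `expected`
#'   (class `LogrankResult`).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0L)) stop("empty stratum")
  if (nlevels(group) < 2L) stop("log-rank needs >= 2 strata")
  v <- validate_surv(time, event)
  group <- group[!(time == 0 & event == 0)]
  time <- v$time; event <- v$event
  if (sum(event) == 0L) stop("no events observed")
  k <- nlevels(group)
  etimes <- sort(unique(time[event == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in etimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1L)
    n_jt <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1L))
    d_jt <- vapply(levels(group), function(g) sum(time == t & event == 1L & group == g),
                   numeric(1L))
    O <- O + d_jt
    E <- E + d_t * n_jt / n_t
    if (n_t > 1) {
      # V_jl = d(n-d)/((n-1)n^2) * (delta_jl * n_j * n - n_j * n_l)
      c_t <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      V <- V + c_t * (diag(n_jt * n_t, k) - outer(n_jt, n_jt))
    }
  }
  idx <- seq_len(k - 1L)
  diffv <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- if (all(abs(diffv) < 1e-12)) 0 else
    as.numeric(t(diffv) %*% solve(Vsub, diffv))
  structure(list(statistic = stat, df = k - 1L,
                 p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "LogrankResult")
}

# Efron partial-likelihood pieces for a single covariate. Returns the log
# likelihood, score and information at beta.
cox_efron_derivs <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  etimes <- sort(unique(time[event == 1L]))
  loglik <- score <- info <- 0
  for (t in etimes) {
    risk <- time >= t
    dead <- time == t & event == 1L
    d <- sum(dead)
    s0r <- sum(w[risk]);  s1r <- sum(w[risk] * x[risk]);  s2r <- sum(w[risk] * x[risk]^2)
    s0d <- sum(w[dead]);  s1d <- sum(w[dead] * x[dead]);  s2d <- sum(w[dead] * x[dead]^2)
    loglik <- loglik + sum(eta[dead])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      a0 <- s0r - f * s0d; a1 <- s1r - f * s1d; a2 <- s2r - f * s2d
      loglik <- loglik - log(a0)
      score <- score - a1 / a0
      info <- info + a2 / a0 - (a1 / a0)^2
    }
    score <- score + sum(x[dead])
  }
  list(loglik = loglik, score = score, info = info)
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton iteration (Efron tie
#' handling). Reports the log hazard ratio, its standard error, the Wald
#' p-value, and the score test at beta = 0 (which equals the 2-group
#' log-rank statistic for a binary covariate without ties).
#'
#' @param time,event as in [km_estimate()].
#' @param covariate numeric (binary or continuous), non-constant.
#' @param tol convergence tolerance on the score, default 1e-9.
#' @param max_iter maximum Newton steps, default 50.
#' @return list (class `CoxResult`): `coef` (log HR), `hr`, `se`, `z`,
#'   `p_value` (Wald), `score_statistic`, `score_p_value`, `iterations`,
#'   `converged`.
#' @export
cox_univariate <- function(time, event, covariate, tol = 1e-9, max_iter = 50L) {
  v <- validate_surv(time, event)
  covariate <- covariate[!(time == 0 & event == 0)]
  time <- v$time; event <- v$event
  if (sum(event) < 1L) stop("need >= 1 event")
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  # score test at beta = 0
  d0 <- cox_efron_derivs(0, time, event, covariate)
  score_stat <- d0$score^2 / d0$info
  beta <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d <- cox_efron_derivs(beta, time, event, covariate)
    if (!is.finite(d$loglik) || d$info <= 0)
      stop("Cox fit diagnostic: non-finite likelihood or non-positive information ",
           "(possible monotone likelihood / complete separation)")
    step <- d$score / d$info
    beta <- beta + step
    if (abs(d$score) < tol || abs(step) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("Cox fit did not converge in ", max_iter,
         " iterations (possible monotone likelihood)")
  if (abs(beta) > 15)
    stop("Cox fit diagnostic: |log HR| > 15 suggests complete separation")
  dfin <- cox_efron_derivs(beta, time, event, covariate)
  se <- sqrt(1 / dfin$info)
  z <- beta / se
  structure(list(coef = beta, hr = exp(beta), se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 score_statistic = score_stat,
                 score_p_value = stats::pchisq(score_stat, 1, lower.tail = FALSE),
                 iterations = iter, converged = converged),
            class = "CoxResult")
}

#' Plot Kaplan-Meier curves in a fixed day window
#'
#' Step-function plot truncated at `t_max` (a display default, not a data
#' filter: events beyond the window still enter every statistic). Empty
#' strata are skipped with a warning.
#'
#' @param curves named list of `km_curve` objects ([km_estimate()]).
#' @param t_max right edge of the x axis in days, default 4000.
#' @param file optional path; when given, a PDF is written there.
#' @param col line colors recycled over strata.
#' @return invisibly, the list of curves drawn.
#' @export
km_plot_window <- function(curves, t_max = 4000, file = NULL,
                           col = seq_along(curves)) {
  keep <- vapply(curves, function(cu) nrow(cu) > 0L, logical(1L))
  if (any(!keep)) warning("excluding ", sum(!keep), " empty stratum/strata from plot")
  curves <- curves[keep]
  if (length(curves) == 0L) stop("no non-empty curves to plot")
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = c(0, t_max), ylim = c(0, 1),
                 xlab = "Days", ylab = "Overall survival", las = 1)
  for (i in seq_along(curves)) {
    cu <- curves[[i]][curves[[i]]$time <= t_max, , drop = FALSE]
    s_end <- if (nrow(cu) > 0L) cu$surv[nrow(cu)] else 1
    graphics::lines(c(0, cu$time, t_max), c(1, cu$surv, s_end),
                    type = "s", col = col[[i]])
  }
  if (!is.null(names(curves)))
    graphics::legend("bottomleft", legend = names(curves), lty = 1,
                     col = col[seq_along(curves)], bty = "n")
  invisible(curves)
}
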