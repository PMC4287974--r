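#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with the usual
#' convention that subjects censored at t remain in the risk set for events
#' at t.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return data.frame of class `km_curve` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) {
    out <- data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric())
  } else {
    n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
    out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                      survival = cumprod(1 - n_event / n_risk))
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate the step function (S = 1 before the
#'   first event).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group weighted log-rank test (Gehan-Breslow-Wilcoxon or log-rank)
#'
#' The generalized Wilcoxon test of Gehan-Breslow: a weighted log-rank
#' statistic with weight w_i = n_i (the total number at risk) at each event
#' time, which emphasises early differences; `method = "logrank"` uses
#' w_i = 1. The statistic (sum of w (observed - expected))^2 / sum(w^2 V)
#' is referred to chi-square with 1 df.
#'
#' @param time_a,event_a Follow-up and event indicator, group A.
#' @param time_b,event_b Follow-up and event indicator, group B.
#' @param method `"gehan_wilcoxon"` (default) or `"logrank"`.
#' @return List of class `surv_test_result`: `statistic`, `p`, `method`.
#' @export
gehan_wilcoxon <- function(time_a, event_a, time_b, event_b,
                           method = c("gehan_wilcoxon", "logrank")) {
  method <- match.arg(method)
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) {
    warning("no events in either group; p = 1", call. = FALSE)
    return(structure(list(statistic = 0, p = 1, method = method),
                     class = "surv_test_result"))
  }
  U <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    dead <- time == t & event == 1
    d_t <- sum(dead)
    d1 <- sum(dead & in_a)
    e1 <- d_t * n1 / n_t
    v <- if (n_t > 1) {
      d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    } else 0
    w <- if (method == "gehan_wilcoxon") n_t else 1
    U <- U + w * (d1 - e1)
    V <- V + w^2 * v
  }
  if (V <= 0) {
    return(structure(list(statistic = 0, p = 1, method = method),
                     class = "surv_test_result"))
  }
  stat <- U^2 / V
  structure(list(statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = method),
            class = "surv_test_result")
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with analytic score
#' and information, using the Efron correction for tied event times by
#' default (Breslow selectable). Convergence when |score| < `tol` or after
#' `max_iter` iterations; a coefficient exceeding 15 in absolute value
#' during iteration is treated as monotone likelihood (separation of risk
#' sets), capped and flagged non-converged.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param covariate Numeric covariate, non-constant, one value per subject.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return List of class `cox_result`: `beta` (log HR), `hr`, `se`,
#'   `wald_p`, `ci_low`/`ci_high` (95% on the HR scale), `loglik`,
#'   `iterations`, `converged`, `ties_method`.
#' @export
cox_univariate <- function(time, event, covariate,
                           ties = c("efron", "breslow"),
                           max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event),
            length(time) == length(covariate))
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  if (stats::sd(covariate) == 0) {
    stop("covariate is constant; hazard ratio undefined", call. = FALSE)
  }
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- covariate[ord]
  et <- unique(t_s[e_s == 1])

  score_info <- function(beta) {
    w <- exp(beta * x_s)
    rc0 <- rev(cumsum(rev(w)))
    rc1 <- rev(cumsum(rev(w * x_s)))
    rc2 <- rev(cumsum(rev(w * x_s^2)))
    ll <- 0; U <- 0; I <- 0
    for (t in et) {
      f <- match(TRUE, t_s >= t)  # first index at risk (sorted)
      dead <- which(t_s == t & e_s == 1)
      d <- length(dead)
      s0R <- rc0[f]; s1R <- rc1[f]; s2R <- rc2[f]
      xb_sum <- sum(x_s[dead])
      ll <- ll + beta * xb_sum
      U <- U + xb_sum
      if (ties == "breslow" || d == 1) {
        ll <- ll - d * log(s0R)
        U <- U - d * s1R / s0R
        I <- I + d * (s2R / s0R - (s1R / s0R)^2)
      } else {
        s0D <- sum(w[dead]); s1D <- sum((w * x_s)[dead])
        s2D <- sum((w * x_s^2)[dead])
        l <- seq_len(d) - 1
        den0 <- s0R - (l / d) * s0D
        den1 <- s1R - (l / d) * s1D
        den2 <- s2R - (l / d) * s2D
        ll <- ll - sum(log(den0))
        U <- U - sum(den1 / den0)
        I <- I + sum(den2 / den0 - (den1 / den0)^2)
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- 0; converged <- FALSE; separated <- FALSE; iter <- 0L
  si <- score_info(beta)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (si$I <= 0) break
    beta <- beta + si$U / si$I
    if (abs(beta) > 15) {
      separated <- TRUE
      beta <- sign(beta) * 15
      warning("monotone partial likelihood (separation); |beta| capped at 15",
              call. = FALSE)
      si <- score_info(beta)
      break
    }
    si <- score_info(beta)
    if (abs(si$U) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- if (si$I > 0) 1 / sqrt(si$I) else NA_real_
  z <- beta / se
  structure(list(beta = beta, hr = exp(beta), se = se,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 ci_low = exp(beta - stats::qnorm(0.975) * se),
                 ci_high = exp(beta + stats::qnorm(0.975) * se),
                 loglik = si$ll, iterations = iter,
                 converged = converged && !separated,
                 separated = separated, ties_method = ties),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (univariate, %s ties): HR = %.4g [%.4g, %.4g], p = %.3g%s\n",
              x$ties_method, x$hr, x$ci_low, x$ci_high, x$wald_p,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}
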