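ld_loglik <- function(f, dose, n_injected, n_positive) {
  p <- 1 - exp(-f * dose)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  sum(n_positive * log(p) + (n_injected - n_positive) * log1p(-p))
}

#' Single-hit Poisson limiting-dilution frequency estimate
#'
#' Under the single-hit model a recipient injected with `d` cells is
#' positive with probability 1 - exp(-f d); the tumor-initiating-cell
#' frequency `f` is estimated by maximizing the binomial likelihood across
#' dose levels. The 95% CI is Wald on log f by default (profile likelihood
#' behind `ci = "profile"`). With no positive recipient the MLE is 0 and an
#' exact one-sided upper bound is reported (the `f` at which observing all
#' negatives has probability `1 - conf_level`); with all recipients
#' positive the frequency is reported at the upper limit 1 with an exact
#' lower bound only.
#'
#' @param dose Cells injected per recipient at each dose level.
#' @param n_injected Recipients per dose level.
#' @param n_positive Positive recipients per dose level.
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"wald"` (default, on log f) or `"profile"`.
#' @return List of class `ld_result`: `frequency` (TICs per cell),
#'   `reciprocal` (cells per TIC), `ci_low`, `ci_high` (on the frequency),
#'   `loglik`, `boundary` (`"none"`, `"all_negative"` or `"all_positive"`).
#' @export
limiting_dilution_mle <- function(dose, n_injected, n_positive,
                                  conf_level = 0.95,
                                  ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  stopifnot(length(dose) >= 1, length(n_injected) == length(dose),
            length(n_positive) == length(dose), all(dose > 0),
            all(n_injected >= 1))
  if (any(n_positive > n_injected) || any(n_positive < 0)) {
    stop("n_positive must lie in [0, n_injected]", call. = FALSE)
  }
  alpha <- 1 - conf_level
  if (sum(n_positive) == 0) {
    upper <- -log(alpha) / sum(n_injected * dose)
    return(structure(list(frequency = 0, reciprocal = Inf,
                          ci_low = 0, ci_high = min(upper, 1),
                          loglik = 0, boundary = "all_negative"),
                     class = "ld_result"))
  }
  if (all(n_positive == n_injected)) {
    g <- function(lf) {
      sum(n_injected * log1p(-exp(-exp(lf) * dose))) - log(alpha)
    }
    lower <- exp(stats::uniroot(g, c(log(1e-12), 0), tol = 1e-12)$root)
    return(structure(list(frequency = 1, reciprocal = 1,
                          ci_low = lower, ci_high = 1,
                          loglik = ld_loglik(1, dose, n_injected, n_positive),
                          boundary = "all_positive"),
                     class = "ld_result"))
  }
  opt <- stats::optimize(function(lf) ld_loglik(exp(lf), dose, n_injected,
                                                n_positive),
                         interval = c(log(1e-9), 0), maximum = TRUE,
                         tol = 1e-12)
  phi <- opt$maximum
  f_hat <- exp(phi)
  ll_hat <- opt$objective
  h <- 1e-5
  d2 <- (ld_loglik(exp(phi + h), dose, n_injected, n_positive) -
           2 * ll_hat +
           ld_loglik(exp(phi - h), dose, n_injected, n_positive)) / h^2
  z <- stats::qnorm(1 - alpha / 2)
  if (is.finite(d2) && d2 < 0) {
    se_phi <- 1 / sqrt(-d2)
    lo <- exp(phi - z * se_phi)
    hi <- exp(phi + z * se_phi)
  } else {
    lo <- 0; hi <- 1
  }
  if (ci == "profile") {
    crit <- ll_hat - stats::qchisq(conf_level, df = 1) / 2
    g <- function(lf) ld_loglik(exp(lf), dose, n_injected, n_positive) - crit
    lo <- tryCatch(exp(stats::uniroot(g, c(log(1e-12), phi),
                                      tol = 1e-12)$root),
                   error = function(e) 0)
    hi <- tryCatch(exp(stats::uniroot(g, c(phi, 0), tol = 1e-12)$root),
                   error = function(e) 1)
  }
  structure(list(frequency = f_hat, reciprocal = 1 / f_hat,
                 ci_low = max(lo, 0), ci_high = min(hi, 1),
                 loglik = ll_hat, boundary = "none"),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("single-hit LD estimate: f = %.4g (1/%.3g cells) [%.3g, %.3g]\n",
              x$frequency, x$reciprocal, x$ci_low, x$ci_high))
  invisible(x)
}
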