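#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` by
#' Levenberg-Marquardt with multi-start over log-spaced IC50 initials
#' spanning the dose range. Parameter bounds: bottom in `[-0.2, 0.5]`, top
#' in `[0.5, 1.3]`, hill in `[0.1, 10]`, IC50 within
#' `[min(dose)/10, max(dose)*10]`. A fit whose IC50 lands on its bound, or
#' with no appreciable dose effect (|top - bottom| < 0.1), is flagged
#' unreliable.
#'
#' @param dose Doses in uM (>= 5 distinct values).
#' @param viability Viability fractions, same length.
#' @param n_starts Number of IC50 multi-start initials (default 7).
#' @return List of class `four_pl_fit`: `bottom`, `top`, `hill`, `ic50`,
#'   `rss`, `converged`, `reliable`, `n_points`.
#' @export
fit_4pl <- function(dose, viability, n_starts = 7L) {
  stopifnot(length(dose) == length(viability), all(dose > 0),
            all(is.finite(viability)))
  if (length(unique(dose)) < 5) {
    stop("need >= 5 distinct doses to fit a 4PL", call. = FALSE)
  }
  df <- data.frame(ld = log(dose), y = viability)
  lo <- c(bottom = -0.2, top = 0.5, hill = 0.1,
          lic50 = log(min(dose) / 10))
  hi <- c(bottom = 0.5, top = 1.3, hill = 10,
          lic50 = log(max(dose) * 10))
  model_rss <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + exp(p[3] * (df$ld - p[4])))
    sum((df$y - pred)^2)
  }
  starts <- seq(log(min(dose)), log(max(dose)), length.out = n_starts)
  best <- NULL
  for (s in starts) {
    init <- c(bottom = max(min(viability), -0.2),
              top = min(max(viability), 1.3), hill = 1, lic50 = s)
    init <- pmin(pmax(init, lo), hi)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lic50))),
        data = df, start = as.list(init), lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cand <- list(par = stats::coef(fit),
                   rss = sum(stats::residuals(fit)^2), converged = TRUE)
    } else {
      o <- stats::optim(init, model_rss, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = 500, factr = 1e4))
      cand <- list(par = o$par, rss = o$value,
                   converged = o$convergence == 0)
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  p <- best$par
  eps <- 1e-8
  at_bound <- p["lic50"] <= lo["lic50"] + eps || p["lic50"] >= hi["lic50"] - eps
  no_effect <- abs(p["top"] - p["bottom"]) < 0.1
  structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                 hill = unname(p["hill"]), ic50 = unname(exp(p["lic50"])),
                 rss = best$rss, converged = best$converged,
                 reliable = best$converged && !at_bound && !no_effect,
                 n_points = length(dose)),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 = %.4g uM (bottom %.3g, top %.3g, hill %.3g)%s\n",
              x$ic50, x$bottom, x$top, x$hill,
              if (!x$reliable) " [unreliable]" else ""))
  invisible(x)
}

#' Correlation of log10 IC50 with pathway activity within one experiment
#'
#' Pearson correlation of log10(IC50) against the activity value, over the
#' cell lines of one experiment. IC50s are log10-transformed because raw
#' micromolar values span orders of magnitude; `log_transform = FALSE`
#' correlates the raw values.
#'
#' @param ic50 Named or ordered IC50 values (uM), one per line.
#' @param activity Pathway-activity values, same lines and order.
#' @param log_transform Log10-transform IC50s first (default TRUE).
#' @return List with `r`, `n`.
#' @export
experiment_correlation <- function(ic50, activity, log_transform = TRUE) {
  stopifnot(length(ic50) == length(activity))
  if (length(ic50) < 3) stop("need >= 3 lines", call. = FALSE)
  x <- if (log_transform) log10(ic50) else ic50
  if (stats::sd(x) == 0 || stats::sd(activity) == 0) {
    stop("constant vector has no defined correlation", call. = FALSE)
  }
  list(r = stats::cor(x, activity), n = length(ic50))
}

#' Pool per-experiment correlations by Fisher-z meta-analysis
#'
#' Each correlation is transformed to z = atanh(r) with sampling variance
#' 1/(n - 3); studies are pooled by inverse-variance weighting, with the
#' DerSimonian-Laird moment estimate of the between-experiment variance
#' tau^2 under the default random-effects model (`method = "fixed"` sets
#' tau^2 = 0). The pooled z and its 95% CI are back-transformed by tanh.
#'
#' @param r Per-experiment correlations.
#' @param n Per-experiment sample sizes (each > 3).
#' @param method `"dersimonian_laird"` (default) or `"fixed"`.
#' @return List of class `meta_result`: `pooled_r`, `ci_low`, `ci_high`,
#'   `tau2`, `z`, `se_z`, `method`, `k`, `per_experiment`.
#' @export
meta_correlation <- function(r, n, method = c("dersimonian_laird", "fixed")) {
  method <- match.arg(method)
  stopifnot(length(r) == length(n), all(abs(r) <= 1))
  if (any(n <= 3)) {
    stop("experiment(s) with n <= 3 cannot be pooled: ",
         paste(which(n <= 3), collapse = ", "), call. = FALSE)
  }
  z <- atanh(r)
  v <- 1 / (n - 3)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  tau2 <- 0
  if (method == "dersimonian_laird" && length(r) > 1) {
    Q <- sum(w * (z - z_fixed)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (length(r) - 1)) / C)
  }
  w_star <- 1 / (v + tau2)
  z_pool <- sum(w_star * z) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  ci <- tanh(z_pool + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(pooled_r = tanh(z_pool), ci_low = ci[1], ci_high = ci[2],
                 tau2 = tau2, z = z_pool, se_z = se, method = method,
                 k = length(r),
                 per_experiment = data.frame(r = r, n = n)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta-analysis (%s, k = %d): pooled r = %.3f [%.3f, %.3f], tau2 = %.4f\n",
              x$method, x$k, x$pooled_r, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}

#' Full dose-response chain: per-line 4PL fits, per-experiment correlation,
#' meta-analysis
#'
#' Fits a 4PL per (experiment, line), correlates fitted log10 IC50 with
#' activity within each experiment, and pools the correlations.
#'
#' @param panel Long data.frame with columns `experiment`, `line`,
#'   `dose_uM`, `viability` (as from [simulate_dose_response()]).
#' @param activities data.frame with columns `experiment`, `line`,
#'   `activity`.
#' @param method Meta-analysis method, see [meta_correlation()].
#' @param n_starts Multi-start count passed to [fit_4pl()].
#' @return List with `fits` (data.frame experiment/line/ic50/reliable),
#'   `correlations` (per experiment r, n) and `meta` (a `meta_result`).
#' @export
panel_meta_analysis <- function(panel, activities,
                                method = c("dersimonian_laird", "fixed"),
                                n_starts = 4L) {
  method <- match.arg(method)
  stopifnot(all(c("experiment", "line", "dose_uM", "viability") %in%
                  names(panel)),
            all(c("experiment", "line", "activity") %in% names(activities)))
  keys <- unique(panel[, c("experiment", "line")])
  fits <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- panel[panel$experiment == keys$experiment[i] &
                   panel$line == keys$line[i], ]
    f <- fit_4pl(sub$dose_uM, sub$viability, n_starts = n_starts)
    data.frame(experiment = keys$experiment[i], line = keys$line[i],
               ic50 = f$ic50, reliable = f$reliable,
               stringsAsFactors = FALSE)
  }))
  merged <- merge(fits, activities, by = c("experiment", "line"))
  exps <- sort(unique(merged$experiment))
  cors <- do.call(rbind, lapply(exps, function(e) {
    sub <- merged[merged$experiment == e, ]
    ec <- experiment_correlation(sub$ic50, sub$activity)
    data.frame(experiment = e, r = ec$r, n = ec$n)
  }))
  list(fits = fits, correlations = cors,
       meta = meta_correlation(cors$r, cors$n, method = method))
}
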