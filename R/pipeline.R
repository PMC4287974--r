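#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates every stage on seeded synthetic fixtures: tumor simulation
#' and signature derivation; cohort simulation, scoring, median-split
#' stratification with Kaplan-Meier curves, Gehan-Wilcoxon test and Cox
#' hazard ratio; the composition-matched random-signature null; reference
#' calibration and Pten/p53 stratification; limiting-dilution estimation;
#' and the dose-response meta-analysis. One master seed fans out to
#' independent per-stage seeds via [child_seeds()] so any stage can be
#' rerun in isolation. Stages can be skipped by name.
#'
#' @param config A [run_config()]; its `rng_seed` is the master seed.
#' @param skip Character vector of stage names to skip, among
#'   `"derive"`, `"survival"`, `"nullrank"`, `"stratify"`, `"ldassay"`,
#'   `"drugfit"`.
#' @param cohort_n Patients in the simulated survival cohort (default 400).
#' @param n_null Random signatures in the null stage (defaults to
#'   `config$n_random_signatures`).
#' @return List of class `pipeline_report` with one element per stage plus
#'   the config snapshot and the seeds used.
#' @export
run_pipeline <- function(config = run_config(), skip = character(),
                         cohort_n = 400L, n_null = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(n_null)) n_null <- config$n_random_signatures
  seeds <- child_seeds(config$rng_seed, 6)
  report <- list(config = config, seeds = seeds)

  sig <- NULL
  if (!"derive" %in% skip) {
    tum <- simulate_tumor_matrix(tumor_sim_spec(rng_seed = seeds[1]))
    der <- derive_de_signature(tum$matrix,
                               q_threshold = config$q_threshold,
                               fc_threshold = config$fc_threshold,
                               name = "derived_signature")
    sig <- der$signature
    report$derive <- list(
      n_genes = nrow(tum$matrix$values),
      n_samples = ncol(tum$matrix$values),
      signature = sig,
      n_up = length(sig$up), n_down = length(sig$down),
      planted_recovered = setequal(c(sig$up, sig$down), tum$truth$gene_id))
  }
  if (is.null(sig)) {
    sig <- signed_signature("planted", up = sprintf("sig_up_%02d", 1:7),
                            down = sprintf("sig_dn_%02d", 1:17))
  }

  coh <- NULL
  if (!"survival" %in% skip || !"nullrank" %in% skip) {
    coh <- simulate_cohort(cohort_sim_spec(n_patients = cohort_n,
                                           signature = sig,
                                           rng_seed = seeds[2]))
  }
  if (!"survival" %in% skip) {
    sc <- dichotomize(score_signature(coh$matrix, sig), "median")
    pos <- sc$label == "positive"
    t <- coh$cohort$time; e <- coh$cohort$event
    report$survival <- list(
      km_positive = km_estimate(t[pos], e[pos]),
      km_negative = km_estimate(t[!pos], e[!pos]),
      test = gehan_wilcoxon(t[pos], e[pos], t[!pos], e[!pos]),
      cox = cox_univariate(t, e, as.numeric(pos)))
  }
  if (!"nullrank" %in% skip) {
    set.seed(seeds[3])
    report$nullrank <- null_rank(sig, coh$matrix, coh$cohort,
                                 N = n_null, alpha = config$alpha)
  }
  if (!"stratify" %in% skip) {
    ref <- simulate_reference_cohort(rng_seed = seeds[4])
    set.seed(seeds[4])
    n <- 200L
    samples <- sprintf("tnbc_%03d", seq_len(n))
    pten <- structure(data.frame(sample_id = samples,
                                 score = stats::rnorm(n),
                                 stringsAsFactors = FALSE),
                      class = c("score_vector", "data.frame"))
    p53_raw <- structure(data.frame(sample_id = samples,
                                    score = stats::rnorm(n, mean = 0.3),
                                    stringsAsFactors = FALSE),
                         class = c("score_vector", "data.frame"))
    cal <- calibrate_activity(p53_raw, ref$score[ref$status == "mutant"],
                              target = config$p53_reference_value)
    report$stratify <- c(
      stratify_pten_p53(pten, cal$scores,
                        pten_low_quantile = config$pten_low_quantile,
                        reference_value = config$p53_reference_value),
      list(calibration = cal$params))
  }
  if (!"ldassay" %in% skip) {
    ld <- simulate_limiting_dilution(ld_sim_spec(rng_seed = seeds[5]))
    report$ldassay <- list(
      table = ld,
      estimate = limiting_dilution_mle(ld$dose, ld$n_injected,
                                       ld$n_positive))
  }
  if (!"drugfit" %in% skip) {
    dr <- simulate_dose_response(panel_sim_spec(rng_seed = seeds[6]))
    report$drugfit <- panel_meta_analysis(dr$panel, dr$activities)
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (master seed", x$config$rng_seed, ")\n")
  if (!is.null(x$derive)) {
    cat(sprintf("  derived signature: %d genes (%d up, %d down)\n",
                x$derive$n_up + x$derive$n_down, x$derive$n_up,
                x$derive$n_down))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: Gehan-Wilcoxon p = %.3g, Cox HR = %.3g\n",
                x$survival$test$p, x$survival$cox$hr))
  }
  if (!is.null(x$nullrank)) {
    cat(sprintf("  null: %.1f%% significant, real rank %s, empirical p %.3g\n",
                100 * x$nullrank$frac_significant,
                ifelse(is.na(x$nullrank$real_rank), "NA",
                       x$nullrank$real_rank),
                x$nullrank$empirical_p))
  }
  if (!is.null(x$stratify)) {
    f <- x$stratify$frequencies
    cat(sprintf("  stratify: %.1f%% Pten-low, %.1f%% p53-low, %.1f%% both\n",
                100 * f["pten_low"], 100 * f["p53_low"], 100 * f["both_low"]))
  }
  if (!is.null(x$ldassay)) {
    cat(sprintf("  limiting dilution: 1/%.3g cells\n",
                x$ldassay$estimate$reciprocal))
  }
  if (!is.null(x$drugfit)) {
    cat(sprintf("  drug response: pooled r = %.3f\n",
                x$drugfit$meta$pooled_r))
  }
  invisible(x)
}
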