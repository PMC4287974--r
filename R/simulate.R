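#' Derive reproducible child seeds from one master seed
#'
#' One global seed fans out to independent per-stage seeds so stages can be
#' rerun in isolation with identical draws.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
child_seeds <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Specification for the two-group tumor simulation
#'
#' Emulates a microarray comparison of two engineered mouse tumor groups:
#' a large null background plus a small set of planted signed
#' differentially expressed genes (by default 7 up and 17 down, the
#' composition of the claudin-low signature, at a twofold-times-two effect).
#'
#' @param n_genes Total genes (default 10000).
#' @param n_per_group Samples per group (default 20).
#' @param n_up_planted,n_down_planted Planted up/down gene counts (7/17).
#' @param planted_effect Mean log2 shift of planted genes (default 2.0).
#' @param noise_sd Per-gene residual SD on the log2 scale (default 0.5).
#' @param rng_seed Integer seed.
#' @return A list of class `tumor_sim_spec`.
#' @export
tumor_sim_spec <- function(n_genes = 10000L, n_per_group = 20L,
                           n_up_planted = 7L, n_down_planted = 17L,
                           planted_effect = 2.0, noise_sd = 0.5,
                           rng_seed = 1L) {
  stopifnot(n_up_planted + n_down_planted <= n_genes, noise_sd > 0,
            n_per_group >= 2)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_up_planted = as.integer(n_up_planted),
                 n_down_planted = as.integer(n_down_planted),
                 planted_effect = planted_effect, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "tumor_sim_spec")
}

#' Simulate a two-group tumor expression matrix with planted signal
#'
#' Background genes share a per-gene baseline mean (drawn around 7 on the
#' log2 scale, typical of normalized arrays) with Gaussian noise. Planted up
#' genes have their mean shifted by `+planted_effect` in the claudin-low
#' group, planted down genes by `-planted_effect`. Group labels are
#' `"claudin_low"` (shifted group) and `"reference"`.
#'
#' @param spec A [tumor_sim_spec()].
#' @return List with `matrix` (an [expression_matrix()] with group labels)
#'   and `truth` (data.frame of planted gene ids and directions).
#' @export
simulate_tumor_matrix <- function(spec = tumor_sim_spec()) {
  stopifnot(inherits(spec, "tumor_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_genes
  m <- 2L * spec$n_per_group
  genes <- sprintf("gene_%05d", seq_len(n))
  samples <- c(sprintf("CL_%02d", seq_len(spec$n_per_group)),
               sprintf("REF_%02d", seq_len(spec$n_per_group)))
  groups <- stats::setNames(rep(c("claudin_low", "reference"),
                                each = spec$n_per_group), samples)
  base_mean <- stats::rnorm(n, mean = 7, sd = 1)
  vals <- base_mean + matrix(stats::rnorm(n * m, sd = spec$noise_sd),
                             nrow = n, ncol = m)
  up_idx <- seq_len(spec$n_up_planted)
  dn_idx <- spec$n_up_planted + seq_len(spec$n_down_planted)
  cl_cols <- seq_len(spec$n_per_group)
  vals[up_idx, cl_cols] <- vals[up_idx, cl_cols] + spec$planted_effect
  vals[dn_idx, cl_cols] <- vals[dn_idx, cl_cols] - spec$planted_effect
  dimnames(vals) <- list(genes, samples)
  truth <- data.frame(
    gene_id = genes[c(up_idx, dn_idx)],
    direction = rep(c("up", "down"),
                    c(spec$n_up_planted, spec$n_down_planted)),
    effect_log2 = rep(c(spec$planted_effect, -spec$planted_effect),
                      c(spec$n_up_planted, spec$n_down_planted)),
    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, groups = groups), truth = truth)
}

#' Specification for the survival-cohort simulation
#'
#' Emulates a breast-cancer cohort whose metastasis hazard depends on a
#' latent signature-positive class with a planted hazard ratio (default
#' 2.24) under proportional hazards, with independent exponential censoring.
#'
#' @param n_patients Cohort size (default 96).
#' @param signature A [signed_signature()] whose genes carry the class signal.
#' @param true_hr Planted hazard ratio, positive vs negative class.
#' @param baseline_hazard Events per month in the negative class.
#' @param censor_rate Independent exponential censoring rate per month.
#' @param loading Mean log2 shift of signature genes in positive patients.
#' @param n_background_genes Null genes added alongside the signature.
#' @param rng_seed Integer seed.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 96L,
                            signature = NULL,
                            true_hr = 2.24, baseline_hazard = 0.02,
                            censor_rate = 0.01, loading = 1.0,
                            n_background_genes = 500L, rng_seed = 1L) {
  if (is.null(signature)) {
    signature <- signed_signature("planted",
                                  up = sprintf("sig_up_%02d", 1:7),
                                  down = sprintf("sig_dn_%02d", 1:17))
  }
  stopifnot(inherits(signature, "signed_signature"),
            true_hr > 0, baseline_hazard > 0, censor_rate > 0,
            n_patients >= 4)
  structure(list(n_patients = as.integer(n_patients), signature = signature,
                 true_hr = true_hr, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, loading = loading,
                 n_background_genes = as.integer(n_background_genes),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_sim_spec")
}

#' Simulate an expression-linked survival cohort
#'
#' Each patient gets a latent binary class (balanced positive/negative).
#' Signature up genes are shifted `+loading` and down genes `-loading` in
#' positive patients; background genes are null. Event times are exponential
#' with hazard `baseline_hazard * true_hr^class`; censoring times are
#' independent exponential; observed time is the minimum.
#'
#' @param spec A [cohort_sim_spec()].
#' @return List with `matrix` ([expression_matrix()]), `cohort`
#'   ([clinical_cohort()]) and `truth` (data.frame with the latent class).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_patients
  sig <- spec$signature
  n_half <- n %/% 2L
  class_pos <- sample(rep(c(1L, 0L), c(n_half, n - n_half)))
  samples <- sprintf("pt_%03d", seq_len(n))
  genes <- c(sig$up, sig$down,
             sprintf("bg_%04d", seq_len(spec$n_background_genes)))
  vals <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, samples))
  if (length(sig$up) > 0) {
    vals[sig$up, ] <- vals[sig$up, ] +
      matrix(spec$loading * class_pos, nrow = length(sig$up),
             ncol = n, byrow = TRUE)
  }
  if (length(sig$down) > 0) {
    vals[sig$down, ] <- vals[sig$down, ] -
      matrix(spec$loading * class_pos, nrow = length(sig$down),
             ncol = n, byrow = TRUE)
  }
  hazard <- spec$baseline_hazard * spec$true_hr^class_pos
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::rexp(n, rate = spec$censor_rate)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)
  cohort <- clinical_cohort(samples, time, event, subtype = "claudin_low")
  truth <- data.frame(sample_id = samples, class_positive = class_pos,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals), cohort = cohort, truth = truth)
}

#' Simulate a reference cohort with mutant / wild-type pathway scores
#'
#' Stand-in for a calibration cohort with known mutation status: wild-type
#' scores sit above mutant scores by `separation` on average (default 0.58,
#' the gap between a mutant median of 0.15 and a wild-type median of 0.73
#' on the calibrated scale), both with unit-SD Gaussian spread.
#'
#' @param n_mut,n_wt Numbers of mutant and wild-type tumors.
#' @param separation Mean score difference, wild-type minus mutant.
#' @param rng_seed Integer seed.
#' @return data.frame with columns `sample_id`, `status`
#'   (`"mutant"`/`"wild_type"`) and `score`.
#' @export
simulate_reference_cohort <- function(n_mut = 60L, n_wt = 190L,
                                      separation = 0.58, rng_seed = 1L) {
  stopifnot(n_mut >= 1, n_wt >= 1)
  set.seed(as.integer(rng_seed))
  score <- c(stats::rnorm(n_mut, 0, 1), stats::rnorm(n_wt, separation, 1))
  data.frame(
    sample_id = sprintf("ref_%03d", seq_len(n_mut + n_wt)),
    status = rep(c("mutant", "wild_type"), c(n_mut, n_wt)),
    score = score, stringsAsFactors = FALSE)
}

#' Specification for the dose-response panel simulation
#'
#' Emulates repeated drug-sensitivity experiments on a cell-line panel in
#' which pathway activity and log10 IC50 are correlated (default -0.70,
#' i.e. higher pathway activity means greater drug sensitivity), with IC50s
#' centred on a 0.2 uM anchor.
#'
#' @param n_experiments Independent experiments (default 7).
#' @param n_lines Cell lines per experiment (default 6).
#' @param true_corr Planted correlation of activity with log10 IC50.
#' @param ic50_anchor Geometric-mean IC50 in uM (default 0.2).
#' @param log_ic50_sd SD of log10 IC50 across lines (default 0.5).
#' @param bottom,top,hill Four-parameter-logistic shape defaults (0, 1, 1).
#' @param viability_noise_sd Gaussian noise on viability fractions.
#' @param doses Dose grid in uM; at least 5 distinct positive values
#'   (default 8 log-spaced points from 0.001 to 10).
#' @param rng_seed Integer seed.
#' @return A list of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_experiments = 7L, n_lines = 6L,
                           true_corr = -0.70, ic50_anchor = 0.2,
                           log_ic50_sd = 0.5,
                           bottom = 0.0, top = 1.0, hill = 1.0,
                           viability_noise_sd = 0.05,
                           doses = 10^seq(log10(0.001), log10(10),
                                          length.out = 8),
                           rng_seed = 1L) {
  stopifnot(abs(true_corr) <= 1, ic50_anchor > 0, all(doses > 0),
            length(unique(doses)) >= 5, n_lines >= 3, n_experiments >= 1,
            viability_noise_sd >= 0)
  structure(list(n_experiments = as.integer(n_experiments),
                 n_lines = as.integer(n_lines), true_corr = true_corr,
                 ic50_anchor = ic50_anchor, log_ic50_sd = log_ic50_sd,
                 bottom = bottom, top = top, hill = hill,
                 viability_noise_sd = viability_noise_sd, doses = doses,
                 rng_seed = as.integer(rng_seed)),
            class = "panel_sim_spec")
}

four_pl <- function(dose, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Simulate a dose-response viability panel
#'
#' For each experiment and line, pathway activity and log10 IC50 are drawn
#' bivariate-normal with correlation `true_corr`; viabilities follow a
#' four-parameter logistic in dose with Gaussian noise, clipped to
#' `[-0.1, 1.2]` as plate readouts are.
#'
#' @param spec A [panel_sim_spec()].
#' @return List with `panel` (long data.frame: experiment, line, drug,
#'   dose_uM, viability), `activities` (experiment, line, activity) and
#'   `truth` (adds the planted log10 IC50 per experiment x line).
#' @export
simulate_dose_response <- function(spec = panel_sim_spec()) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  set.seed(spec$rng_seed)
  rho <- spec$true_corr
  rows <- list(); act <- list(); tru <- list()
  for (e in seq_len(spec$n_experiments)) {
    a <- stats::rnorm(spec$n_lines)
    eps <- stats::rnorm(spec$n_lines)
    log10_ic50 <- log10(spec$ic50_anchor) +
      spec$log_ic50_sd * (rho * a + sqrt(1 - rho^2) * eps)
    ic50 <- 10^log10_ic50
    lines <- sprintf("line_%02d", seq_len(spec$n_lines))
    for (l in seq_len(spec$n_lines)) {
      v <- four_pl(spec$doses, spec$bottom, spec$top, spec$hill, ic50[l])
      if (spec$viability_noise_sd > 0) {
        v <- v + stats::rnorm(length(v), sd = spec$viability_noise_sd)
      }
      v <- pmin(pmax(v, -0.1), 1.2)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = e, line = lines[l], drug = "drug_1",
        dose_uM = spec$doses, viability = v, stringsAsFactors = FALSE)
    }
    act[[e]] <- data.frame(experiment = e, line = lines, activity = a,
                           stringsAsFactors = FALSE)
    tru[[e]] <- data.frame(experiment = e, line = lines, activity = a,
                           log10_ic50 = log10_ic50, stringsAsFactors = FALSE)
  }
  list(panel = do.call(rbind, rows), activities = do.call(rbind, act),
       truth = do.call(rbind, tru))
}

#' Specification for the limiting-dilution transplant simulation
#'
#' Emulates a transplantation assay under the single-hit Poisson model:
#' a recipient injected with `d` cells becomes tumor-positive with
#' probability `1 - exp(-f * d)` where `f` is the tumor-initiating-cell
#' frequency (default 1/57).
#'
#' @param true_frequency TICs per cell, in (0, 1).
#' @param doses Cells per injection (positive integers).
#' @param n_recipients Recipients per dose level.
#' @param rng_seed Integer seed.
#' @return A list of class `ld_sim_spec`.
#' @export
ld_sim_spec <- function(true_frequency = 1 / 57,
                        doses = c(10L, 50L, 100L, 500L),
                        n_recipients = 6L, rng_seed = 1L) {
  stopifnot(true_frequency > 0, true_frequency < 1, all(doses > 0),
            n_recipients >= 1)
  structure(list(true_frequency = true_frequency, doses = as.integer(doses),
                 n_recipients = as.integer(n_recipients),
                 rng_seed = as.integer(rng_seed)),
            class = "ld_sim_spec")
}

#' Simulate a limiting-dilution transplant table
#'
#' @param spec An [ld_sim_spec()].
#' @return data.frame with columns `dose`, `n_injected`, `n_positive`.
#' @export
simulate_limiting_dilution <- function(spec = ld_sim_spec()) {
  stopifnot(inherits(spec, "ld_sim_spec"))
  set.seed(spec$rng_seed)
  p <- 1 - exp(-spec$true_frequency * spec$doses)
  data.frame(dose = spec$doses,
             n_injected = rep(spec$n_recipients, length(spec$doses)),
             n_positive = stats::rbinom(length(spec$doses),
                                        spec$n_recipients, p))
}
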