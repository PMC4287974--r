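#' Generate composition-matched random signed signatures
#'
#' Each signature draws `n_up + n_down` distinct genes uniformly without
#' replacement from the universe; the first `n_up` become the up set. Draws
#' are independent across signatures (a seeded PRNG stands in for the
#' atmospheric-noise source sometimes used for such nulls).
#'
#' @param universe Character vector of candidate gene ids.
#' @param n_up,n_down Up/down gene counts every signature must have.
#' @param N Number of signatures.
#' @return List of [signed_signature()] objects named `random_0001`, ...
#' @export
generate_random_signatures <- function(universe, n_up, n_down, N) {
  universe <- unique(as.character(universe))
  k <- n_up + n_down
  if (length(universe) < k) {
    stop("universe (", length(universe), " genes) smaller than signature (",
         k, ")", call. = FALSE)
  }
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  lapply(seq_len(N), function(i) {
    g <- sample(universe, k)
    signed_signature(sprintf("random_%04d", i),
                     up = g[seq_len(n_up)],
                     down = if (n_down > 0) g[n_up + seq_len(n_down)]
                            else character())
  })
}

evaluate_from_z <- function(z, sig, time, event) {
  score <- score_from_z(z, sig)
  lab <- as.numeric(score > stats::median(score))
  if (length(unique(lab)) < 2) {
    return(c(hr = NA_real_, p = 1))
  }
  gw <- gehan_wilcoxon(time[lab == 1], event[lab == 1],
                       time[lab == 0], event[lab == 0])
  cx <- cox_univariate(time, event, lab)
  c(hr = cx$hr, p = gw$p)
}

#' Evaluate the prognostic power of one signature
#'
#' The full stratification chain: score the signature, median-split the
#' samples into positive (high score) and negative, compare metastasis-free
#' survival between the classes with the Gehan-Breslow-Wilcoxon test, and
#' take the hazard ratio from univariate Cox regression on the binary
#' label. A degenerate split (all samples one class) yields HR = NA, p = 1.
#'
#' @param sig A [signed_signature()].
#' @param matrix An [expression_matrix()] covering the cohort samples.
#' @param cohort A [clinical_cohort()].
#' @return Named numeric vector with `hr` and `p`.
#' @export
evaluate_signature_prognosis <- function(sig, matrix, cohort) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(cohort, "clinical_cohort"))
  idx <- match(cohort$sample_id, colnames(matrix$values))
  if (any(is.na(idx))) {
    stop("cohort sample(s) missing from expression matrix", call. = FALSE)
  }
  present <- intersect(c(sig$up, sig$down), rownames(matrix$values))
  if (length(present) == 0) {
    stop("no signature gene present in matrix", call. = FALSE)
  }
  z <- z_score_rows(matrix$values[, idx, drop = FALSE])
  z <- z[rowSums(is.na(z)) == 0, , drop = FALSE]
  evaluate_from_z(z, sig, cohort$time, cohort$event)
}

#' Rank a real signature against a composition-matched random null
#'
#' Evaluates the real signature and `N` random signatures of identical
#' up/down composition (drawn from the matrix genes excluding the real
#' signature's, so no random set partially overlaps it) through the same
#' score / median-split / survival chain, then summarises: the fraction of
#' random signatures significant at `alpha`, the fraction significant with
#' HR > 1, the real signature's rank by descending HR among the significant
#' ones (and among all), and a +1-smoothed empirical p-value
#' `(1 + #\{random significant with HR >= real HR\}) / (N + 1)`.
#'
#' @param real_sig The signature under test.
#' @param matrix An [expression_matrix()].
#' @param cohort A [clinical_cohort()] on the same samples.
#' @param N Number of random signatures (default 1000).
#' @param alpha Significance gate on the Gehan-Wilcoxon p (default 0.05).
#' @param include_real_genes If TRUE, random draws may reuse the real
#'   signature's genes.
#' @return List of class `null_rank_result`: `n_signatures`,
#'   `frac_significant`, `frac_hr_gt1_significant`, `real_hr`, `real_p`,
#'   `real_rank` (among significant; NA if the real signature is not
#'   significant), `real_rank_all` (among all N+1 by HR), `empirical_p`,
#'   and `table` (per-random-signature hr and p).
#' @export
null_rank <- function(real_sig, matrix, cohort, N = 1000, alpha = 0.05,
                      include_real_genes = FALSE) {
  stopifnot(inherits(real_sig, "signed_signature"))
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  idx <- match(cohort$sample_id, colnames(matrix$values))
  if (any(is.na(idx))) {
    stop("cohort sample(s) missing from expression matrix", call. = FALSE)
  }
  all_genes <- rownames(matrix$values)
  missing <- setdiff(c(real_sig$up, real_sig$down), all_genes)
  if (length(missing) > 0) {
    warning(length(missing), " real-signature gene(s) absent from matrix",
            call. = FALSE)
  }
  universe <- if (include_real_genes) all_genes
              else setdiff(all_genes, c(real_sig$up, real_sig$down))
  z <- z_score_rows(matrix$values[, idx, drop = FALSE])
  z <- z[rowSums(is.na(z)) == 0, , drop = FALSE]
  time <- cohort$time; event <- cohort$event

  real <- evaluate_from_z(z, real_sig, time, event)
  rand_sigs <- generate_random_signatures(
    intersect(universe, rownames(z)),
    length(real_sig$up), length(real_sig$down), N)
  res <- t(vapply(rand_sigs, evaluate_from_z, numeric(2),
                  z = z, time = time, event = event))
  tab <- data.frame(signature = vapply(rand_sigs, `[[`, "", "name"),
                    hr = res[, "hr"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  sig_mask <- !is.na(tab$hr) & tab$p < alpha
  frac_significant <- mean(sig_mask)
  frac_hr_gt1 <- mean(sig_mask & tab$hr > 1)
  real_significant <- !is.na(real["hr"]) && real["p"] < alpha
  emp_p <- if (real_significant) {
    (1 + sum(sig_mask & tab$hr >= real["hr"])) / (N + 1)
  } else 1
  real_rank <- if (real_significant) {
    1 + sum(sig_mask & tab$hr > real["hr"])
  } else NA_integer_
  real_rank_all <- 1 + sum(!is.na(tab$hr) & tab$hr > real["hr"])
  structure(list(n_signatures = N,
                 frac_significant = frac_significant,
                 frac_hr_gt1_significant = frac_hr_gt1,
                 real_hr = unname(real["hr"]), real_p = unname(real["p"]),
                 real_rank = real_rank, real_rank_all = real_rank_all,
                 empirical_p = emp_p, alpha = alpha, table = tab),
            class = "null_rank_result")
}

#' @export
print.null_rank_result <- function(x, ...) {
  cat(sprintf(paste0(
    "random-signature null (N = %d, alpha = %.2g):\n",
    "  significant: %.1f%%; significant with HR > 1: %.1f%%\n",
    "  real signature: HR = %.3g, p = %.3g, rank %s among significant, ",
    "empirical p = %.4g\n"),
    x$n_signatures, x$alpha, 100 * x$frac_significant,
    100 * x$frac_hr_gt1_significant, x$real_hr, x$real_p,
    ifelse(is.na(x$real_rank), "NA", as.character(x$real_rank)),
    x$empirical_p))
  invisible(x)
}
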