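#' Construct a validated expression matrix
#'
#' Container for log2-scale gene expression, genes in rows and samples in
#' columns. Values are assumed to be on the log2 scale already; nothing in
#' the package re-logs. Missing values are rejected rather than imputed.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids). All values must be finite.
#' @param groups Optional named character vector mapping sample id -> group
#'   label; names must be a subset of the sample ids.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `groups`.
#' @export
expression_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix needs rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  if (!is.null(groups)) {
    if (is.null(names(groups)) || !all(names(groups) %in% sid)) {
      stop("`groups` must be named by sample ids present in the matrix",
           call. = FALSE)
    }
    groups <- stats::setNames(as.character(groups), names(groups))
  }
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a signed gene signature
#'
#' A named pair of disjoint gene sets: genes expected up-regulated and genes
#' expected down-regulated in the condition of interest (e.g. a 24-gene
#' claudin-low signature with 7 up and 17 down genes).
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene ids; must be disjoint and jointly
#'   non-empty.
#' @return An object of class `signed_signature`.
#' @export
signed_signature <- function(name, up = character(), down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0) {
    stop("gene(s) in both up and down sets of '", name, "': ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  if (length(up) + length(down) < 1) {
    stop("signature '", name, "' is empty", call. = FALSE)
  }
  structure(list(name = name, up = up, down = down),
            class = "signed_signature")
}

#' @export
print.signed_signature <- function(x, ...) {
  cat(sprintf("signed_signature '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Construct a validated clinical cohort
#'
#' Per-patient follow-up for survival analysis: time to event or censoring
#' (months), an event indicator (1 = metastasis/death observed, 0 =
#' censored), and an intrinsic-subtype label.
#'
#' @param sample_id Character vector of unique patient/sample ids.
#' @param time Non-negative numeric follow-up times (months).
#' @param event Event indicators in {0, 1}.
#' @param subtype Subtype labels (recycled if length 1).
#' @return A data.frame of class `clinical_cohort` with columns
#'   `sample_id`, `time`, `event`, `subtype`.
#' @export
clinical_cohort <- function(sample_id, time, event, subtype = "unknown") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s) in cohort", call. = FALSE)
  }
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id)) {
    stop("sample_id, time and event must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and >= 0", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  if (length(subtype) == 1) subtype <- rep(subtype, length(sample_id))
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    subtype = as.character(subtype),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' Default run configuration
#'
#' The thresholds the pipeline uses, collected in one place so the printed
#' settings (q < 0.05, twofold change, 1,000 random signatures, top-30% AKT
#' cutoff, p53-mutant reference median 0.15, bottom-quartile Pten-low) are
#' visible configuration rather than constants buried in code.
#'
#' @param q_threshold FDR q-value cutoff for differential expression.
#' @param fc_threshold Linear fold-change cutoff (2.0 means |delta log2| > 1).
#' @param alpha Significance level for survival tests.
#' @param n_random_signatures Size of the composition-matched null.
#' @param akt_high_quantile Fraction called AKT-high (top quantile).
#' @param p53_reference_value Calibration anchor for p53-pathway activity.
#' @param pten_low_quantile Fraction called Pten-low (bottom quantile).
#' @param rng_seed Integer seed for all randomness.
#' @return A list of class `run_config`.
#' @export
run_config <- function(q_threshold = 0.05, fc_threshold = 2.0, alpha = 0.05,
                       n_random_signatures = 1000, akt_high_quantile = 0.30,
                       p53_reference_value = 0.15, pten_low_quantile = 0.25,
                       rng_seed = 1L) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            fc_threshold >= 1,
            alpha > 0, alpha < 1,
            n_random_signatures >= 1,
            akt_high_quantile > 0, akt_high_quantile < 1,
            pten_low_quantile > 0, pten_low_quantile < 1,
            is.finite(p53_reference_value))
  rng_seed <- as.integer(rng_seed)
  structure(list(q_threshold = q_threshold, fc_threshold = fc_threshold,
                 alpha = alpha, n_random_signatures = n_random_signatures,
                 akt_high_quantile = akt_high_quantile,
                 p53_reference_value = p53_reference_value,
                 pten_low_quantile = pten_low_quantile,
                 rng_seed = rng_seed),
            class = "run_config")
}
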