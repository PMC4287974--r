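z_score_rows <- function(vals) {
  mu <- rowMeans(vals)
  sdv <- sqrt(rowSums((vals - mu)^2) / (ncol(vals) - 1))
  z <- (vals - mu) / sdv
  z[sdv == 0, ] <- NA_real_
  z
}

score_from_z <- function(z, sig) {
  up <- intersect(sig$up, rownames(z))
  down <- intersect(sig$down, rownames(z))
  up_part <- if (length(up) > 0) colMeans(z[up, , drop = FALSE]) else 0
  dn_part <- if (length(down) > 0) colMeans(z[down, , drop = FALSE]) else 0
  up_part - dn_part
}

#' Score samples against a signed signature
#'
#' Each gene is z-scored across samples; the sample score is the mean z of
#' the up genes minus the mean z of the down genes (an empty side
#' contributes 0), so a positive score means expression concordant with the
#' signature. Signature genes absent from the matrix, or with zero variance,
#' are skipped with a warning.
#'
#' @param matrix An [expression_matrix()] with at least 2 samples.
#' @param sig A [signed_signature()]; at least one of its genes must be in
#'   the matrix.
#' @return data.frame of class `score_vector` with columns `sample_id`,
#'   `score`.
#' @export
score_signature <- function(matrix, sig) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(sig, "signed_signature"))
  if (ncol(matrix$values) < 2) {
    stop("z-scoring needs at least 2 samples", call. = FALSE)
  }
  present <- intersect(c(sig$up, sig$down), rownames(matrix$values))
  if (length(present) == 0) {
    stop("no gene of signature '", sig$name, "' present in the matrix",
         call. = FALSE)
  }
  missing <- setdiff(c(sig$up, sig$down), present)
  if (length(missing) > 0) {
    warning(length(missing), " signature gene(s) absent from matrix, skipped",
            call. = FALSE)
  }
  z <- z_score_rows(matrix$values[present, , drop = FALSE])
  zero_var <- rownames(z)[apply(is.na(z), 1, all)]
  if (length(zero_var) > 0) {
    warning(length(zero_var), " zero-variance signature gene(s) skipped",
            call. = FALSE)
    z <- z[setdiff(rownames(z), zero_var), , drop = FALSE]
    if (nrow(z) == 0) {
      stop("all signature genes have zero variance", call. = FALSE)
    }
  }
  out <- data.frame(sample_id = colnames(matrix$values),
                    score = unname(score_from_z(z, sig)),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Dichotomize scores into positive / negative classes
#'
#' Rules: `"median"` (positive = strictly above the median),
#' `"top_quantile"` (positive = the top `q` fraction),
#' `"bottom_quantile"` (positive = the bottom `q` fraction) and
#' `"threshold"` (positive = strictly beyond `c`). Ties at the cut always go
#' to the negative class, so a top-30% rule never labels more than 30% of
#' samples positive; with all scores equal everything is negative.
#'
#' @param scores A `score_vector` (data.frame with `sample_id`, `score`).
#' @param rule One of `"median"`, `"top_quantile"`, `"bottom_quantile"`,
#'   `"threshold"`.
#' @param q Quantile in (0, 1) for the quantile rules.
#' @param c Cut value for the threshold rule.
#' @return The score vector with an added `label` column
#'   (`"positive"`/`"negative"`).
#' @export
dichotomize <- function(scores, rule = c("median", "top_quantile",
                                         "bottom_quantile", "threshold"),
                        q = NULL, c = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  s <- scores$score
  n <- length(s)
  positive <- switch(rule,
    median = s > stats::median(s),
    top_quantile = {
      if (is.null(q) || q <= 0 || q >= 1) {
        stop("top_quantile needs q in (0, 1)", call. = FALSE)
      }
      k <- floor(q * n)
      if (k >= n) rep(TRUE, n)
      else if (k == 0) rep(FALSE, n)
      else s > sort(s, decreasing = TRUE)[k + 1]
    },
    bottom_quantile = {
      if (is.null(q) || q <= 0 || q >= 1) {
        stop("bottom_quantile needs q in (0, 1)", call. = FALSE)
      }
      k <- floor(q * n)
      if (k >= n) rep(TRUE, n)
      else if (k == 0) rep(FALSE, n)
      else s < sort(s)[k + 1]
    },
    threshold = {
      if (is.null(c) || !is.finite(c)) {
        stop("threshold rule needs a finite cut c", call. = FALSE)
      }
      s > c
    })
  scores$label <- ifelse(positive, "positive", "negative")
  scores
}

#' Calibrate pathway-activity scores against a mutant reference
#'
#' Shifts all scores by a single offset so the median of the mutant
#' reference scores lands exactly on `target` (default 0.15). A pure
#' location shift: the ordering of samples is unchanged, and "low" activity
#' is then defined as calibrated score < `target`.
#'
#' @param scores A `score_vector` to calibrate.
#' @param mutant_reference_scores Numeric scores of the mutant reference
#'   tumors (uncalibrated, same scale as `scores`).
#' @param target Reference anchor value (default 0.15).
#' @return List with `scores` (calibrated score vector, plus a `low`
#'   logical column) and `params` (list with `offset`, `reference_value`).
#' @export
calibrate_activity <- function(scores, mutant_reference_scores,
                               target = 0.15) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  if (length(mutant_reference_scores) == 0) {
    stop("mutant reference is empty", call. = FALSE)
  }
  offset <- target - stats::median(mutant_reference_scores)
  scores$score <- scores$score + offset
  scores$low <- scores$score < target
  list(scores = scores,
       params = list(offset = offset, reference_value = target))
}

#' Pearson correlation with a two-sided p-value
#'
#' r with significance from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Joint Pten-expression / p53-activity stratification
#'
#' Classifies each sample as Pten-low (bottom `pten_low_quantile` of Pten
#' expression, ties at the cut excluded), p53-activity-low (calibrated
#' activity below the reference value), both, or neither, and reports the
#' group frequencies.
#'
#' @param pten_expression `score_vector` of Pten expression per sample.
#' @param p53_activity Calibrated `score_vector` of p53-pathway activity
#'   (as returned by [calibrate_activity()]).
#' @param pten_low_quantile Fraction called Pten-low (default 0.25).
#' @param reference_value Activity cut for "low" (default 0.15).
#' @return List with `status` (data.frame: sample_id, pten_low, p53_low,
#'   status) and `frequencies` (named fractions: pten_low, p53_low,
#'   both_low, neither).
#' @export
stratify_pten_p53 <- function(pten_expression, p53_activity,
                              pten_low_quantile = 0.25,
                              reference_value = 0.15) {
  stopifnot(is.data.frame(pten_expression), is.data.frame(p53_activity))
  if (!setequal(pten_expression$sample_id, p53_activity$sample_id)) {
    stop("Pten and p53 tables must cover the same samples", call. = FALSE)
  }
  p53 <- p53_activity[match(pten_expression$sample_id,
                            p53_activity$sample_id), ]
  pten_cls <- dichotomize(pten_expression, "bottom_quantile",
                          q = pten_low_quantile)
  pten_low <- pten_cls$label == "positive"
  p53_low <- p53$score < reference_value
  status <- ifelse(pten_low & p53_low, "both-low",
            ifelse(pten_low, "pten-low-only",
            ifelse(p53_low, "p53-low-only", "neither")))
  freq <- c(pten_low = mean(pten_low), p53_low = mean(p53_low),
            both_low = mean(pten_low & p53_low),
            neither = mean(!pten_low & !p53_low))
  list(status = data.frame(sample_id = pten_expression$sample_id,
                           pten_low = pten_low, p53_low = p53_low,
                           status = status, stringsAsFactors = FALSE),
       frequencies = freq)
}
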