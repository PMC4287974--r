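#' Per-gene one-way ANOVA between two groups
#'
#' Vectorized genome-wide scan: for each gene, a one-way fixed-effects ANOVA
#' between exactly two groups (equivalent to a pooled-variance t-test, with
#' F = t^2), plus the log2 fold change as the difference of group means —
#' the data are already log2-scale so no further transformation is applied.
#' A Welch variant (Satterthwaite df) is available.
#'
#' The reference group (whose mean comes first in the difference) is the
#' lexicographically first label unless `ref` overrides it; log2FC =
#' mean(ref group) - mean(other group).
#'
#' Genes with zero pooled variance cannot be tested: they get p = 1,
#' F = NA, and `degenerate = TRUE` so a genome-wide scan does not abort.
#'
#' @param matrix An [expression_matrix()] with group labels (or `groups`
#'   supplied here).
#' @param groups Optional named group vector overriding the matrix's labels.
#' @param ref Optional label to treat as the first (reference) group.
#' @param var_equal Pooled-variance ANOVA (default TRUE) or Welch.
#' @return data.frame with columns `gene_id`, `log2fc`, `F`, `p`,
#'   `degenerate`.
#' @export
anova_per_gene <- function(matrix, groups = NULL, ref = NULL,
                           var_equal = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (is.null(groups)) groups <- matrix$groups
  if (is.null(groups)) stop("no group labels available", call. = FALSE)
  sid <- colnames(matrix$values)
  groups <- groups[sid]
  if (any(is.na(groups))) stop("every sample needs a group label", call. = FALSE)
  levs <- sort(unique(groups))
  if (length(levs) != 2) {
    stop("exactly two groups required, got ", length(levs), call. = FALSE)
  }
  if (!is.null(ref)) {
    if (!ref %in% levs) stop("ref group '", ref, "' not found", call. = FALSE)
    levs <- c(ref, setdiff(levs, ref))
  }
  a_cols <- which(groups == levs[1])
  b_cols <- which(groups == levs[2])
  na <- length(a_cols); nb <- length(b_cols)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples", call. = FALSE)
  x <- matrix$values
  ma <- rowMeans(x[, a_cols, drop = FALSE])
  mb <- rowMeans(x[, b_cols, drop = FALSE])
  va <- rowSums((x[, a_cols, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((x[, b_cols, drop = FALSE] - mb)^2) / (nb - 1)
  d <- ma - mb
  if (var_equal) {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- s2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, nrow(x))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degen <- se2 <= 0 | !is.finite(se2)
  Fstat <- ifelse(degen, NA_real_, d^2 / se2)
  p <- ifelse(degen, 1, stats::pf(Fstat, 1, df, lower.tail = FALSE))
  data.frame(gene_id = rownames(x), log2fc = unname(d), F = unname(Fstat),
             p = unname(p), degenerate = unname(degen),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validates the inputs and applies the BH step-up procedure
#' (q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j, with monotone
#' enforcement), preserving the order of the p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter a differential-expression table into a signed signature
#'
#' Genes pass if `q < q_threshold` and the absolute log2 fold change
#' strictly exceeds `log2(fc_threshold)` (a "> twofold" rule on the linear
#' scale with the default 2.0); the sign of log2FC assigns them to the up
#' or down side. An empty result is returned with a warning, not an error.
#'
#' @param de data.frame from [anova_per_gene()], with a `q` column (add one
#'   with [bh_fdr()] if absent).
#' @param q_threshold FDR cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff (default 2.0).
#' @param name Signature name.
#' @return A [signed_signature()], or `NULL` with a warning if no gene
#'   passes.
#' @export
derive_signature <- function(de, q_threshold = 0.05, fc_threshold = 2.0,
                             name = "signature") {
  stopifnot(is.data.frame(de), all(c("gene_id", "log2fc", "p") %in% names(de)))
  if (!"q" %in% names(de)) de$q <- bh_fdr(de$p)
  stopifnot(q_threshold > 0, q_threshold < 1, fc_threshold >= 1)
  lfc_cut <- log2(fc_threshold)
  up <- de$gene_id[de$q < q_threshold & de$log2fc > lfc_cut]
  down <- de$gene_id[de$q < q_threshold & de$log2fc < -lfc_cut]
  if (length(up) + length(down) == 0) {
    warning("no gene passed q < ", q_threshold, " and |log2FC| > ", lfc_cut,
            "; returning NULL", call. = FALSE)
    return(NULL)
  }
  signed_signature(name, up = up, down = down)
}

#' Full derivation chain: ANOVA, BH FDR, fold-change filter
#'
#' Convenience wrapper composing [anova_per_gene()], [bh_fdr()] and
#' [derive_signature()]; also returns the annotated per-gene table.
#'
#' @inheritParams anova_per_gene
#' @inheritParams derive_signature
#' @return List with `signature` and `de` (per-gene table with `q` and
#'   `direction` columns).
#' @export
derive_de_signature <- function(matrix, groups = NULL, ref = NULL,
                                q_threshold = 0.05, fc_threshold = 2.0,
                                name = "signature", var_equal = TRUE) {
  de <- anova_per_gene(matrix, groups = groups, ref = ref,
                       var_equal = var_equal)
  de$q <- bh_fdr(de$p)
  lfc_cut <- log2(fc_threshold)
  de$direction <- "none"
  de$direction[de$q < q_threshold & de$log2fc > lfc_cut] <- "up"
  de$direction[de$q < q_threshold & de$log2fc < -lfc_cut] <- "down"
  sig <- derive_signature(de, q_threshold, fc_threshold, name)
  list(signature = sig, de = de)
}
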