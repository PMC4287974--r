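# Small in-code fixtures shared across test files.

tiny_matrix <- function(vals = NULL, genes = c("g1", "g2", "g3"),
                        samples = c("s1", "s2"), groups = NULL) {
  if (is.null(vals)) vals <- matrix(seq_len(length(genes) * length(samples)),
                                    nrow = length(genes))
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, groups = groups)
}

# Independent partial-likelihood evaluator for untied data (test oracle).
partial_loglik_untied <- function(beta, time, event, x) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      at_risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[at_risk])))
    }
    ll
  }, numeric(1))
}

# Independent single-hit binomial log-likelihood (test oracle).
ld_loglik_oracle <- function(f, dose, n_injected, n_positive) {
  p <- 1 - exp(-f * dose)
  sum(n_positive * log(p) + (n_injected - n_positive) * log(1 - p))
}

score_vec <- function(ids, score) {
  structure(data.frame(sample_id = ids, score = score,
                       stringsAsFactors = FALSE),
            class = c("score_vector", "data.frame"))
}
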