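#!/usr/bin/env Rscript
# Stage 5 — calibrated pathway-activity stratification: anchor p53-pathway
# activity so the mutant-reference median equals 0.15, classify samples as
# Pten-low (bottom quartile) and/or p53-activity-low (< 0.15), report the
# joint frequencies, and correlate Pten expression with p53 activity.

library(clawsig)
seed <- as.integer(Sys.getenv("PIPELINE_SEED", "7"))
dir.create("results", showWarnings = FALSE)

ref <- simulate_reference_cohort(rng_seed = seed)
cat(sprintf("reference cohort: %d mutant, %d wild-type\n",
            sum(ref$status == "mutant"), sum(ref$status == "wild_type")))

# a TNBC cohort in which Pten expression partly drives p53-pathway activity
set.seed(seed)
n <- 200
samples <- sprintf("tnbc_%03d", seq_len(n))
pten_score <- rnorm(n)
p53_raw <- 0.6 * pten_score + rnorm(n, sd = 0.8)
pten <- structure(data.frame(sample_id = samples, score = pten_score),
                  class = c("score_vector", "data.frame"))
p53 <- structure(data.frame(sample_id = samples, score = p53_raw),
                 class = c("score_vector", "data.frame"))

cal <- calibrate_activity(p53, ref$score[ref$status == "mutant"],
                          target = 0.15)
cat(sprintf("calibration offset: %.4f (mutant median -> 0.15)\n",
            cal$params$offset))

corr <- pearson_with_p(pten$score, cal$scores$score)
cat(sprintf("Pten expression vs p53 activity: r = %.3f, p = %.3g (n = %d)\n",
            corr$r, corr$p, corr$n))

strat <- stratify_pten_p53(pten, cal$scores, pten_low_quantile = 0.25,
                           reference_value = 0.15)
f <- strat$frequencies
cat(sprintf("Pten-low %.1f%%, p53-low %.1f%%, both %.1f%%\n",
            100 * f["pten_low"], 100 * f["p53_low"], 100 * f["both_low"]))

# AKT-high dichotomization at the top-30% cutoff on the same activity scale
akt <- dichotomize(cal$scores, "top_quantile", q = 0.30)
cat(sprintf("AKT-high (top 30%%): %d of %d samples\n",
            sum(akt$label == "positive"), n))

utils::write.table(strat$status, "results/05_stratification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(metric = c("pten_low", "p53_low", "both_low", "neither",
                        "pearson_r", "pearson_p", "offset"),
             value = c(f, corr$r, corr$p, cal$params$offset)),
  "results/05_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/05_stratification.tsv, results/05_summary.tsv\n")
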