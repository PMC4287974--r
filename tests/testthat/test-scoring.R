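test_that("a one-gene signature score is that gene's z-score", {
  set.seed(4)
  vals <- matrix(rnorm(8), nrow = 2,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m <- expression_matrix(vals)
  sc <- score_signature(m, signed_signature("one", up = "g1"))
  z <- (vals["g1", ] - mean(vals["g1", ])) / sd(vals["g1", ])
  expect_equal(sc$score, unname(z))
})

test_that("swapping up and down sets negates every score", {
  set.seed(5)
  vals <- matrix(rnorm(20), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m <- expression_matrix(vals)
  a <- score_signature(m, signed_signature("s", up = c("g1", "g2"),
                                           down = c("g3", "g4")))
  b <- score_signature(m, signed_signature("s", up = c("g3", "g4"),
                                           down = c("g1", "g2")))
  expect_equal(a$score, -b$score)
})

test_that("scores match a hand z-mean computation on a worked matrix", {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   5, 5, 6, 8), nrow = 3, byrow = TRUE,
                 dimnames = list(c("u1", "u2", "d1"), paste0("s", 1:4)))
  m <- expression_matrix(vals)
  z <- t(apply(vals, 1, function(x) (x - mean(x)) / sd(x)))
  expected <- colMeans(z[c("u1", "u2"), ]) - z["d1", ]
  sc <- score_signature(m, signed_signature("w", up = c("u1", "u2"),
                                            down = "d1"))
  expect_equal(sc$score, unname(expected))
})

test_that("scores are invariant to per-gene affine transforms", {
  set.seed(6)
  vals <- matrix(rnorm(30), nrow = 6,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  sig <- signed_signature("s", up = paste0("g", 1:3), down = paste0("g", 4:6))
  a <- score_signature(expression_matrix(vals), sig)
  scaled <- vals * runif(6, 0.5, 3) + rnorm(6)
  b <- score_signature(expression_matrix(scaled), sig)
  expect_equal(a$score, b$score)
})

test_that("missing and zero-variance signature genes are skipped loudly", {
  vals <- matrix(c(rnorm(4), rep(2, 4)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("ok", "flat"), paste0("s", 1:4)))
  m <- expression_matrix(vals)
  expect_warning(score_signature(m, signed_signature("s", up = c("ok", "gone"))),
                 "absent")
  expect_warning(score_signature(m, signed_signature("s", up = c("ok", "flat"))),
                 "zero-variance")
  expect_error(score_signature(m, signed_signature("s", up = "gone")),
               "no gene")
})

test_that("dichotomize obeys its tie and count conventions", {
  sc <- score_vec(paste0("s", 1:10), c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  top <- dichotomize(sc, "top_quantile", q = 0.30)
  expect_equal(sum(top$label == "positive"), 3)
  expect_setequal(top$sample_id[top$label == "positive"],
                  c("s1", "s2", "s3"))

  flat <- dichotomize(score_vec(paste0("s", 1:5), rep(1, 5)), "median")
  expect_true(all(flat$label == "negative"))

  thr <- dichotomize(sc, "threshold", c = 0)
  expect_true(all(thr$label == "positive"))

  med <- dichotomize(sc, "median")
  expect_equal(sum(med$label == "positive"), 5)

  expect_error(dichotomize(sc, "top_quantile", q = 1.5), "\\(0, 1\\)")
})

test_that("ties at a top-quantile cut are demoted to negative", {
  sc <- score_vec(paste0("s", 1:10), c(9, 9, 8, 8, 8, 8, 3, 2, 1, 0))
  top <- dichotomize(sc, "top_quantile", q = 0.30)
  expect_lte(sum(top$label == "positive"), 3)
  expect_setequal(top$sample_id[top$label == "positive"], c("s1", "s2"))
})

test_that("calibration pins the mutant reference median to the target", {
  set.seed(7)
  ref <- rnorm(61, mean = -0.4)
  sc <- score_vec(paste0("s", 1:9), rnorm(9))
  cal <- calibrate_activity(sc, ref, target = 0.15)
  expect_equal(median(ref + cal$params$offset), 0.15)
  expect_equal(order(cal$scores$score), order(sc$score))  # pure shift
  expect_identical(cal$scores$low, cal$scores$score < 0.15)

  already <- calibrate_activity(sc, c(0.1, 0.15, 0.2), target = 0.15)
  expect_equal(already$params$offset, 0)
  expect_equal(already$scores$score, sc$score)
})

test_that("dichotomize commutes with calibration via a shifted threshold", {
  set.seed(8)
  sc <- score_vec(paste0("s", 1:20), rnorm(20))
  offset <- 0.6
  shifted <- sc; shifted$score <- sc$score + offset
  a <- dichotomize(shifted, "threshold", c = 0.15)
  b <- dichotomize(sc, "threshold", c = 0.15 - offset)
  expect_equal(a$label, b$label)
})

test_that("pearson_with_p matches hand values and edge conventions", {
  x <- c(1, 2, 3)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  out <- pearson_with_p(x, c(1, 3, 2))
  expect_equal(out$r, 0.5)
  t_stat <- 0.5 * sqrt(1 / (1 - 0.25))
  expect_equal(out$p, 2 * pt(-abs(t_stat), df = 1))
  expect_error(pearson_with_p(c(1, 1, 1), x), "constant")
  set.seed(1)
  z <- rnorm(10)
  expect_equal(pearson_with_p(z, z)$r, 1)
})

test_that("pearson p-value holds its type-I error under the null", {
  set.seed(99)
  rej <- mean(vapply(1:1000, function(i) {
    pearson_with_p(rnorm(20), rnorm(20))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.072)
})

test_that("Pten/p53 stratification counts are forced by its rules", {
  set.seed(10)
  pten <- score_vec(paste0("s", 1:100), rnorm(100))
  p53 <- score_vec(paste0("s", 1:100), rnorm(100, mean = 6))
  out <- stratify_pten_p53(pten, p53, pten_low_quantile = 0.25)
  expect_equal(sum(out$status$pten_low), 25)
  expect_equal(unname(out$frequencies["p53_low"]), 0)  # all above 0.15
  expect_error(stratify_pten_p53(pten, score_vec("zz", 1)), "same samples")
})

test_that("planted joint-low fractions are recovered", {
  set.seed(11)
  n <- 4000
  # plant the four cells directly: 18.7% both, 24.4% Pten-low, 65.6% p53-low
  cell <- sample(c("both", "pten", "p53", "none"), n, replace = TRUE,
                 prob = c(0.187, 0.244 - 0.187, 0.656 - 0.187,
                          1 - 0.244 - 0.656 + 0.187))
  pten_low <- cell %in% c("both", "pten")
  p53_low <- cell %in% c("both", "p53")
  pten <- score_vec(paste0("s", 1:n),
                    ifelse(pten_low, rnorm(n, -2), rnorm(n, 2)))
  p53 <- score_vec(paste0("s", 1:n),
                   ifelse(p53_low, 0.15 - runif(n), 0.15 + runif(n)))
  out <- stratify_pten_p53(pten, p53, pten_low_quantile = mean(pten_low))
  expect_lt(abs(out$frequencies["both_low"] - 0.187), 0.03)
  expect_lt(abs(out$frequencies["p53_low"] - 0.656), 0.03)
  expect_lt(abs(out$frequencies["pten_low"] - 0.244), 0.03)
})
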