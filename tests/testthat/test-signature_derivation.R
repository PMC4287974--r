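test_that("per-gene ANOVA matches the hand-evaluated F on one gene", {
  # groups {1,2,3} vs {2,3,4}: pooled s2 = 1, F = (-1)^2 / (2/3) = 1.5
  m <- tiny_matrix(matrix(c(1, 2, 3, 2, 3, 4), nrow = 1),
                   genes = "g1", samples = paste0("s", 1:6),
                   groups = setNames(rep(c("a", "b"), each = 3),
                                     paste0("s", 1:6)))
  de <- anova_per_gene(m)
  expect_equal(de$F, 1.5)
  expect_equal(de$log2fc, -1)
  expect_equal(de$p, pf(1.5, 1, 4, lower.tail = FALSE))
})

test_that("vectorized ANOVA agrees with stats::aov gene by gene", {
  set.seed(21)
  vals <- matrix(rnorm(10 * 9), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:9)))
  grp <- setNames(rep(c("a", "b"), c(4, 5)), paste0("s", 1:9))
  de <- anova_per_gene(expression_matrix(vals, groups = grp))
  for (i in c(1, 5, 10)) {
    fit <- summary(aov(vals[i, ] ~ factor(grp)))[[1]]
    expect_equal(de$F[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(de$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("swapping group labels negates log2FC but not F or p", {
  set.seed(3)
  vals <- matrix(rnorm(5 * 8), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  grp <- setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  m <- expression_matrix(vals, groups = grp)
  de_a <- anova_per_gene(m, ref = "a")
  de_b <- anova_per_gene(m, ref = "b")
  expect_equal(de_a$log2fc, -de_b$log2fc)
  expect_equal(de_a$F, de_b$F)
  expect_equal(de_a$p, de_b$p)
})

test_that("zero-variance genes are flagged degenerate with p = 1", {
  vals <- matrix(c(rep(5, 6), rnorm(6)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), paste0("s", 1:6)))
  grp <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  de <- anova_per_gene(expression_matrix(vals, groups = grp))
  expect_true(de$degenerate[de$gene_id == "flat"])
  expect_equal(de$p[de$gene_id == "flat"], 1)
  expect_false(de$degenerate[de$gene_id == "ok"])
})

test_that("groups smaller than two samples are rejected", {
  m <- tiny_matrix(matrix(rnorm(9), 3), samples = paste0("s", 1:3),
                   groups = setNames(c("a", "a", "b"), paste0("s", 1:3)))
  expect_error(anova_per_gene(m), ">= 2 samples")
})

test_that("BH step-up reproduces hand-evaluated q-values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand step-up: sorted p (0.01, 0.02, 0.9); q_(i) = min_j>=i p_(j) m / j
  expect_equal(bh_fdr(c(0.9, 0.01, 0.02)), c(0.9, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # q is monotone in p (step-up ties allowed)
  set.seed(8)
  p <- runif(50)
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= 0))
})

test_that("fold-change and q filters are strict and complete", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.0, 1.001, -1.2, 2),
                   p = c(1e-4, 1e-4, 1e-4, 0.9),
                   q = c(0.049, 0.049, 0.01, 0.9))
  sig <- derive_signature(de, q_threshold = 0.05, fc_threshold = 2)
  expect_false("a" %in% sig$up)       # log2fc exactly 1 is excluded
  expect_true("b" %in% sig$up)
  expect_true("c" %in% sig$down)
  expect_false("d" %in% c(sig$up, sig$down))
  # completeness on the table itself
  passed <- de$q < 0.05 & abs(de$log2fc) > 1
  expect_setequal(c(sig$up, sig$down), de$gene_id[passed])
})

test_that("an empty signature is a warning, not an error", {
  de <- data.frame(gene_id = "a", log2fc = 0.1, p = 0.9, q = 0.9)
  expect_warning(sig <- derive_signature(de), "no gene passed")
  expect_null(sig)
})

test_that("the seeded tumor fixture yields exactly the planted signature", {
  tum <- simulate_tumor_matrix(tumor_sim_spec(rng_seed = 7))
  out <- derive_de_signature(tum$matrix)
  expect_length(out$signature$up, 7)
  expect_length(out$signature$down, 17)
  expect_setequal(c(out$signature$up, out$signature$down), tum$truth$gene_id)
  expect_setequal(out$signature$up,
                  tum$truth$gene_id[tum$truth$direction == "up"])
})

test_that("a null fixture yields no signature", {
  tum <- simulate_tumor_matrix(tumor_sim_spec(n_genes = 2000,
                                              planted_effect = 0,
                                              rng_seed = 7))
  expect_warning(out <- derive_de_signature(tum$matrix), "no gene passed")
  expect_null(out$signature)
})

test_that("the derived signature is invariant to sample order", {
  tum <- simulate_tumor_matrix(tumor_sim_spec(n_genes = 300, rng_seed = 5))
  set.seed(1)
  perm <- sample(ncol(tum$matrix$values))
  shuffled <- expression_matrix(tum$matrix$values[, perm],
                                groups = tum$matrix$groups[perm])
  a <- derive_de_signature(tum$matrix)$signature
  b <- derive_de_signature(shuffled)$signature
  expect_setequal(a$up, b$up)
  expect_setequal(a$down, b$down)
})

test_that("false-discovery proportion stays near the nominal level", {
  fdp <- vapply(1:10, function(s) {
    tum <- simulate_tumor_matrix(tumor_sim_spec(n_genes = 2000,
                                                rng_seed = s))
    out <- derive_de_signature(tum$matrix)
    found <- c(out$signature$up, out$signature$down)
    mean(!found %in% tum$truth$gene_id)
  }, numeric(1))
  expect_lt(mean(fdp), 0.05 + 0.05)
})
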