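# Fold-change convention, permutation p-values, BH q-values, Korn step-down.

test_that("signed fold-change follows the geometric-mean convention", {
  expect_equal(fold_change(c(10, 10), c(381.7, 381.7)), 38.17)
  expect_equal(fold_change(c(8, 8), c(2, 2)), -4)
  expect_equal(fold_change(c(5, 2), c(5, 2)), 1)
  expect_error(fold_change(c(1, -1), c(2, 2)), "positive")
})

test_that("exhaustive enumeration reproduces the closed-form permutation p", {
  # one gene, {1,2,3} vs {10,11,12} on the log2 scale: C(6,3) = 20
  # assignments, only the observed split and its mirror reach |t|, p = 2/20
  m <- as_expr(2^matrix(c(1, 2, 3, 10, 11, 12), nrow = 1))
  lab <- rep(c("healthy", "malignant"), each = 3)
  de <- permutation_test(m, lab, de_criteria(n_permutations = 1000), seed = 1)
  expect_true(attr(de, "exhaustive"))
  expect_equal(de$p_perm, 0.1)
  # swapping the class labels flips t and leaves p unchanged
  de_sw <- permutation_test(m, rev(lab), de_criteria(n_permutations = 1000),
                            seed = 1, ref = "healthy")
  expect_equal(de_sw$p_perm, de$p_perm)
  expect_equal(de_sw$t, -de$t)
  expect_equal(de_sw$fold_change, -de$fold_change)
})

test_that("a gene identical in both classes gets p = 1 and is flagged", {
  m <- as_expr(rbind(rep(4, 8), 2^rnorm(8, 8)))
  lab <- rep(c("healthy", "malignant"), each = 4)
  de <- permutation_test(m, lab, de_criteria(n_permutations = 200), seed = 2)
  expect_true(de$flagged[1])
  expect_equal(de$p_perm[1], 1)
  expect_equal(de$t[1], 0)
  expect_equal(de$fold_change[1], 1)
})

test_that("reported q-values equal an independent BH implementation", {
  m <- planted_matrix(80, 6, 6, n_sig = 10, shift = 1.5, seed = 3)
  de <- permutation_test(m, rep(c("healthy", "malignant"), each = 6),
                         de_criteria(n_permutations = 400), seed = 3)
  expect_equal(de$q_bh, naive_bh(de$p_perm), tolerance = 1e-12)
  expect_equal(de$q_bh, p.adjust(de$p_perm, "BH"), tolerance = 1e-15)
  expect_true(all(de$q_bh >= de$p_perm - 1e-15))
  # smoothed estimator never returns p below 1/(B+1)
  expect_true(all(de$p_perm >= 1 / (attr(de, "n_permutations_used") + 1)))
})

test_that("permutation engine validates inputs", {
  m <- planted_matrix(10, 3, 1, 0)
  expect_error(permutation_test(m, rep(c("healthy", "malignant"), c(3, 1)),
                                de_criteria()), "at least 2")
  expect_error(permutation_test(planted_matrix(10, 3, 3, 0),
                                rep("healthy", 6), de_criteria()), "two classes")
})

test_that("Welch option is available and agrees on balanced homoscedastic data", {
  m <- planted_matrix(40, 8, 8, n_sig = 5, shift = 1.5, seed = 4)
  lab <- rep(c("healthy", "malignant"), each = 8)
  de_p <- permutation_test(m, lab, de_criteria(n_permutations = 500), seed = 5)
  de_w <- permutation_test(m, lab, de_criteria(n_permutations = 500), seed = 5,
                           var_equal = FALSE)
  # same permutations, near-identical inference for equal group sizes
  expect_equal(cor(de_p$p_perm, de_w$p_perm) > 0.99, TRUE)
  expect_true(all(de_w$p_perm > 0 & de_w$p_perm <= 1))
})

test_that("a fully separated single gene is rejected by the step-down procedure", {
  set.seed(6)
  null_mat <- matrix(abs(rnorm(500)), 1, dimnames = list("g1", NULL))
  pass <- korn_stepdown(c(g1 = 10), null_mat, gamma = 0.01, confidence = 0.99)
  expect_true(pass[["g1"]])
  expect_error(korn_stepdown(c(g1 = 10), null_mat, gamma = 1.5, confidence = 0.99),
               "gamma")
  expect_error(korn_stepdown(c(g1 = 10), null_mat, gamma = 0.01, confidence = 0),
               "confidence")
})

test_that("under the global null the step-down procedure rarely rejects", {
  # gamma small enough that u(r) = 0 throughout: family-wise-like control at
  # the stated confidence; Monte-Carlo check over independent replicates
  reps <- 30
  any_rej <- logical(reps)
  for (i in seq_len(reps)) {
    m <- planted_matrix(50, 8, 8, n_sig = 0, seed = 100 + i)
    de <- permutation_test(m, rep(c("healthy", "malignant"), each = 8),
                           de_criteria(mode = "korn", korn_gamma = 1e-6,
                                       korn_confidence = 0.9,
                                       n_permutations = 300),
                           seed = 200 + i)
    any_rej[i] <- any(de$korn_pass)
  }
  # P(any rejection) <= 0.1; allow 3 Monte-Carlo SE
  expect_lte(mean(any_rej), 0.1 + 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("strong planted effects pass the step-down while nulls are spared", {
  m <- planted_matrix(200, 10, 10, n_sig = 20, shift = 2, seed = 7)
  de <- permutation_test(m, rep(c("healthy", "malignant"), each = 10),
                         de_criteria(mode = "korn"), seed = 8)
  sig <- de_significant(de)
  expect_gte(sum(grepl("^SIG", sig)), 18)
  expect_equal(sum(grepl("^NUL", sig)), 0)
})
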