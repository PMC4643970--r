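# Binomial over/under-representation and Mann-Whitney rank enrichment.

test_that("binomial tails, doubling and Bonferroni follow the definitions", {
  universe <- sprintf("u%03d", 1:100)
  cats <- list(HALF = universe[1:50], TENTH = universe[1:10],
               OTHER = universe[51:100], MISS = c("zz1", "zz2"))
  lst <- universe[1:10]  # all 10 inside HALF and TENTH

  expect_warning(res_g <- overrepresentation(lst, universe, cats,
                                             alternative = "greater"),
                 "MISS")
  p_half <- res_g$p[res_g$category == "HALF"]
  expect_equal(p_half, 0.5^10, tolerance = 1e-12)
  expect_equal(res_g$direction[res_g$category == "HALF"], "+")
  # Bonferroni multiplies by the number of *tested* categories (3 here)
  expect_equal(attr(res_g, "n_categories_tested"), 3L)
  expect_equal(res_g$p_adjusted, pmin(1, res_g$p * 3), tolerance = 1e-15)

  res_t <- suppressWarnings(overrepresentation(lst, universe, cats))
  expect_equal(res_t$p[res_t$category == "HALF"], min(1, 2 * 0.5^10),
               tolerance = 1e-12)
  # matched frequency: half the list in a half-universe category -> p = 1
  bal <- c(universe[1:5], universe[51:55])
  res_b <- suppressWarnings(overrepresentation(bal, universe, cats["HALF"]))
  expect_equal(res_b$p, 1)
  # under-representation carries a minus direction
  res_u <- suppressWarnings(overrepresentation(universe[51:60], universe, cats["HALF"]))
  expect_equal(res_u$direction, "-")
  expect_error(overrepresentation(c("nope"), universe, cats), "subset")
})

test_that("binomial p-values match a brute-force oracle on all small instances", {
  for (N_cat in c(3, 10, 15, 23)) {
    universe <- sprintf("u%02d", 1:30)
    category <- list(C = universe[seq_len(N_cat)])
    for (n in c(5, 12, 30)) {
      for (k in unique(c(0, 1, floor(n / 2), min(n, N_cat)))) {
        if (k > N_cat || (n - k) > (30 - N_cat)) next
        lst <- c(universe[seq_len(k)], universe[N_cat + seq_len(n - k)])
        res <- overrepresentation(lst, universe, category)
        expect_equal(res$p, naive_binom(k, n, N_cat / 30, "two.sided"),
                     tolerance = 1e-12,
                     info = sprintf("N_cat=%d n=%d k=%d", N_cat, n, k))
      }
    }
  }
})

test_that("the hypergeometric option agrees with phyper", {
  universe <- sprintf("u%02d", 1:40)
  category <- list(C = universe[1:12])
  lst <- c(universe[1:6], universe[13:20])
  res <- overrepresentation(lst, universe, category, method = "hypergeometric",
                            alternative = "greater")
  expect_equal(res$p, phyper(5, 12, 28, 14, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("rank enrichment is exact at small n and matches wilcox.test", {
  set.seed(51)
  for (i in 1:8) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)  # continuous: no ties
    fc <- setNames(c(x, y), sprintf("g%02d", seq_len(n1 + n2)))
    res <- rank_enrichment(fc, list(C = names(fc)[seq_len(n1)]))
    oracle <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(res$p, oracle, tolerance = 1e-12, info = paste("instance", i))
    expect_true(res$exact)
  }
})

test_that("strictly top-ranked categories reach the minimal enumeration p", {
  fc <- setNames(c(10, 9, 8, 1, 2, 3, 0.5, -1), sprintf("g%d", 1:8))
  res <- rank_enrichment(fc, list(TOP = c("g1", "g2", "g3")))
  # category occupies the top 3 ranks strictly: two-sided exact p = 2/C(8,3)
  expect_equal(res$p, 2 / choose(8, 3), tolerance = 1e-12)
  expect_equal(res$direction, "+")
})

test_that("the normal approximation applies tie correction and handles degeneracy", {
  set.seed(52)
  x <- round(rnorm(12), 1)
  y <- round(rnorm(15), 1)
  fc <- setNames(c(x, y), sprintf("g%02d", 1:27))
  res <- rank_enrichment(fc, list(C = names(fc)[1:12]))
  oracle <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE)$p.value)
  expect_equal(res$p, oracle, tolerance = 1e-10)
  expect_false(res$exact)
  # a single shared value everywhere: sigma = 0 -> p = 1
  const <- setNames(rep(1, 20), sprintf("g%02d", 1:20))
  expect_equal(rank_enrichment(const, list(C = names(const)[1:10]))$p, 1)
  # categories with < 2 usable members are skipped with a warning
  expect_warning(
    expect_error(rank_enrichment(fc, list(TINY = "g01")), "no usable"),
    "TINY")
})
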