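# Correlation pre-filter and the High-vs-Low microenvironment comparison.

# build a gene with exact Pearson correlation r to an anchor (log2 scale)
gene_with_cor <- function(anchor_log2, r, seed = 1) {
  set.seed(seed)
  x <- anchor_log2 - mean(anchor_log2)
  z <- rnorm(length(x))
  z <- z - mean(z)
  z <- z - sum(z * x) / sum(x * x) * x     # orthogonalize
  y <- r * x / sqrt(sum(x^2)) + sqrt(1 - r^2) * z / sqrt(sum(z^2))
  8 + y                                     # any affine shift keeps r
}

test_that("the filter applies the t-based p-value and joint thresholds", {
  n <- 187
  set.seed(41)
  anchor <- rnorm(n, 8, 1)
  m <- as_expr(rbind(2^anchor,
                     2^gene_with_cor(anchor, 0.22, seed = 2),
                     2^gene_with_cor(anchor, 0.10, seed = 3),
                     2^gene_with_cor(anchor, -0.50, seed = 4),
                     2^gene_with_cor(anchor, 0.50, seed = 5),
                     matrix(3, 1, n)),
               genes = c("CAV1", "R22", "R10", "RNEG", "RPOS", "CONST"))
  fl <- correlation_filter(m, "CAV1")
  get <- function(g, col) fl[[col]][fl$gene == g]
  expect_equal(get("CAV1", "r"), 1)
  expect_true(get("CAV1", "pass"))
  # r = 0.22 at n = 187: t ~ 3.07, two-sided p ~ 0.0025 < 0.01 -> pass
  expect_equal(get("R22", "r"), 0.22, tolerance = 1e-9)
  expect_equal(get("R22", "p"), 2 * pt(-0.22 * sqrt(185) / sqrt(1 - 0.22^2), 185),
               tolerance = 1e-9)
  expect_lt(get("R22", "p"), 0.01)
  expect_true(get("R22", "pass"))
  expect_false(get("R10", "pass"))
  # sign symmetry: -0.5 and +0.5 agree
  expect_equal(get("RNEG", "pass"), get("RPOS", "pass"))
  expect_equal(abs(get("RNEG", "r")), abs(get("RPOS", "r")), tolerance = 1e-9)
  # constant gene: undefined r, recorded fail
  expect_true(is.na(get("CONST", "r")))
  expect_false(get("CONST", "pass"))
  expect_error(correlation_filter(m, "CONST"), "constant")
})

test_that("planted coupled genes pass the filter on a simulated cohort", {
  cfg <- sim_config(n_healthy_cd4 = 5L, n_healthy_cd8 = 5L,
                    n_per_subtype = c(NOS = 120L), n_genes = 80L,
                    probes_per_gene_range = c(1L, 1L),
                    planted_signature = data.frame(gene = "CAV1", NOS = 16),
                    cav1_high_prob = c(NOS = 0.6), n_tme_genes = 10L,
                    tme_coupling_r = 0.7, panel_size = 20L, seed = 9L)
  co <- simulate_cohort(cfg)
  g <- collapse_probes(co$expression, co$probe_map)
  mal <- co$annotation$sample_id[co$annotation$class == "malignant"]
  fl <- correlation_filter(g, "CAV1", samples = mal)
  expect_true(all(co$truth$tme_genes$gene %in% fl$gene[fl$pass]))
})

test_that("the High-vs-Low run equals a direct class comparison on the filtered set", {
  cfg <- sim_config(n_healthy_cd4 = 4L, n_healthy_cd8 = 4L,
                    n_per_subtype = c(NOS = 40L), n_genes = 60L,
                    probes_per_gene_range = c(1L, 1L),
                    planted_signature = data.frame(gene = "CAV1", NOS = 16),
                    cav1_high_prob = c(NOS = 0.6), n_tme_genes = 8L,
                    tme_coupling_r = 0.8, panel_size = 20L, seed = 12L)
  co <- simulate_cohort(cfg)
  g <- collapse_probes(co$expression, co$probe_map)
  st <- stratify_expression(g, co$annotation)
  mal <- co$annotation$sample_id[co$annotation$class == "malignant"]
  fl <- correlation_filter(g, "CAV1", samples = mal)
  crit <- de_criteria(mode = "korn", n_permutations = 400)
  res <- tme_de(g, st, fl, criteria = crit, seed = 33)
  direct <- permutation_test(g[fl$gene[fl$pass], mal], st$labels[mal],
                             criteria = crit, seed = 33, ref = "Low")
  expect_equal(res$de$p_perm, direct$p_perm)
  expect_equal(res$de$korn_pass, direct$korn_pass)
  expect_equal(res$de$fold_change, direct$fold_change)
  # count identity: fraction up recomputes from the up/down split
  s <- res$summary
  expect_equal(s$n_up + s$n_down, s$n_de)
  if (s$n_de > 0) expect_equal(s$fraction_up, s$n_up / s$n_de)
  # the planted coupled genes dominate the DE calls
  expect_gte(sum(co$truth$tme_genes$gene %in% de_significant(res$de)), 6)
})

test_that("shuffled High/Low labels give a near-empty reject set", {
  cfg <- sim_config(n_healthy_cd4 = 4L, n_healthy_cd8 = 4L,
                    n_per_subtype = c(NOS = 40L), n_genes = 60L,
                    probes_per_gene_range = c(1L, 1L),
                    planted_signature = data.frame(gene = "CAV1", NOS = 16),
                    cav1_high_prob = c(NOS = 0.6), n_tme_genes = 8L,
                    tme_coupling_r = 0.8, panel_size = 20L, seed = 13L)
  co <- simulate_cohort(cfg)
  g <- collapse_probes(co$expression, co$probe_map)
  st <- stratify_expression(g, co$annotation)
  mal <- co$annotation$sample_id[co$annotation$class == "malignant"]
  fl <- correlation_filter(g, "CAV1", samples = mal)
  set.seed(14)
  shuffled <- setNames(sample(st$labels), names(st$labels))
  res <- tme_de(g, shuffled, fl,
                criteria = de_criteria(mode = "korn", n_permutations = 400),
                seed = 15)
  expect_lte(res$summary$n_de, max(1, round(0.02 * res$summary$n_tested)))
})
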