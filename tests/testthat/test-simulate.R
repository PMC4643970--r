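# Synthetic cohort generator: planted structure, determinism, edge cases.

small_config <- function(...) {
  defaults <- list(
    n_healthy_cd4 = 5L, n_healthy_cd8 = 5L,
    n_per_subtype = c(AITL = 8L, ALCL = 8L),
    n_genes = 60L, probes_per_gene_range = c(1L, 3L),
    planted_signature = pan_signature_foldchanges()[, c("gene", "AITL", "ALCL")],
    cav1_high_prob = c(AITL = 0.8, ALCL = 0.5),
    n_tme_genes = 5L, panel_size = 40L, seed = 11L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("identical configurations give identical cohorts, all values positive", {
  c1 <- simulate_cohort(small_config())
  c2 <- simulate_cohort(small_config())
  expect_identical(c1, c2)
  expect_true(all(c1$expression > 0))
  expect_equal(nrow(c1$expression), nrow(c1$probe_map))
  expect_equal(ncol(c1$expression), nrow(c1$annotation))
  # truth covers exactly the planted genes; every malignant sample labelled
  expect_setequal(rownames(c1$truth$planted_directions),
                  pan_signature_foldchanges()$gene)
  expect_setequal(names(c1$truth$cav1_high),
                  c1$annotation$sample_id[c1$annotation$class == "malignant"])
})

test_that("zero-noise group means reproduce the planted fold-changes exactly", {
  # cav1_high_prob = NULL: CAV1 follows its planted per-subtype fold-change
  cfg <- sim_config(
    n_healthy_cd4 = 5L, n_healthy_cd8 = 5L,
    n_per_subtype = c(AITL = 8L, ALCL = 8L),
    n_genes = 60L, probes_per_gene_range = c(1L, 3L),
    planted_signature = pan_signature_foldchanges()[, c("gene", "AITL", "ALCL")],
    cav1_high_prob = NULL, n_tme_genes = 0L, panel_size = 40L,
    noise_log2_sd = 0, seed = 11L)
  co <- simulate_cohort(cfg)
  gene_mat <- collapse_probes(co$expression, co$probe_map)
  ann <- co$annotation
  healthy <- ann$class == "healthy"
  fc_tab <- pan_signature_foldchanges()
  for (s in c("AITL", "ALCL")) {
    in_s <- ann$subtype == s
    for (gi in c("CAV1", "BCL10", "TNFRSF14")) {
      planted <- fc_tab[[s]][fc_tab$gene == gi]
      ratio <- gene_mat[gi, in_s][1] / gene_mat[gi, healthy][1]
      expected <- if (planted >= 1) planted else 1 / (-planted)
      expect_equal(unname(ratio), expected, tolerance = 1e-9)
      # means equal generating means: all samples in a group identical
      expect_equal(stats::sd(gene_mat[gi, in_s]), 0)
    }
  }
  # CAV1 / AITL generating ratio is exactly the planted 16.33
  in_aitl <- ann$subtype == "AITL"
  expect_equal(unname(gene_mat["CAV1", in_aitl][1] / gene_mat["CAV1", healthy][1]),
               16.33, tolerance = 1e-9)
})

test_that("null configuration plants nothing and labels every sample Low", {
  flat <- pan_signature_foldchanges()[, c("gene", "AITL", "ALCL")]
  flat$AITL <- 1
  flat$ALCL <- 1
  co <- simulate_cohort(small_config(planted_signature = flat,
                                     cav1_high_prob = c(AITL = 0, ALCL = 0)))
  expect_true(all(co$truth$planted_directions == 0))
  expect_true(all(!co$truth$cav1_high))
})

test_that("maximal probe per gene matches the recorded truth at zero noise", {
  cfg <- small_config(noise_log2_sd = 0, n_tme_genes = 0L)
  co <- simulate_cohort(cfg)
  g <- collapse_probes(co$expression, co$probe_map)
  chosen <- attr(g, "chosen_probes")
  expect_identical(unname(chosen[names(co$truth$max_probe)]),
                   unname(co$truth$max_probe))
})

test_that("default cohort CAV1-High counts land in the planted binomial range", {
  co <- simulate_cohort(sim_config(seed = 7L))
  ann <- co$annotation
  aitl <- ann$sample_id[ann$class == "malignant" & ann$subtype == "AITL"]
  n_high <- sum(co$truth$cav1_high[aitl])
  expect_gte(n_high, qbinom(0.005, 43, 0.77))
  expect_lte(n_high, qbinom(0.995, 43, 0.77))
})

test_that("coupled genes converge to the target correlation at large n", {
  cfg <- sim_config(
    n_healthy_cd4 = 5L, n_healthy_cd8 = 5L, n_per_subtype = c(NOS = 1000L),
    n_genes = 30L, probes_per_gene_range = c(1L, 1L),
    planted_signature = data.frame(gene = "CAV1", NOS = 16),
    cav1_high_prob = c(NOS = 0.6), n_tme_genes = 4L, tme_coupling_r = 0.6,
    panel_size = 10L, seed = 5L
  )
  co <- simulate_cohort(cfg)
  mal <- co$annotation$class == "malignant"
  z <- log2(co$expression[co$truth$max_probe[["CAV1"]], mal])
  for (i in seq_len(nrow(co$truth$tme_genes))) {
    g <- co$truth$tme_genes$gene[i]
    y <- log2(co$expression[co$truth$max_probe[[g]], mal])
    r_hat <- stats::cor(y, z)
    expect_lt(abs(r_hat - co$truth$tme_genes$sign[i] * 0.6), 0.1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(n_per_subtype = c(AITL = 0L, ALCL = 8L)), "counts")
  expect_error(small_config(cav1_high_prob = c(AITL = 1.2, ALCL = 0.5)), "\\[0, 1\\]")
  expect_error(small_config(n_genes = 10L) |> simulate_cohort(), "planted genes")
  bad_fc <- pan_signature_foldchanges()[, c("gene", "AITL", "ALCL")]
  bad_fc$AITL[1] <- 0.5
  expect_error(small_config(planted_signature = bad_fc), "FC")
})

test_that("staining-call simulation matches requested marginals exactly", {
  counts <- data.frame(subtype = c("AITL", "X", "X"),
                       marker = c("BCL10", "M", "N"),
                       n_positive = c(7L, 0L, 5L), n_total = c(8L, 5L, 5L))
  tab <- simulate_ihc_table(counts, seed = 3, cores_per_patient = 1L)
  expect_s3_class(tab, "staining_table")
  aitl <- tab[tab$subtype == "AITL" & tab$marker == "BCL10", ]
  expect_equal(sum(aitl$lymphoid_call %in% c("positive", "light")), 7L)
  expect_equal(nrow(aitl), 8L)
  m <- tab[tab$marker == "M", ]
  expect_true(all(m$lymphoid_call == "negative"))
  expect_equal(nrow(m), 5L)
  n <- tab[tab$marker == "N", ]
  expect_true(all(n$lymphoid_call %in% c("positive", "light")))
  expect_error(simulate_ihc_table(data.frame(subtype = "X", marker = "M",
                                             n_positive = -1L, n_total = 5L)),
               "non-negative")
  expect_error(simulate_ihc_table(data.frame(subtype = "X", marker = "M",
                                             n_positive = 6L, n_total = 5L)),
               "exceed")
})
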