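# Synthetic cohort simulator. Expression follows a log2-normal model:
# log2 signal = gene baseline + subtype effect + probe offset + N(0, noise),
# exponentiated to a positive, MAS5-like linear scale so planted effects are
# multiplicative fold-changes. CAV1 is optionally bimodal among malignant
# samples (High: baseline * 2^shift, Low: the healthy distribution), and a
# block of microenvironment genes is generated as a linear function of each
# sample's measured CAV1 log2 signal with noise calibrated to a target
# Pearson correlation.

#' Configuration for the synthetic T-cell lymphoma cohort
#'
#' Defaults emulate the reference study conditions: 52 healthy CD4+/CD8+
#' controls, 187 malignant samples across five subtypes
#' ([default_subtype_sizes()]), the 21-gene planted signature with its
#' published per-subtype fold-changes ([pan_signature_foldchanges()]), and
#' per-subtype CAV1-High probabilities ([default_cav1_high_prob()]).
#'
#' @param n_healthy_cd4,n_healthy_cd8 healthy control counts (26 + 26 = 52)
#' @param n_per_subtype named integer vector of malignant sample counts
#' @param n_genes total number of genes (planted + null)
#' @param probes_per_gene_range integer interval `c(lo, hi)`, lo >= 1
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 expression
#' @param noise_log2_sd within-group log2 noise standard deviation
#' @param planted_signature data.frame with column `gene` and one signed
#'   fold-change column per subtype (|FC| >= 1; negative = down-regulated)
#' @param cav1_high_prob named per-subtype probability that a malignant
#'   sample is CAV1-High, or NULL to disable the bimodal CAV1 model (CAV1
#'   then follows its planted fold-changes like any other gene)
#' @param cav1_high_log2_shift log2 shift of CAV1-High samples above the
#'   healthy CAV1 baseline
#' @param n_tme_genes number of CAV1-coupled microenvironment genes
#' @param tme_coupling_r target absolute Pearson correlation (log2 scale,
#'   malignant samples) between a coupled gene and CAV1
#' @param tme_positive_frac fraction of coupled genes with positive coupling
#' @param panel_size size of the emitted T-cell compartment panel gene set
#'   (planted genes plus sampled null genes; coupled genes are excluded)
#' @param seed integer RNG seed; identical configurations give
#'   byte-identical cohorts
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_healthy_cd4 = 26L,
                       n_healthy_cd8 = 26L,
                       n_per_subtype = default_subtype_sizes(),
                       n_genes = 2000L,
                       probes_per_gene_range = c(1L, 3L),
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 1.2,
                       noise_log2_sd = 0.5,
                       planted_signature = pan_signature_foldchanges(),
                       cav1_high_prob = default_cav1_high_prob(),
                       cav1_high_log2_shift = 5,
                       n_tme_genes = 30L,
                       tme_coupling_r = 0.6,
                       tme_positive_frac = 2 / 3,
                       panel_size = 217L,
                       seed = 1L) {
  check_count(n_healthy_cd4, "n_healthy_cd4")
  check_count(n_healthy_cd8, "n_healthy_cd8")
  check_count(n_per_subtype, "n_per_subtype")
  if (is.null(names(n_per_subtype)) || any(names(n_per_subtype) == "")) {
    stop("'n_per_subtype' must be a named vector of subtype sample counts")
  }
  check_count(n_genes, "n_genes")
  if (length(probes_per_gene_range) != 2L || probes_per_gene_range[1L] < 1L ||
      probes_per_gene_range[2L] < probes_per_gene_range[1L]) {
    stop("'probes_per_gene_range' must be c(lo, hi) with 1 <= lo <= hi")
  }
  if (noise_log2_sd < 0 || baseline_log2_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (!is.data.frame(planted_signature) || !"gene" %in% names(planted_signature)) {
    stop("'planted_signature' must be a data.frame with a 'gene' column")
  }
  missing_sub <- setdiff(names(n_per_subtype), names(planted_signature))
  if (nrow(planted_signature) > 0L && length(missing_sub) > 0L) {
    stop("'planted_signature' lacks fold-change columns for: ",
         paste(missing_sub, collapse = ", "))
  }
  if (anyDuplicated(planted_signature$gene)) stop("planted genes must be unique")
  fc <- as.matrix(planted_signature[, names(n_per_subtype), drop = FALSE])
  if (nrow(fc) > 0L && (any(!is.finite(fc)) || any(abs(fc) < 1))) {
    stop("planted fold-changes must be finite with |FC| >= 1")
  }
  if (!is.null(cav1_high_prob)) {
    check_probability(cav1_high_prob, "cav1_high_prob")
    if (!all(names(n_per_subtype) %in% names(cav1_high_prob))) {
      stop("'cav1_high_prob' must cover every subtype")
    }
  }
  check_count(n_tme_genes, "n_tme_genes", min = 0L)
  if (tme_coupling_r <= 0 || tme_coupling_r > 1) {
    stop("'tme_coupling_r' must be in (0, 1]")
  }
  check_probability(tme_positive_frac, "tme_positive_frac")
  check_count(panel_size, "panel_size")
  cfg <- list(
    n_healthy_cd4 = as.integer(n_healthy_cd4),
    n_healthy_cd8 = as.integer(n_healthy_cd8),
    n_per_subtype = stats::setNames(as.integer(n_per_subtype), names(n_per_subtype)),
    n_genes = as.integer(n_genes),
    probes_per_gene_range = as.integer(probes_per_gene_range),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd,
    planted_signature = planted_signature,
    cav1_high_prob = cav1_high_prob,
    cav1_high_log2_shift = cav1_high_log2_shift,
    n_tme_genes = as.integer(n_tme_genes),
    tme_coupling_r = tme_coupling_r,
    tme_positive_frac = tme_positive_frac,
    panel_size = as.integer(panel_size),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# signed linear fold-change -> additive log2 effect
fc_to_log2 <- function(f) {
  out <- numeric(length(f))
  up <- f >= 1
  out[up] <- log2(f[up])
  out[!up] <- -log2(-f[!up])
  out
}

#' Simulate a probe-level expression cohort with planted truth
#'
#' @param config a [sim_config()] object
#' @return an object of class `tcl_cohort`: a list with elements
#'   `expression` (probe x sample linear-scale matrix), `probe_map`
#'   (data.frame probe_id, gene_symbol), `annotation` (sample_id, class,
#'   subtype), `gene_sets` (named list, incl. the `TCELL_COMPARTMENT` panel),
#'   `truth` (planted directions, per-sample CAV1-High indicators, coupled
#'   genes, maximal probe per gene, seed) and `config`
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config object")
  set.seed(config$seed)
  subtypes <- names(config$n_per_subtype)
  planted <- config$planted_signature
  n_planted <- nrow(planted)
  if (n_planted > config$n_genes) {
    stop("more planted genes (", n_planted, ") than n_genes (", config$n_genes, ")")
  }

  ## samples -----------------------------------------------------------------
  healthy_ids <- c(sprintf("H_CD4_%02d", seq_len(config$n_healthy_cd4)),
                   sprintf("H_CD8_%02d", seq_len(config$n_healthy_cd8)))
  mal_ids <- unlist(lapply(subtypes, function(s) {
    sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", s), seq_len(config$n_per_subtype[[s]]))
  }), use.names = FALSE)
  annotation <- data.frame(
    sample_id = c(healthy_ids, mal_ids),
    class = c(rep("healthy", length(healthy_ids)), rep("malignant", length(mal_ids))),
    subtype = c(rep("CD4", config$n_healthy_cd4), rep("CD8", config$n_healthy_cd8),
                rep(subtypes, config$n_per_subtype)),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(annotation)
  is_mal <- annotation$class == "malignant"

  ## genes and probes --------------------------------------------------------
  n_null <- config$n_genes - n_planted
  genes <- c(planted$gene, if (n_null > 0L) sprintf("G%04d", seq_len(n_null)))
  baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  names(baseline) <- genes

  lo <- config$probes_per_gene_range[1L]
  hi <- config$probes_per_gene_range[2L]
  k <- if (lo == hi) rep(lo, config$n_genes) else
    sample(seq.int(lo, hi), config$n_genes, replace = TRUE)
  gene_idx <- rep(seq_len(config$n_genes), k)
  probe_within <- sequence(k)
  probe_ids <- sprintf("%s_p%d", genes[gene_idx], probe_within)
  max_within <- vapply(k, function(kk) sample.int(kk, 1L), 1L)
  is_max <- probe_within == max_within[gene_idx]
  offsets <- numeric(length(probe_ids))
  offsets[!is_max] <- stats::runif(sum(!is_max), -2, -0.25)

  ## planted subtype effects (log2, gene x subtype) --------------------------
  eff <- matrix(0, config$n_genes, length(subtypes),
                dimnames = list(genes, subtypes))
  if (n_planted > 0L) {
    for (s in subtypes) eff[planted$gene, s] <- fc_to_log2(planted[[s]])
  }

  ## bimodal CAV1 ------------------------------------------------------------
  bimodal <- !is.null(config$cav1_high_prob) && "CAV1" %in% genes
  cav1_high <- stats::setNames(rep(FALSE, sum(is_mal)), annotation$sample_id[is_mal])
  if (bimodal) {
    p_high <- config$cav1_high_prob[annotation$subtype[is_mal]]
    cav1_high[] <- stats::rbinom(sum(is_mal), 1L, p_high) == 1L
  }

  ## per-sample gene-level effects -------------------------------------------
  eff_sample <- matrix(0, config$n_genes, n_samples,
                       dimnames = list(genes, annotation$sample_id))
  eff_sample[, is_mal] <- eff[, annotation$subtype[is_mal], drop = FALSE]
  if (bimodal) {
    eff_sample["CAV1", ] <- 0
    eff_sample["CAV1", names(cav1_high)[cav1_high]] <- config$cav1_high_log2_shift
  }

  ## probe-level log2 matrix -------------------------------------------------
  L <- eff_sample[gene_idx, , drop = FALSE]
  L <- L + (baseline[gene_idx] + offsets)
  L <- L + matrix(stats::rnorm(length(probe_ids) * n_samples, 0, config$noise_log2_sd),
                  nrow = length(probe_ids))
  rownames(L) <- probe_ids

  ## CAV1-coupled microenvironment genes -------------------------------------
  tme_truth <- data.frame(gene = character(), sign = integer(),
                          target_r = numeric(), stringsAsFactors = FALSE)
  null_genes <- setdiff(genes, planted$gene)
  if (config$n_tme_genes > 0L) {
    if (!"CAV1" %in% genes) stop("coupled microenvironment genes require CAV1 among the planted genes")
    if (config$n_tme_genes > length(null_genes)) {
      stop("n_tme_genes exceeds the number of unplanted genes")
    }
    tme_genes <- sample(null_genes, config$n_tme_genes)
    n_pos <- round(config$tme_positive_frac * config$n_tme_genes)
    signs <- rep(c(1L, -1L), c(n_pos, config$n_tme_genes - n_pos))
    cav1_max_probe <- probe_ids[gene_idx == match("CAV1", genes) & is_max]
    z <- L[cav1_max_probe, ]
    sz <- stats::sd(z[is_mal])
    s_noise <- if (sz > 0) sz * sqrt(1 / config$tme_coupling_r^2 - 1) else 0
    z_c <- z - mean(z[is_mal])
    for (i in seq_along(tme_genes)) {
      g <- tme_genes[i]
      rows <- which(gene_idx == match(g, genes))
      base_g <- baseline[g] + offsets[rows]
      coup <- signs[i] * z_c
      L[rows, ] <- outer(base_g, rep(1, n_samples)) +
        matrix(coup, nrow = length(rows), ncol = n_samples, byrow = TRUE) +
        matrix(stats::rnorm(length(rows) * n_samples, 0, s_noise), nrow = length(rows))
    }
    tme_truth <- data.frame(gene = tme_genes, sign = signs,
                            target_r = config$tme_coupling_r,
                            stringsAsFactors = FALSE)
  }

  ## gene sets ---------------------------------------------------------------
  panel_nulls <- setdiff(null_genes, tme_truth$gene)
  n_fill <- max(0L, min(config$panel_size - n_planted, length(panel_nulls)))
  panel <- c(planted$gene, if (n_fill > 0L) sample(panel_nulls, n_fill))
  gene_sets <- list(
    TCELL_COMPARTMENT = panel,
    CAV1_COUPLED = c("CAV1", tme_truth$gene),
    RANDOM_A = sample(genes, min(50L, length(genes))),
    RANDOM_B = sample(genes, min(80L, length(genes)))
  )
  attr(gene_sets, "descriptions") <- c(
    TCELL_COMPARTMENT = "T-cell compartment panel (planted signature + null genes)",
    CAV1_COUPLED = "CAV1 and its coupled microenvironment genes",
    RANDOM_A = "random gene set", RANDOM_B = "random gene set")

  ## planted truth directions ------------------------------------------------
  directions <- matrix(0L, n_planted, length(subtypes),
                       dimnames = list(planted$gene, subtypes))
  if (n_planted > 0L) {
    directions[] <- sign(eff[planted$gene, , drop = FALSE])
    if (bimodal) {
      directions["CAV1", ] <- ifelse(
        config$cav1_high_prob[subtypes] > 0,
        sign(config$cav1_high_log2_shift), 0L)
    }
  }

  truth <- list(
    planted_directions = directions,
    cav1_high = cav1_high,
    tme_genes = tme_truth,
    max_probe = stats::setNames(probe_ids[is_max], genes),
    seed = config$seed
  )

  out <- list(
    expression = 2^L,
    probe_map = data.frame(probe_id = probe_ids, gene_symbol = genes[gene_idx],
                           stringsAsFactors = FALSE),
    annotation = annotation,
    gene_sets = gene_sets,
    truth = truth,
    config = config
  )
  class(out) <- "tcl_cohort"
  out
}

#' @export
print.tcl_cohort <- function(x, ...) {
  cat("Synthetic T-cell lymphoma cohort\n")
  cat(sprintf("  %d probes / %d genes x %d samples (%d healthy, %d malignant)\n",
              nrow(x$expression), x$config$n_genes, ncol(x$expression),
              sum(x$annotation$class == "healthy"),
              sum(x$annotation$class == "malignant")))
  cat(sprintf("  planted signature genes: %d; coupled microenvironment genes: %d\n",
              nrow(x$truth$planted_directions), nrow(x$truth$tme_genes)))
  cat(sprintf("  seed: %d\n", x$truth$seed))
  invisible(x)
}

#' Write all cohort artifacts to a directory
#'
#' Emits expression.tsv, probe_map.tsv, annotation.tsv, gene_sets.gmt and
#' truth.json.
#' @param cohort a `tcl_cohort`
#' @param dir output directory (created if absent)
#' @return invisibly, the named vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(cohort$expression, paths[["expression"]], id_name = "probe_id")
  write_probe_map(cohort$probe_map, paths[["probe_map"]])
  write_annotation(cohort$annotation, paths[["annotation"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  tr <- cohort$truth
  tr$planted_directions <- as.data.frame(tr$planted_directions)
  tr$cav1_high <- as.list(tr$cav1_high)
  write_truth(tr, paths[["truth"]])
  invisible(paths)
}

#' Simulate a tissue-microarray staining-call table with exact marginals
#'
#' Emits one record per core such that, under the any-core-positive patient
#' rule, the patient-level positive counts match the requested marginals
#' exactly. A fraction of positive calls are scored "light" (light counts as
#' positive downstream).
#'
#' @param counts data.frame with columns subtype, marker, n_positive,
#'   n_total (patient-level marginals); defaults to [default_ihc_counts()]
#' @param seed integer RNG seed
#' @param cores_per_patient cores per patient and marker (the reference
#'   microarray has 130 cores for 65 patients)
#' @return a `staining_table` data.frame with columns core_id, patient_id,
#'   subtype, marker, lymphoid_call, stromal_call
#' @export
simulate_ihc_table <- function(counts = default_ihc_counts(), seed = 1L,
                               cores_per_patient = 2L) {
  need <- c("subtype", "marker", "n_positive", "n_total")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop("'counts' must be a data.frame with columns ", paste(need, collapse = ", "))
  }
  if (any(counts$n_positive < 0) || any(counts$n_total < 0)) {
    stop("staining counts must be non-negative")
  }
  if (any(counts$n_positive > counts$n_total)) {
    stop("n_positive cannot exceed n_total")
  }
  check_count(cores_per_patient, "cores_per_patient")
  set.seed(as.integer(seed))
  recs <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    st <- counts$subtype[i]; mk <- counts$marker[i]
    nt <- counts$n_total[i]; np <- counts$n_positive[i]
    if (nt == 0L) next
    patients <- sprintf("%s_pt%02d", gsub("[^A-Za-z0-9]", "", st), seq_len(nt))
    pos <- rep(FALSE, nt)
    pos[sample.int(nt, np)] <- TRUE
    per_core <- lapply(seq_len(nt), function(j) {
      calls <- if (pos[j]) {
        first <- sample(c("positive", "light"), 1L, prob = c(0.85, 0.15))
        rest <- if (cores_per_patient > 1L) {
          sample(c("positive", "negative"), cores_per_patient - 1L, replace = TRUE)
        } else character()
        c(first, rest)
      } else {
        rep("negative", cores_per_patient)
      }
      data.frame(
        core_id = sprintf("%s_core%d", patients[j], seq_len(cores_per_patient)),
        patient_id = patients[j], subtype = st, marker = mk,
        lymphoid_call = calls,
        stromal_call = sample(c("positive", "negative", "none-recorded"),
                              cores_per_patient, replace = TRUE,
                              prob = c(0.15, 0.15, 0.7)),
        stringsAsFactors = FALSE
      )
    })
    recs[[i]] <- do.call(rbind, per_core)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("staining_table", "data.frame")
  out
}
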