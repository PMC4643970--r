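# End-to-end pipeline: simulate -> collapse -> panel filter -> per-subtype
# DE -> signature -> TSP -> stratify -> TME -> enrichment -> IHC, from a
# single configuration, with a provenance manifest (parameters, seeds,
# output checksums, per-stage summary counts).

#' Pipeline configuration
#'
#' All thresholds default to the reference settings: DE at p < 0.001 and
#' BH FDR < 0.001 with 1,000 permutations; the microenvironment run under a
#' 1% false-discovery proportion at 99% confidence; the stratification
#' threshold two SD above the healthy mean; the correlation filter at
#' p < 0.01 and |r| >= 0.22; Bonferroni 0.05 for enrichment.
#'
#' @param outdir output directory
#' @param seed master seed; per-stage seeds derive from it
#' @param simulate a [sim_config()] (its own seed is overridden by `seed`)
#' @param de [de_criteria()] for the per-subtype DE runs
#' @param tme_criteria [de_criteria()] for the High-vs-Low run
#' @param min_support relaxed-signature support (default 3)
#' @param tsp_scheme `"loocv"` or `"resubstitution"`
#' @param stratify_gene gene for threshold stratification (default "CAV1")
#' @param corr_p_cutoff,corr_r_cutoff correlation-filter thresholds
#' @param enrich_alpha Bonferroni-adjusted enrichment threshold
#' @param ihc_counts staining marginals for the simulated microarray
#' @param stages named logical vector toggling stages (names among
#'   simulate, collapse, panel_filter, de, signature, tsp, stratify, tme,
#'   enrichment, ihc); disabled stages are marked skipped and stages whose
#'   inputs are missing fail cleanly
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(outdir = tempfile("pantcl_run_"),
                            seed = 1L,
                            simulate = sim_config(),
                            de = de_criteria(),
                            tme_criteria = de_criteria(mode = "korn"),
                            min_support = 3L,
                            tsp_scheme = "loocv",
                            stratify_gene = "CAV1",
                            corr_p_cutoff = 0.01,
                            corr_r_cutoff = 0.22,
                            enrich_alpha = 0.05,
                            ihc_counts = default_ihc_counts(),
                            stages = NULL) {
  all_stages <- c("simulate", "collapse", "panel_filter", "de", "signature",
                  "tsp", "stratify", "tme", "enrichment", "ihc")
  enabled <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) {
    unknown <- setdiff(names(stages), all_stages)
    if (length(unknown) > 0L) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
    enabled[names(stages)] <- as.logical(stages)
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              de = de, tme_criteria = tme_criteria,
              min_support = as.integer(min_support), tsp_scheme = tsp_scheme,
              stratify_gene = stratify_gene, corr_p_cutoff = corr_p_cutoff,
              corr_r_cutoff = corr_r_cutoff, enrich_alpha = enrich_alpha,
              ihc_counts = ihc_counts, stages = enabled)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `simulate`, `de`
#' and `tme_criteria` sub-maps are passed to [sim_config()] and
#' [de_criteria()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("outdir", "seed", "min_support", "tsp_scheme", "stratify_gene",
               "corr_p_cutoff", "corr_r_cutoff", "enrich_alpha")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    for (vec in c("n_per_subtype", "cav1_high_prob", "probes_per_gene_range")) {
      if (!is.null(sim_args[[vec]])) sim_args[[vec]] <- unlist(sim_args[[vec]])
    }
    if (!is.null(sim_args$planted_signature)) {
      sim_args$planted_signature <- as.data.frame(sim_args$planted_signature)
    }
    args$simulate <- do.call(sim_config, sim_args)
  }
  if (!is.null(y$de)) args$de <- do.call(de_criteria, y$de)
  if (!is.null(y$tme_criteria)) args$tme_criteria <- do.call(de_criteria, y$tme_criteria)
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under `config$outdir` and recording a manifest
#' (`manifest.json`): parameters, seeds, md5 checksums of outputs, and
#' per-stage summary counts. A stage failure writes the partial manifest
#' (stage marked `failed`, run marked incomplete) and then halts with the
#' stage name and cause. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config a [pipeline_config()] (or path to a YAML file)
#' @return the run manifest, invisibly a list (also written as JSON)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stop("'config' must come from pipeline_config()")
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), complete = FALSE)
  env <- new.env(parent = emptyenv())

  finish_stage <- function(name, status, outputs = character(), summary = NULL) {
    entry <- list(status = status)
    if (length(outputs) > 0L) {
      entry$outputs <- as.list(tools::md5sum(outputs))
    }
    if (!is.null(summary)) entry$summary <- summary
    manifest$stages[[name]] <<- entry
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!config$stages[[name]]) {
      finish_stage(name, "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      finish_stage(name, "failed", summary = list(error = conditionMessage(res)))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    finish_stage(name, "complete", outputs = res$outputs, summary = res$summary)
  }
  need <- function(what, stage) {
    if (is.null(env[[what]])) {
      stop("requires output of a disabled or failed stage ('", stage, "')")
    }
    env[[what]]
  }

  run_stage("simulate", function() {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    env$cohort <- simulate_cohort(sim_cfg)
    paths <- write_cohort(env$cohort, outdir)
    list(outputs = unname(paths),
         summary = list(n_probes = nrow(env$cohort$expression),
                        n_genes = sim_cfg$n_genes,
                        n_samples = ncol(env$cohort$expression)))
  })

  run_stage("collapse", function() {
    cohort <- need("cohort", "simulate")
    env$gene_mat <- collapse_probes(cohort$expression, cohort$probe_map)
    path <- file.path(outdir, "expression_gene.tsv")
    write_expression(env$gene_mat, path, id_name = "gene")
    list(outputs = path, summary = list(n_genes = nrow(env$gene_mat)))
  })

  run_stage("panel_filter", function() {
    cohort <- need("cohort", "simulate")
    mat <- need("gene_mat", "collapse")
    env$panel_mat <- filter_to_panel(mat, cohort$gene_sets$TCELL_COMPARTMENT)
    path <- file.path(outdir, "expression_panel.tsv")
    write_expression(env$panel_mat, path, id_name = "gene")
    list(outputs = path, summary = list(n_genes = nrow(env$panel_mat)))
  })

  run_stage("de", function() {
    cohort <- need("cohort", "simulate")
    mat <- need("panel_mat", "panel_filter")
    ann <- cohort$annotation
    subtypes <- names(config$simulate$n_per_subtype)
    env$de_results <- list()
    paths <- character()
    for (i in seq_along(subtypes)) {
      s <- subtypes[i]
      keep <- ann$class == "healthy" | ann$subtype == s
      de <- permutation_test(mat[, ann$sample_id[keep], drop = FALSE],
                             ann$class[keep], criteria = config$de,
                             seed = config$seed + i)
      env$de_results[[s]] <- de
      p <- file.path(outdir, sprintf("de_%s.tsv", gsub("[^A-Za-z0-9]", "", s)))
      utils::write.table(as.data.frame(de), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    list(outputs = paths,
         summary = lapply(env$de_results, function(d) length(de_significant(d))))
  })

  run_stage("signature", function() {
    des <- need("de_results", "de")
    env$signature <- intersect_signatures(des, min_support = config$min_support)
    p1 <- file.path(outdir, "signature.tsv")
    utils::write.table(env$signature$relaxed, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- p1
    if (length(env$signature$pan_up) + length(env$signature$pan_down) > 0L) {
      p2 <- file.path(outdir, "signature_pan.gmt")
      write_signature_gmt(env$signature, p2)
      outs <- c(outs, p2)
    }
    list(outputs = outs,
         summary = list(pan_up = length(env$signature$pan_up),
                        pan_down = length(env$signature$pan_down),
                        relaxed = nrow(env$signature$relaxed)))
  })

  run_stage("tsp", function() {
    cohort <- need("cohort", "simulate")
    mat <- need("panel_mat", "panel_filter")
    sig <- need("signature", "signature")
    candidates <- c(sig$pan_up, sig$pan_down)
    if (length(candidates) < 2L) stop("fewer than two pan-regulated candidate genes")
    ev <- evaluate_tsp(mat, cohort$annotation$class, candidates,
                       scheme = config$tsp_scheme)
    env$tsp_eval <- ev
    p <- file.path(outdir, "tsp_report.tsv")
    utils::write.table(ev$folds, p, sep = "\t", quote = FALSE, row.names = FALSE)
    list(outputs = p,
         summary = list(sensitivity = ev$sensitivity,
                        specificity = ev$specificity, scheme = ev$scheme))
  })

  run_stage("stratify", function() {
    cohort <- need("cohort", "simulate")
    mat <- need("gene_mat", "collapse")
    env$strat <- stratify_expression(mat, cohort$annotation,
                                     gene = config$stratify_gene)
    p <- file.path(outdir, "stratification.tsv")
    utils::write.table(
      data.frame(sample_id = names(env$strat$labels), label = env$strat$labels,
                 row.names = NULL),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    ps <- file.path(outdir, "stratification_summary.tsv")
    utils::write.table(env$strat$per_subtype, ps, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = c(p, ps),
         summary = list(threshold = env$strat$threshold,
                        pooled_high_percent = env$strat$pooled$percent))
  })

  run_stage("tme", function() {
    cohort <- need("cohort", "simulate")
    mat <- need("gene_mat", "collapse")
    strat <- need("strat", "stratify")
    mal <- cohort$annotation$sample_id[cohort$annotation$class == "malignant"]
    filt <- correlation_filter(mat, anchor_gene = config$stratify_gene,
                               samples = mal, p_cutoff = config$corr_p_cutoff,
                               r_cutoff = config$corr_r_cutoff)
    env$tme <- tme_de(mat, strat, filt, criteria = config$tme_criteria,
                      seed = config$seed + 100L)
    p1 <- file.path(outdir, "tme_filter.tsv")
    utils::write.table(as.data.frame(filt), p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- file.path(outdir, "tme_de.tsv")
    utils::write.table(as.data.frame(env$tme$de), p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = c(p1, p2), summary = env$tme$summary)
  })

  run_stage("enrichment", function() {
    cohort <- need("cohort", "simulate")
    tme <- need("tme", "tme")
    sig_genes <- de_significant(tme$de)
    up_genes <- tme$de$gene[tme$de$gene %in% sig_genes & tme$de$fold_change > 0]
    universe <- tme$de$gene
    if (length(up_genes) == 0L) stop("no upregulated genes to test for enrichment")
    enr <- overrepresentation(up_genes, universe, cohort$gene_sets,
                              alpha = config$enrich_alpha)
    fc <- stats::setNames(tme$de$fold_change, tme$de$gene)
    rnk <- tryCatch(rank_enrichment(fc[sig_genes], cohort$gene_sets,
                                    alpha = config$enrich_alpha),
                    error = function(e) NULL)
    env$enrichment <- list(overrepresentation = enr, rank = rnk)
    p <- file.path(outdir, "enrichment.tsv")
    utils::write.table(as.data.frame(enr), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = p,
         summary = list(n_categories = nrow(enr),
                        n_significant = sum(enr$significant)))
  })

  run_stage("ihc", function() {
    tab <- simulate_ihc_table(config$ihc_counts, seed = config$seed + 200L)
    env$ihc <- summarize_staining(tab)
    p1 <- file.path(outdir, "ihc_calls.tsv")
    write_staining(tab, p1)
    p2 <- file.path(outdir, "ihc_summary.tsv")
    write_staining_summary(env$ihc, p2)
    list(outputs = c(p1, p2),
         summary = list(n_records = nrow(tab),
                        pooled = stats::setNames(as.list(env$ihc$pooled$percent),
                                                 env$ihc$pooled$marker)))
  })

  manifest$complete <- all(vapply(manifest$stages, function(s) {
    s$status %in% c("complete", "skipped")
  }, TRUE))
  manifest$parameters <- list(
    seed = config$seed, min_support = config$min_support,
    tsp_scheme = config$tsp_scheme, stratify_gene = config$stratify_gene,
    corr_p_cutoff = config$corr_p_cutoff, corr_r_cutoff = config$corr_r_cutoff,
    enrich_alpha = config$enrich_alpha,
    de = unclass(config$de), tme_criteria = unclass(config$tme_criteria)
  )
  write_manifest()
  invisible(manifest)
}
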