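# Tumour-microenvironment comparison: genes are pre-filtered by Pearson
# correlation of their log2 signal with an anchor gene (CAV1) across the
# malignant samples, then compared CAV1-High vs CAV1-Low under Korn
# false-discovery-proportion control.

#' Correlation pre-filter against an anchor gene
#'
#' Pearson correlation of each gene's log2 signal with the anchor's over
#' the chosen samples; the two-sided p-value uses
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom. A gene
#' passes iff p < `p_cutoff` AND |r| >= `r_cutoff`. Constant genes have
#' undefined r and fail (recorded).
#'
#' @param matrix gene-level expression matrix
#' @param anchor_gene anchor symbol (default "CAV1")
#' @param samples column names (or logical/integer index) of the samples to
#'   correlate over; defaults to all columns
#' @param p_cutoff,r_cutoff joint pass thresholds (defaults 0.01 and 0.22)
#' @return an object of class `correlation_filter`: data.frame (gene, r, p,
#'   pass) plus metadata attributes
#' @export
correlation_filter <- function(matrix, anchor_gene = "CAV1", samples = NULL,
                               p_cutoff = 0.01, r_cutoff = 0.22) {
  check_expression_matrix(matrix)
  if (!anchor_gene %in% rownames(matrix)) stop("anchor gene '", anchor_gene, "' not in the matrix")
  sub <- if (is.null(samples)) matrix else matrix[, samples, drop = FALSE]
  n <- ncol(sub)
  if (n < 3L) stop("need at least 3 samples for the correlation filter")
  L <- log2(sub)
  anchor <- L[anchor_gene, ]
  if (stats::sd(anchor) == 0) stop("anchor gene is constant over the chosen samples")
  sds <- apply(L, 1L, stats::sd)
  r <- rep(NA_real_, nrow(L))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(t(L[ok, , drop = FALSE]), anchor))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.finite(tt)] <- 0  # |r| = 1
  # boundary-inclusive with a float guard: |r| equal to the cut-off passes
  pass <- !is.na(r) & p < p_cutoff & (abs(r) - r_cutoff) > -1e-12
  out <- data.frame(gene = rownames(L), r = r, p = p, pass = pass,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("correlation_filter", "data.frame")
  attr(out, "anchor_gene") <- anchor_gene
  attr(out, "samples") <- colnames(sub)
  attr(out, "p_cutoff") <- p_cutoff
  attr(out, "r_cutoff") <- r_cutoff
  out
}

#' @export
print.correlation_filter <- function(x, ...) {
  cat(sprintf("Correlation filter vs %s over %d samples: %d/%d genes pass (p < %g & |r| >= %g)\n",
              attr(x, "anchor_gene"), length(attr(x, "samples")),
              sum(x$pass), nrow(x), attr(x, "p_cutoff"), attr(x, "r_cutoff")))
  invisible(x)
}

#' CAV1-High vs CAV1-Low differential expression of the microenvironment
#'
#' Runs [permutation_test()] in Korn mode on the correlation-filtered genes
#' over the malignant samples, contrasting High vs Low, and summarizes the
#' result (counts of DE genes and the fraction overexpressed in High).
#' Fold-changes are High over Low.
#'
#' @param matrix gene-level expression matrix (malignant columns at least)
#' @param stratification a `stratification_result` from
#'   [stratify_expression()] (or a named High/Low label vector)
#' @param filtered a `correlation_filter` result; only passing genes are
#'   tested
#' @param criteria a [de_criteria()] object; default Korn mode with a 1%
#'   false-discovery proportion at 99% confidence
#' @param seed RNG seed passed to the permutation test
#' @return an object of class `tme_result`: the `de_result` plus a summary
#'   list (n_tested, n_de, n_up, n_down, fraction_up)
#' @export
tme_de <- function(matrix, stratification, filtered,
                   criteria = de_criteria(mode = "korn"), seed = 1L) {
  labels <- if (inherits(stratification, "stratification_result")) {
    stratification$labels
  } else {
    stratification
  }
  if (is.null(names(labels))) stop("High/Low labels must be named by sample")
  if (!all(labels %in% c("High", "Low"))) stop("labels must be 'High'/'Low'")
  keep_genes <- filtered$gene[filtered$pass]
  if (length(keep_genes) == 0L) stop("the correlation filter passed no genes")
  samples <- intersect(colnames(matrix), names(labels))
  if (length(samples) < 4L) stop("need labelled samples present in the matrix")
  sub <- matrix[intersect(rownames(matrix), keep_genes), samples, drop = FALSE]
  de <- permutation_test(sub, labels[samples], criteria = criteria,
                         seed = seed, ref = "Low")
  sig <- de_significant(de)
  up <- sum(de$fold_change[de$gene %in% sig] > 0)
  out <- list(
    de = de,
    summary = list(n_tested = nrow(de), n_de = length(sig), n_up = up,
                   n_down = length(sig) - up,
                   fraction_up = if (length(sig) > 0L) up / length(sig) else NA_real_)
  )
  class(out) <- "tme_result"
  out
}

#' @export
print.tme_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CAV1-High vs CAV1-Low comparison: %d genes tested, %d differentially expressed\n",
              s$n_tested, s$n_de))
  if (s$n_de > 0L) {
    cat(sprintf("  %d (%.0f%%) overexpressed in the High group\n",
                s$n_up, 100 * s$fraction_up))
  }
  invisible(x)
}
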