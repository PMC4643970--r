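# CAV1 expression-threshold stratification: the threshold is two sample
# standard deviations above the healthy mean of the designated gene's
# linear-scale signal; malignant samples strictly above it are High, the
# rest Low.

#' Healthy-derived expression threshold
#'
#' @param healthy_values linear-scale signal of the gene in healthy samples
#' @return list with `mean`, `sd` (sample, n-1 denominator) and
#'   `threshold` = mean + 2 * sd
#' @export
compute_threshold <- function(healthy_values) {
  healthy_values <- as.numeric(healthy_values)
  if (length(healthy_values) < 2L) stop("need at least 2 healthy samples")
  if (any(!is.finite(healthy_values))) stop("healthy values must be finite")
  mu <- mean(healthy_values)
  sigma <- stats::sd(healthy_values)
  list(mean = mu, sd = sigma, threshold = mu + 2 * sigma)
}

#' Classify malignant samples against an expression threshold
#'
#' Strictly above the threshold is High; at or below is Low.
#'
#' @param malignant_values named linear-scale signal vector
#' @param threshold the threshold (from [compute_threshold()])
#' @param subtypes optional per-sample subtype labels for per-subtype
#'   fractions
#' @return list with per-sample `labels` ("High"/"Low"), `per_subtype`
#'   data.frame (subtype, n_high, n, fraction, percent) when subtypes are
#'   given, and `pooled` (n_high, n, fraction, percent)
#' @export
classify_samples <- function(malignant_values, threshold, subtypes = NULL) {
  if (length(threshold) != 1L || !is.finite(threshold)) stop("'threshold' must be a single finite value")
  v <- as.numeric(malignant_values)
  labels <- ifelse(v > threshold, "High", "Low")
  names(labels) <- names(malignant_values)
  out <- list(labels = labels)
  if (!is.null(subtypes)) {
    if (length(subtypes) != length(v)) stop("one subtype per sample required")
    tab <- summarize_high_counts(
      n_high = tapply(labels == "High", subtypes, sum),
      n_total = tapply(rep(1L, length(v)), subtypes, sum)
    )
    out$per_subtype <- tab$per_subtype
    out$pooled <- tab$pooled
  } else {
    out$pooled <- summarize_high_counts(sum(labels == "High"), length(v))$pooled
  }
  out
}

#' Pool per-subtype High counts into fractions and percentages
#'
#' The stratification summarizer: given High counts and totals per subtype
#' it recomputes per-subtype and pooled High fractions, with percentages
#' rounded half-up to whole percent as printed in clinical tables.
#'
#' @param n_high,n_total equally-long (optionally named) count vectors
#' @return list with `per_subtype` data.frame (subtype, n_high, n,
#'   fraction, percent) and `pooled` list (n_high, n, fraction, percent)
#' @export
summarize_high_counts <- function(n_high, n_total) {
  subtype <- names(n_high) %||% as.character(seq_along(n_high))
  n_high <- as.integer(n_high)
  n_total <- as.integer(n_total)
  if (length(n_high) != length(n_total)) stop("count vectors must align")
  if (any(n_high < 0L) || any(n_total <= 0L) || any(n_high > n_total)) {
    stop("counts must satisfy 0 <= n_high <= n_total, n_total > 0")
  }
  per_subtype <- data.frame(
    subtype = subtype, n_high = n_high, n = n_total,
    fraction = n_high / n_total,
    percent = pct_round(100 * n_high / n_total),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pooled <- list(n_high = sum(n_high), n = sum(n_total),
                 fraction = sum(n_high) / sum(n_total),
                 percent = pct_round(100 * sum(n_high) / sum(n_total)))
  list(per_subtype = per_subtype, pooled = pooled)
}

#' Healthy-sample outliers by the boxplot rule
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7,
#' recorded in the output); the upper fence is Q3 + 1.5 * IQR and outliers
#' are values strictly above it. Also reports the fraction of healthy
#' values at or below the expression threshold.
#'
#' @param healthy_values linear-scale signal vector (>= 4 values)
#' @param threshold optional expression threshold for the below-threshold
#'   fraction
#' @return list with `outliers`, `upper_fence`, `quartiles`,
#'   `below_threshold_fraction` (NA without a threshold) and
#'   `quartile_convention`
#' @export
healthy_outliers <- function(healthy_values, threshold = NULL) {
  v <- as.numeric(healthy_values)
  if (length(v) < 4L) stop("need at least 4 values for quartiles")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  list(
    outliers = v[v > fence],
    upper_fence = fence,
    quartiles = c(q1 = q[1L], q3 = q[2L]),
    below_threshold_fraction = if (is.null(threshold)) NA_real_ else mean(v <= threshold),
    quartile_convention = "linear interpolation (R quantile type 7)"
  )
}

#' Stratify a cohort by a gene's expression threshold
#'
#' Computes the healthy-derived threshold for `gene` (mean + 2 sample SD of
#' the linear signal in healthy samples) and classifies every malignant
#' sample as High or Low, with per-subtype and pooled fractions and the
#' healthy boxplot outliers.
#'
#' @param matrix gene-level expression matrix (samples in columns)
#' @param annotation data.frame with sample_id, class, subtype matching the
#'   matrix columns
#' @param gene gene symbol to stratify on (default "CAV1")
#' @return an object of class `stratification_result`
#' @export
stratify_expression <- function(matrix, annotation, gene = "CAV1") {
  check_expression_matrix(matrix)
  if (!gene %in% rownames(matrix)) stop("gene '", gene, "' not in the matrix")
  if (!all(colnames(matrix) %in% annotation$sample_id)) {
    stop("annotation does not cover all samples")
  }
  ann <- annotation[match(colnames(matrix), annotation$sample_id), ]
  v <- matrix[gene, ]
  healthy <- v[ann$class == "healthy"]
  malignant <- v[ann$class == "malignant"]
  if (length(malignant) == 0L) stop("no malignant samples to classify")
  thr <- compute_threshold(healthy)
  cls <- classify_samples(malignant, thr$threshold,
                          subtypes = ann$subtype[ann$class == "malignant"])
  out <- c(list(gene = gene, healthy_mean = thr$mean, healthy_sd = thr$sd,
                threshold = thr$threshold,
                healthy = healthy_outliers(healthy, thr$threshold)),
           cls)
  class(out) <- "stratification_result"
  out
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("%s stratification: threshold %.2f (healthy mean %.2f + 2 x SD %.2f)\n",
              x$gene, x$threshold, x$healthy_mean, x$healthy_sd))
  cat(sprintf("  pooled High: %d/%d (%d%%); healthy at/below threshold: %.0f%%\n",
              x$pooled$n_high, x$pooled$n, x$pooled$percent,
              100 * x$healthy$below_threshold_fraction))
  if (!is.null(x$per_subtype)) {
    for (i in seq_len(nrow(x$per_subtype))) {
      r <- x$per_subtype[i, ]
      cat(sprintf("    %-9s %d/%d (%d%%)\n", r$subtype, r$n_high, r$n, r$percent))
    }
  }
  invisible(x)
}
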