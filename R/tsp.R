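# Top-scoring-pairs classifier. For a gene pair (i, j) the score is
# Delta_ij = |P(X_i < X_j | class 1) - P(X_i < X_j | class 2)|: the pair
# whose within-sample ordering best separates the classes. Prediction uses
# only which of the two genes is larger in a sample, making the rule
# invariant to any monotone within-sample transformation. Delta ties are
# broken by the secondary rank score Gamma (between-class gap in the mean
# within-sample rank difference), then lexicographically.

#' Fit a top-scoring-pair classifier
#'
#' Scores every unordered pair of candidate genes and returns the pair with
#' maximal Delta. Within-sample ties (equal signals) count as "not (i < j)".
#'
#' @param matrix gene-level expression matrix
#' @param labels two-class assignment, one label per column
#' @param candidates character vector of candidate gene symbols
#' @return an object of class `tsp_model`: the selected pair, per-class
#'   frequencies of the event \{signal_i < signal_j\}, the pair score Delta,
#'   the secondary score Gamma, and the decision rule
#' @export
fit_tsp <- function(matrix, labels, candidates) {
  check_expression_matrix(matrix)
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix)) stop("one label per sample required")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required")
  genes <- sort(intersect(candidates, rownames(matrix)))
  if (length(genes) < 2L) stop("need at least two candidate genes present in the matrix")
  sub <- matrix[genes, , drop = FALSE]
  ranks <- apply(sub, 2L, rank)  # within-sample ranks across candidates
  c1 <- labels == lev[1L]
  c2 <- !c1

  pairs <- utils::combn(genes, 2L)
  n_pairs <- ncol(pairs)
  stats_tab <- data.frame(
    gene_i = pairs[1L, ], gene_j = pairs[2L, ],
    p1 = NA_real_, p2 = NA_real_, delta = NA_real_, gamma = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n_pairs)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    lt <- sub[i, ] < sub[j, ]
    p1 <- mean(lt[c1])
    p2 <- mean(lt[c2])
    rd <- ranks[i, ] - ranks[j, ]
    stats_tab$p1[k] <- p1
    stats_tab$p2[k] <- p2
    stats_tab$delta[k] <- abs(p1 - p2)
    stats_tab$gamma[k] <- abs(mean(rd[c1]) - mean(rd[c2]))
  }
  best <- order(-stats_tab$delta, -stats_tab$gamma,
                stats_tab$gene_i, stats_tab$gene_j, method = "radix")[1L]

  model <- list(
    gene_i = stats_tab$gene_i[best],
    gene_j = stats_tab$gene_j[best],
    classes = lev,
    p_lt = stats::setNames(c(stats_tab$p1[best], stats_tab$p2[best]), lev),
    delta = stats_tab$delta[best],
    gamma = stats_tab$gamma[best],
    pair_scores = stats_tab
  )
  class(model) <- "tsp_model"
  model
}

#' @export
print.tsp_model <- function(x, ...) {
  cat(sprintf("Top-scoring pair: (%s, %s), Delta = %.3f, Gamma = %.2f\n",
              x$gene_i, x$gene_j, x$delta, x$gamma))
  cat(sprintf("  P(%s < %s): %s = %.3f, %s = %.3f\n", x$gene_i, x$gene_j,
              x$classes[1L], x$p_lt[1L], x$classes[2L], x$p_lt[2L]))
  cat(sprintf("  rule: %s < %s -> %s, otherwise -> %s\n", x$gene_i, x$gene_j,
              x$classes[which.max(x$p_lt)], x$classes[which.min(x$p_lt)]))
  invisible(x)
}

#' Predict classes from a top-scoring-pair model
#'
#' If signal_i < signal_j the sample is assigned the class with the larger
#' estimated frequency of that ordering; otherwise (including exact ties)
#' the other class.
#'
#' @param object a `tsp_model`
#' @param newdata gene-level matrix (genes x samples) or a named per-gene
#'   signal vector for a single sample
#' @param ... unused
#' @return character vector of predicted class labels
#' @export
predict.tsp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- cbind(sample = newdata)
  for (g in c(object$gene_i, object$gene_j)) {
    if (!g %in% rownames(newdata)) stop("sample lacks model gene '", g, "'")
  }
  lt <- newdata[object$gene_i, ] < newdata[object$gene_j, ]
  # when frequencies tie, fall back to the first class level (deterministic)
  class_lt <- object$classes[which.max(object$p_lt)]
  class_ge <- object$classes[which.max(1 - object$p_lt)]
  unname(ifelse(lt, class_lt, class_ge))
}

#' Evaluate a top-scoring-pair classifier
#'
#' `"loocv"` refits the pair within each leave-one-out fold (the honest
#' default); `"resubstitution"` scores the training data with the full-data
#' pair. Sensitivity and specificity are computed with the `positive` class
#' (malignant by convention) as positive.
#'
#' @param matrix gene-level expression matrix
#' @param labels two-class assignment
#' @param candidates candidate gene symbols
#' @param scheme `"loocv"` or `"resubstitution"`
#' @param positive positive class label; defaults to `"malignant"` when
#'   present, else the second sorted label
#' @return an object of class `tsp_eval`: confusion counts, sensitivity,
#'   specificity, the scheme, and the per-fold selected pairs
#' @export
evaluate_tsp <- function(matrix, labels, candidates,
                         scheme = c("loocv", "resubstitution"),
                         positive = NULL) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required")
  if (is.null(positive)) positive <- if ("malignant" %in% lev) "malignant" else lev[2L]
  if (!positive %in% lev) stop("'positive' must be one of the labels")

  if (scheme == "resubstitution") {
    model <- fit_tsp(matrix, labels, candidates)
    pred <- predict(model, matrix)
    folds <- data.frame(fold = NA_integer_, gene_i = model$gene_i,
                        gene_j = model$gene_j, stringsAsFactors = FALSE)
  } else {
    if (min(table(labels)) < 2L) {
      stop("leave-one-out would empty a class; each class needs >= 2 samples")
    }
    n <- ncol(matrix)
    pred <- character(n)
    folds <- data.frame(fold = seq_len(n), gene_i = NA_character_,
                        gene_j = NA_character_, stringsAsFactors = FALSE)
    for (s in seq_len(n)) {
      model <- fit_tsp(matrix[, -s, drop = FALSE], labels[-s], candidates)
      pred[s] <- predict(model, matrix[, s])
      folds$gene_i[s] <- model$gene_i
      folds$gene_j[s] <- model$gene_j
    }
  }

  truth_pos <- labels == positive
  pred_pos <- pred == positive
  tp <- sum(truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  out <- list(
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    scheme = scheme, positive = positive, folds = folds
  )
  class(out) <- "tsp_eval"
  out
}

#' @export
print.tsp_eval <- function(x, ...) {
  cat(sprintf("TSP evaluation (%s, positive = %s)\n", x$scheme, x$positive))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%% (TP %d, FN %d, TN %d, FP %d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}
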