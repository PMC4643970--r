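# Two-class differential expression. Test statistics are two-sample t
# statistics on log2 signal (Welch by default; the cohorts are highly
# unbalanced); fold-changes are ratios of linear-scale geometric means with
# the signed convention (down-regulation as the negative reciprocal). The
# permutation test is multivariate: one label permutation is applied to all
# genes jointly, preserving gene-gene correlation. False-discovery control
# is either Benjamini-Hochberg on the permutation p-values or the Korn
# step-down procedure bounding the proportion of false discoveries at a
# stated confidence.

#' Differential-expression criteria
#'
#' @param alpha_p permutation p-value threshold (default 0.001)
#' @param alpha_fdr BH q-value threshold (default 0.001)
#' @param korn_gamma allowed proportion of false discoveries (default 0.01)
#' @param korn_confidence confidence with which the proportion is bounded
#'   (default 0.99)
#' @param n_permutations number of label permutations (default 1000)
#' @param mode `"p_and_fdr"` (significant iff p < alpha_p and q < alpha_fdr)
#'   or `"korn"` (significant iff retained by the step-down procedure)
#' @return an object of class `de_criteria`
#' @export
de_criteria <- function(alpha_p = 0.001, alpha_fdr = 0.001,
                        korn_gamma = 0.01, korn_confidence = 0.99,
                        n_permutations = 1000L,
                        mode = c("p_and_fdr", "korn")) {
  check_open_unit(alpha_p, "alpha_p")
  check_open_unit(alpha_fdr, "alpha_fdr")
  check_open_unit(korn_gamma, "korn_gamma")
  check_open_unit(korn_confidence, "korn_confidence")
  check_count(n_permutations, "n_permutations")
  out <- list(alpha_p = alpha_p, alpha_fdr = alpha_fdr,
              korn_gamma = korn_gamma, korn_confidence = korn_confidence,
              n_permutations = as.integer(n_permutations),
              mode = match.arg(mode))
  class(out) <- "de_criteria"
  out
}

#' Signed fold-change between two groups
#'
#' Ratio of linear-scale geometric means, malignant (second argument) over
#' healthy (first). Ratios below one are reported as the negative
#' reciprocal, so |FC| >= 1 always and down-regulation carries a minus
#' sign; equal means give 1.
#'
#' @param healthy_values,malignant_values strictly positive signal vectors
#' @return signed fold-change
#' @export
fold_change <- function(healthy_values, malignant_values) {
  if (length(healthy_values) == 0L || length(malignant_values) == 0L) {
    stop("both groups must be non-empty")
  }
  h <- geomean(healthy_values)
  m <- geomean(malignant_values)
  if (m >= h) m / h else -(h / m)
}

# elementwise t statistic from group sums/sums-of-squares (vectors or
# matrices); direction is group2 minus group1
t_from_sums <- function(S2, Q2, S, Q, n1, n2, var_equal) {
  S1 <- S - S2
  Q1 <- Q - Q2
  m1 <- S1 / n1
  m2 <- S2 / n2
  v1 <- pmax((Q1 - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax((Q2 - n2 * m2^2) / (n2 - 1), 0)
  se2 <- if (var_equal) {
    (((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) * (1 / n1 + 1 / n2)
  } else {
    v1 / n1 + v2 / n2
  }
  d <- m2 - m1
  t <- d / sqrt(se2)
  zero <- se2 <= 0
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  t
}

#' Multivariate permutation test for two-class differential expression
#'
#' Per-gene t statistics on log2-transformed signal; permutation p-values
#' from label permutations applied jointly to all genes. With B random
#' permutations, p = (1 + #\{|t*| >= |t|\}) / (B + 1). When the number of
#' distinct label assignments is at most B the test enumerates them
#' exhaustively (observed assignment included) and p = #\{|t*| >= |t|\} /
#' total. Benjamini-Hochberg q-values are computed over all tested genes; in
#' `"korn"` mode the step-down procedure of [korn_stepdown()] is applied to
#' the shared permutation replicates.
#'
#' @param matrix gene-level expression matrix (positive linear scale)
#' @param labels two-class assignment, one label per column
#' @param criteria a [de_criteria()] object
#' @param seed RNG seed for the permutations
#' @param ref reference class (fold-change denominator); defaults to
#'   `"healthy"` when present, else the first sorted label
#' @param var_equal use the classical pooled-variance two-sample t (the
#'   default, matching the class-comparison convention of the microarray
#'   tools this mirrors; the permutation p is exact either way), or the
#'   Welch statistic with `FALSE`
#' @param keep_null retain the permutation |t*| matrix in the result
#'   (attribute `"null_abs_t"`); implied by `mode = "korn"`
#' @return a `de_result` data.frame with columns gene, fold_change, t,
#'   p_perm, q_bh, korn_pass, flagged
#' @export
permutation_test <- function(matrix, labels, criteria = de_criteria(),
                             seed = 1L, ref = NULL, var_equal = TRUE,
                             keep_null = FALSE) {
  check_expression_matrix(matrix)
  if (!inherits(criteria, "de_criteria")) stop("'criteria' must come from de_criteria()")
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix)) stop("one label per sample required")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required")
  if (is.null(ref)) ref <- if ("healthy" %in% lev) "healthy" else lev[1L]
  if (!ref %in% lev) stop("'ref' must be one of the labels")
  grp2 <- labels != ref
  n1 <- sum(!grp2)
  n2 <- sum(grp2)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  n <- n1 + n2

  L <- log2(matrix)
  L2 <- L * L
  S <- rowSums(L)
  Q <- rowSums(L2)
  S2_obs <- rowSums(L[, grp2, drop = FALSE])
  Q2_obs <- rowSums(L2[, grp2, drop = FALSE])
  t_obs <- t_from_sums(S2_obs, Q2_obs, S, Q, n1, n2, var_equal)
  abs_t <- abs(t_obs)
  # genes constant across all samples are uninformative: t = 0, p = 1
  flagged <- (Q - S^2 / n) <= 1e-12 * pmax(1, Q)
  t_obs[flagged] <- 0
  abs_t[flagged] <- 0

  # comparison threshold with a relative tolerance so the observed
  # assignment always counts against itself in the enumeration
  thr <- abs_t - 1e-8 * (1 + abs_t)
  thr[!is.finite(abs_t)] <- Inf

  total <- suppressWarnings(choose(n, n2))
  exhaustive <- is.finite(total) && total <= criteria$n_permutations
  B <- if (exhaustive) as.integer(total) else criteria$n_permutations
  need_null <- keep_null || criteria$mode == "korn"
  null_abs_t <- if (need_null) matrix(NA_real_, nrow(L), B) else NULL

  set.seed(as.integer(seed))
  count <- numeric(nrow(L))
  if (exhaustive) {
    picks <- utils::combn(n, n2)
  }
  chunk <- max(1L, min(B, as.integer(ceiling(2e6 / nrow(L)))))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    P <- matrix(0, n, b)
    if (exhaustive) {
      cols <- rep(seq_len(b), each = n2)
      P[cbind(as.vector(picks[, (done + 1L):(done + b), drop = FALSE]), cols)] <- 1
    } else {
      idx <- vapply(seq_len(b), function(i) sample.int(n, n2), integer(n2))
      cols <- rep(seq_len(b), each = n2)
      P[cbind(as.vector(idx), cols)] <- 1
    }
    Tb <- t_from_sums(L %*% P, L2 %*% P, S, Q, n1, n2, var_equal)
    aTb <- abs(Tb)
    count <- count + rowSums(aTb >= thr)
    if (need_null) null_abs_t[, (done + 1L):(done + b)] <- aTb
    done <- done + b
  }

  p <- if (exhaustive) count / B else (1 + count) / (B + 1)
  p[flagged] <- 1
  q <- stats::p.adjust(p, method = "BH")

  gm1 <- 2^rowMeans(L[, !grp2, drop = FALSE])
  gm2 <- 2^rowMeans(L[, grp2, drop = FALSE])
  fc <- ifelse(gm2 >= gm1, gm2 / gm1, -gm1 / gm2)

  korn_pass <- rep(NA, nrow(L))
  if (criteria$mode == "korn") {
    rownames(null_abs_t) <- rownames(L)
    korn_pass <- korn_stepdown(stats::setNames(t_obs, rownames(L)), null_abs_t,
                               gamma = criteria$korn_gamma,
                               confidence = criteria$korn_confidence)
  }

  out <- data.frame(
    gene = rownames(L), fold_change = fc, t = t_obs, p_perm = p, q_bh = q,
    korn_pass = korn_pass, flagged = flagged,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("de_result", "data.frame")
  attr(out, "criteria") <- criteria
  attr(out, "seed") <- as.integer(seed)
  attr(out, "ref") <- ref
  attr(out, "n_permutations_used") <- B
  attr(out, "exhaustive") <- exhaustive
  attr(out, "group_sizes") <- c(stats::setNames(n1, ref),
                                stats::setNames(n2, setdiff(lev, ref)))
  if (keep_null) attr(out, "null_abs_t") <- null_abs_t
  out
}

#' Genes called significant by a differential-expression result
#'
#' Applies the criteria the result was run with (or overriding criteria):
#' `p_and_fdr` mode requires p_perm < alpha_p and q_bh < alpha_fdr; `korn`
#' mode uses the step-down pass flag.
#'
#' @param de a `de_result`
#' @param criteria optional [de_criteria()] override
#' @return character vector of gene symbols
#' @export
de_significant <- function(de, criteria = NULL) {
  criteria <- criteria %||% attr(de, "criteria")
  if (criteria$mode == "korn") {
    if (all(is.na(de$korn_pass))) stop("result carries no step-down flags; rerun in korn mode")
    de$gene[which(de$korn_pass)]
  } else {
    de$gene[de$p_perm < criteria$alpha_p & de$q_bh < criteria$alpha_fdr]
  }
}

#' @export
print.de_result <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf("Two-class permutation DE: %d genes, %d permutations%s\n",
              nrow(x), attr(x, "n_permutations_used"),
              if (isTRUE(attr(x, "exhaustive"))) " (exhaustive)" else ""))
  gs <- attr(x, "group_sizes")
  cat(sprintf("  classes: %s (n=%d, reference) vs %s (n=%d)\n",
              names(gs)[1L], gs[1L], names(gs)[2L], gs[2L]))
  cat(sprintf("  mode %s: %d significant gene(s)\n", crit$mode,
              length(de_significant(x))))
  invisible(x)
}

#' Korn step-down control of the proportion of false discoveries
#'
#' Rejects genes in decreasing order of |t|, allowing u(r) = floor(gamma *
#' r) false discoveries among the first r rejections. The critical value at
#' rank r is the `confidence` quantile, over permutation replicates, of the
#' (u+1)-th largest |t*| among the genes not already exempted (the r-u-1
#' most significant genes are removed from the reference set, as they may be
#' true positives). Ranks at which floor(gamma * r) increments are rejected
#' automatically; the first failed comparison stops the procedure. The
#' observed statistics are included in the permutation reference set.
#'
#' @param t_obs named vector of observed t statistics
#' @param null_abs_t genes x permutations matrix of |t*| under label
#'   permutation (shared permutations across genes)
#' @param gamma allowed proportion of false discoveries, in (0, 1)
#' @param confidence probability with which the proportion is bounded
#' @param include_observed add the observed |t| as one replicate
#' @return named logical vector: TRUE for rejected (significant) genes
#' @export
korn_stepdown <- function(t_obs, null_abs_t, gamma, confidence,
                          include_observed = TRUE) {
  check_open_unit(gamma, "gamma")
  check_open_unit(confidence, "confidence")
  m <- length(t_obs)
  if (nrow(null_abs_t) != m) stop("permutation matrix must have one row per gene")
  abs_obs <- abs(t_obs)
  A <- abs(null_abs_t)
  if (include_observed) A <- cbind(A, abs_obs)
  ord <- order(-abs_obs, names(t_obs) %||% seq_len(m), method = "radix")
  A <- A[ord, , drop = FALSE]
  obs_sorted <- abs_obs[ord]
  BB <- ncol(A)

  # suffix maxima over the rank dimension: suffmax[r, ] = max over ranks r..m
  suffmax <- A
  if (m > 1L) {
    for (r in (m - 1L):1L) suffmax[r, ] <- pmax(suffmax[r, ], suffmax[r + 1L, ])
  }

  reject_sorted <- rep(FALSE, m)
  for (r in seq_len(m)) {
    u <- floor(gamma * r)
    if (r > 1L && u > floor(gamma * (r - 1L))) {
      reject_sorted[r] <- TRUE  # the incremented allowance covers this rank
      next
    }
    d <- if (u == 0) {
      suffmax[r, ]
    } else {
      lo <- r - u
      apply(A[lo:m, , drop = FALSE], 2L,
            function(x) sort(x, decreasing = TRUE)[u + 1L])
    }
    crit <- sort(d)[ceiling(confidence * BB)]
    if (obs_sorted[r] > crit) reject_sorted[r] <- TRUE else break
  }
  out <- logical(m)
  out[ord] <- reject_sorted
  names(out) <- names(t_obs)
  out
}
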