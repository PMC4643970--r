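# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and separate from the package's own code paths.

# Benjamini-Hochberg by the textbook formula: q_(i) = min_{j >= i} p_(j)*m/j
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- cummin(rev(p[o] * m / seq_len(m)))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  pmin(q, 1)
}

# exact binomial tails by direct density summation
naive_binom <- function(k, n, p0, alternative) {
  p_hi <- sum(stats::dbinom(k:n, n, p0))
  p_lo <- sum(stats::dbinom(0:k, n, p0))
  switch(alternative,
         greater = p_hi,
         less = p_lo,
         two.sided = min(1, 2 * min(p_hi, p_lo)))
}

# exhaustive top-scoring-pair scorer: double loop over all unordered pairs,
# ties in delta broken by gamma then lexicographically
brute_tsp <- function(mat, labels) {
  lev <- sort(unique(labels))
  genes <- sort(rownames(mat))
  ranks <- apply(mat[genes, , drop = FALSE], 2, rank)
  best <- NULL
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (b <= a) next
      i <- genes[a]; j <- genes[b]
      lt <- mat[i, ] < mat[j, ]
      p1 <- mean(lt[labels == lev[1]])
      p2 <- mean(lt[labels == lev[2]])
      delta <- abs(p1 - p2)
      rd <- ranks[i, ] - ranks[j, ]
      gam <- abs(mean(rd[labels == lev[1]]) - mean(rd[labels == lev[2]]))
      cand <- list(i = i, j = j, delta = delta, gamma = gam)
      if (is.null(best) || delta > best$delta ||
          (delta == best$delta && gam > best$gamma)) {
        best <- cand
      }
    }
  }
  best
}

# expression matrix from a numeric matrix, adding names
as_expr <- function(m, genes = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fabricated DE result for signature-rule tests
fake_de <- function(genes, p, fc, q = NULL,
                    criteria = de_criteria(alpha_p = 0.05, alpha_fdr = 0.05)) {
  out <- data.frame(gene = genes, fold_change = fc, t = sign(fc),
                    p_perm = p, q_bh = q %||% p, korn_pass = NA,
                    flagged = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "criteria") <- criteria
  out
}

# small planted two-class matrix: first `n_sig` genes shifted in class 2
planted_matrix <- function(n_genes, n1, n2, n_sig, shift = 1, sd = 0.5,
                           seed = 1) {
  set.seed(seed)
  L <- matrix(stats::rnorm(n_genes * (n1 + n2), 8, sd), n_genes)
  if (n_sig > 0) {
    L[seq_len(n_sig), n1 + seq_len(n2)] <- L[seq_len(n_sig), n1 + seq_len(n2)] + shift
  }
  dimnames(L) <- list(
    c(sprintf("SIG%03d", seq_len(n_sig)), sprintf("NUL%03d", seq_len(n_genes - n_sig)))[seq_len(n_genes)],
    sprintf("s%03d", seq_len(n1 + n2)))
  2^L
}
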