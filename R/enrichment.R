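# Gene-set statistics: binomial over/under-representation of a gene list
# against a universe, and Mann-Whitney rank enrichment of signed
# fold-changes, both with Bonferroni correction across the tested
# categories. These are self-contained methodological equivalents of the
# web-tool statistics typically used for such lists; categories are
# supplied as GMT, no ontology is bundled.

#' Category over/under-representation of a gene list
#'
#' For each category, tests the observed number of list members against the
#' expectation n * (category frequency in the universe). The binomial test
#' (default) is two-sided by doubling the smaller tail (capped at 1);
#' one-sided alternatives are available. A hypergeometric variant (sampling
#' without replacement) is offered as an option. Direction is "+" when
#' observed > expected, "-" when below, "0" at equality.
#'
#' @param gene_list character vector, a subset of `universe`
#' @param universe character vector of all considered genes
#' @param categories named list of character vectors (e.g. from
#'   [read_gmt()]); each is intersected with the universe, empty
#'   intersections are skipped with a warning
#' @param method `"binomial"` (default) or `"hypergeometric"`
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @param alpha Bonferroni-adjusted significance threshold reported in the
#'   result (default 0.05)
#' @return an `enrichment_result` data.frame: category, n_list, expected,
#'   direction, p, p_adjusted, significant
#' @export
overrepresentation <- function(gene_list, universe, categories,
                               method = c("binomial", "hypergeometric"),
                               alternative = c("two.sided", "greater", "less"),
                               alpha = 0.05) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  gene_list <- unique(as.character(gene_list))
  if (length(universe) == 0L) stop("empty universe")
  if (!all(gene_list %in% universe)) stop("gene list must be a subset of the universe")
  if (is.null(names(categories))) stop("categories must be named")

  n <- length(gene_list)
  rows <- lapply(names(categories), function(nm) {
    cat_u <- intersect(unique(categories[[nm]]), universe)
    if (length(cat_u) == 0L) {
      warning("category '", nm, "' does not intersect the universe; skipped")
      return(NULL)
    }
    k <- sum(gene_list %in% cat_u)
    p0 <- length(cat_u) / length(universe)
    expected <- n * p0
    if (method == "binomial") {
      p_hi <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
      p_lo <- stats::pbinom(k, n, p0)
    } else {
      m <- length(cat_u)
      p_hi <- stats::phyper(k - 1L, m, length(universe) - m, n, lower.tail = FALSE)
      p_lo <- stats::phyper(k, m, length(universe) - m, n)
    }
    p <- switch(alternative,
                greater = p_hi,
                less = p_lo,
                two.sided = min(1, 2 * min(p_hi, p_lo)))
    data.frame(category = nm, n_list = k, expected = expected,
               direction = if (k > expected) "+" else if (k < expected) "-" else "0",
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no category overlaps the universe")
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "test") <- paste0(method, "_overrep")
  attr(out, "alternative") <- alternative
  attr(out, "n_categories_tested") <- nrow(out)
  out
}

# Mann-Whitney U of x (category) vs y (complement): U counts pairs where
# x beats y, ties count one half. Exact p by enumeration of the permutation
# distribution of U (two-sided: |U - mu| at least as extreme); normal
# approximation with tie correction otherwise.
mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x)
  n2 <- length(y)
  u <- mw_u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    vals <- c(x, y)
    picks <- utils::combn(n1 + n2, n1)
    r_all <- rank(vals)
    us <- apply(picks, 2L, function(ix) sum(r_all[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    list(u = u, p = p, exact = TRUE)
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1, exact = FALSE))
    z <- (u - mu) / sqrt(sigma2)
    list(u = u, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
  }
}

#' Rank enrichment of fold-changes within categories
#'
#' Two-sided Mann-Whitney comparison of category members' signed
#' fold-changes against all other genes, exact by enumeration when both
#' groups have at most 8 members and by normal approximation with tie
#' correction otherwise; Bonferroni across the tested categories.
#' Direction is "+" when the category median exceeds the complement
#' median.
#'
#' @param fold_changes named numeric vector of signed per-gene fold-changes
#' @param categories named list of character vectors
#' @param alpha Bonferroni-adjusted significance threshold (default 0.05)
#' @return an `enrichment_result` data.frame: category, n_list, U,
#'   direction, p, p_adjusted, significant
#' @export
rank_enrichment <- function(fold_changes, categories, alpha = 0.05) {
  if (is.null(names(fold_changes))) stop("fold-changes must be named by gene")
  if (is.null(names(categories))) stop("categories must be named")
  genes <- names(fold_changes)
  rows <- lapply(names(categories), function(nm) {
    members <- intersect(unique(categories[[nm]]), genes)
    if (length(members) < 2L || length(genes) - length(members) < 2L) {
      warning("category '", nm, "' has fewer than 2 usable members in or out; skipped")
      return(NULL)
    }
    x <- fold_changes[members]
    y <- fold_changes[setdiff(genes, members)]
    res <- mw_test(x, y)
    data.frame(category = nm, n_list = length(members), U = res$u,
               direction = if (stats::median(x) > stats::median(y)) "+" else "-",
               p = res$p, exact = res$exact, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no usable category")
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "test") <- "mannwhitney_enrich"
  attr(out, "n_categories_tested") <- nrow(out)
  out
}
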