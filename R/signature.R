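# Cross-subtype signature construction: intersect per-subtype DE results
# into pan-subtype up/down lists and a relaxed >= k-of-n list, requiring a
# consistent direction throughout.

#' Intersect per-subtype DE results into shared signatures
#'
#' A gene enters `pan_up` iff it is significant (per `criteria`) with
#' fold-change > 1 in every subtype, `pan_down` analogously with
#' fold-change < -1. A gene enters the relaxed list iff it is significant
#' with one consistent direction in at least `min_support` subtypes. Genes
#' significant up in some subtypes and down in others are excluded from
#' both lists and reported as direction-conflicted.
#'
#' @param per_subtype named list of `de_result` objects over a common gene
#'   universe
#' @param criteria optional [de_criteria()] override applied to every result
#' @param min_support minimum number of supporting subtypes for the relaxed
#'   list (default 3)
#' @return an object of class `signature_result`: lists `pan_up`,
#'   `pan_down`, data.frame `relaxed` (gene, direction, support),
#'   `conflicted` genes, and the gene x subtype fold-change matrix
#' @export
intersect_signatures <- function(per_subtype, criteria = NULL, min_support = 3L) {
  if (!is.list(per_subtype) || length(per_subtype) < 2L) {
    stop("need DE results for at least two subtypes")
  }
  if (is.null(names(per_subtype)) || any(names(per_subtype) == "")) {
    stop("'per_subtype' must be a named list")
  }
  genes <- sort(per_subtype[[1L]]$gene)
  for (nm in names(per_subtype)) {
    if (!identical(sort(per_subtype[[nm]]$gene), genes)) {
      stop("DE results are not over a common gene universe ('", nm, "' differs)")
    }
  }
  check_count(min_support, "min_support")
  n_sub <- length(per_subtype)
  if (min_support > n_sub) stop("'min_support' exceeds the number of subtypes")

  fc <- sapply(per_subtype, function(de) de$fold_change[match(genes, de$gene)])
  rownames(fc) <- genes
  sig <- sapply(per_subtype, function(de) {
    genes %in% de_significant(de, criteria)
  })
  rownames(sig) <- genes

  up <- sig & fc > 1
  down <- sig & fc < -1
  n_up <- rowSums(up)
  n_down <- rowSums(down)

  conflicted <- genes[n_up > 0L & n_down > 0L]
  clean <- !(genes %in% conflicted)
  pan_up <- genes[clean & n_up == n_sub]
  pan_down <- genes[clean & n_down == n_sub]

  support <- pmax(n_up, n_down)
  in_relaxed <- clean & support >= min_support
  relaxed <- data.frame(
    gene = genes[in_relaxed],
    direction = ifelse(n_up[in_relaxed] >= n_down[in_relaxed], "up", "down"),
    support = as.integer(support[in_relaxed]),
    stringsAsFactors = FALSE
  )
  relaxed <- relaxed[order(-relaxed$support, relaxed$gene), ]
  rownames(relaxed) <- NULL

  out <- list(pan_up = pan_up, pan_down = pan_down, relaxed = relaxed,
              conflicted = conflicted, fold_changes = fc,
              min_support = as.integer(min_support))
  class(out) <- "signature_result"
  out
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("Shared signature over %d subtypes\n", ncol(x$fold_changes)))
  cat(sprintf("  pan-up (%d): %s\n", length(x$pan_up),
              paste(utils::head(x$pan_up, 10L), collapse = ", ")))
  cat(sprintf("  pan-down (%d): %s\n", length(x$pan_down),
              paste(utils::head(x$pan_down, 10L), collapse = ", ")))
  cat(sprintf("  relaxed (>= %d of %d subtypes): %d gene(s); %d direction-conflicted\n",
              x$min_support, ncol(x$fold_changes), nrow(x$relaxed),
              length(x$conflicted)))
  invisible(x)
}

#' Write the pan-subtype signature lists as a GMT file
#' @param signature a `signature_result`
#' @param path output GMT path
#' @export
write_signature_gmt <- function(signature, path) {
  sets <- list(PAN_UP = signature$pan_up, PAN_DOWN = signature$pan_down)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  if (length(sets) == 0L) stop("signature has no pan-regulated genes to write")
  write_gmt(sets, path,
            descriptions = c(PAN_UP = "up-regulated in all subtypes",
                             PAN_DOWN = "down-regulated in all subtypes")[names(sets)])
}
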