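# Probe-level preprocessing: averaging replicate spots, collapsing multiple
# probes per gene symbol to the maximally expressed probe (mean intensity
# across all arrays, linear scale), and restricting to a declared gene panel.

#' Average replicate rows
#'
#' Rows named in `replicate_groups` are replaced by the per-sample
#' arithmetic mean of their group; rows not mentioned pass through
#' unchanged. The averaged row takes the group id as its name and sits at
#' the position of the group's first member.
#'
#' @param mat expression matrix (rows x samples)
#' @param replicate_groups named character vector: row id -> group id
#' @return expression matrix with one row per group
#' @export
average_replicates <- function(mat, replicate_groups) {
  check_expression_matrix(mat)
  if (length(replicate_groups) == 0L) return(mat)
  if (is.null(names(replicate_groups))) {
    stop("'replicate_groups' must be named by row id")
  }
  missing_rows <- setdiff(names(replicate_groups), rownames(mat))
  if (length(missing_rows) > 0L) {
    stop("replicate group members absent from the matrix: ",
         paste(missing_rows, collapse = ", "))
  }
  new_id <- rownames(mat)
  sel <- match(names(replicate_groups), rownames(mat))
  new_id[sel] <- unname(replicate_groups)
  if (anyDuplicated(new_id[-sel]) || length(intersect(new_id[-sel], new_id[sel])) > 0L) {
    stop("group ids collide with pass-through row ids")
  }
  keep <- !duplicated(new_id)
  sums <- rowsum(mat, group = new_id, reorder = FALSE)
  counts <- as.vector(table(factor(new_id, levels = rownames(sums))))
  out <- sums / counts
  # rowsum orders groups by first appearance, matching keep
  stopifnot(identical(rownames(out), new_id[keep]))
  out
}

#' Collapse probes to one row per gene symbol
#'
#' For each gene, keeps the probe with the highest mean signal across all
#' samples (healthy and malignant pooled, linear scale); ties go to the
#' lexicographically smallest probe id. Output rows are named by gene
#' symbol and sorted by symbol, so the result is invariant to input row
#' order. The chosen probe per gene is recorded in the `"chosen_probes"`
#' attribute.
#'
#' @param mat probe-level expression matrix
#' @param map named character vector (probe id -> gene symbol) or
#'   data.frame with columns probe_id, gene_symbol
#' @return gene-level expression matrix with attribute `chosen_probes`
#' @export
collapse_probes <- function(mat, map) {
  check_expression_matrix(mat)
  if (is.data.frame(map)) {
    map <- stats::setNames(as.character(map$gene_symbol), as.character(map$probe_id))
  }
  unmapped <- setdiff(rownames(mat), names(map))
  if (length(unmapped) > 0L) {
    stop("unmapped probe(s): ", paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  gene <- unname(map[rownames(mat)])
  m <- rowMeans(mat)
  ord <- order(gene, -m, rownames(mat), method = "radix")
  first <- ord[!duplicated(gene[ord])]
  out <- mat[first, , drop = FALSE]
  chosen <- rownames(mat)[first]
  rownames(out) <- gene[first]
  attr(out, "chosen_probes") <- stats::setNames(chosen, gene[first])
  out
}

#' Restrict a gene-level matrix to a gene panel
#'
#' Keeps the rows whose symbol is in the panel, preserving the matrix's
#' original row order. Panel genes absent from the matrix are reported via
#' a warning and the `"missing_genes"` attribute.
#'
#' @param mat gene-level expression matrix
#' @param panel character vector of gene symbols (or one element of a GMT
#'   list as returned by [read_gmt()])
#' @return the restricted matrix
#' @export
filter_to_panel <- function(mat, panel) {
  check_expression_matrix(mat)
  panel <- unique(as.character(panel))
  if (length(panel) == 0L) stop("empty gene panel")
  keep <- rownames(mat) %in% panel
  if (!any(keep)) stop("no panel gene is present in the matrix")
  absent <- setdiff(panel, rownames(mat))
  if (length(absent) > 0L) {
    warning(length(absent), " panel gene(s) absent from the matrix: ",
            paste(utils::head(absent, 10L), collapse = ", "))
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "missing_genes") <- absent
  out
}
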