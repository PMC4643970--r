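# Readers/writers for the plain-text formats used throughout: expression TSV
# (first column row id, header of sample ids), probe-map TSV, sample
# annotation TSV, GMT gene sets, staining-call TSV, and JSON truth records.

#' Read an expression matrix from TSV
#'
#' First column holds probe/gene identifiers, remaining columns one sample
#' each. Values must be finite and strictly positive (linear-scale signal);
#' offending files are rejected rather than imputed.
#'
#' @param path file path
#' @return numeric matrix (rows = probes/genes, columns = samples)
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus at least one sample")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  check_expression_matrix(mat, paste0("expression matrix '", path, "'"))
  mat
}

#' Write an expression matrix to TSV
#' @param mat numeric matrix with row and column names
#' @param path output file
#' @param id_name header for the identifier column
#' @export
write_expression <- function(mat, path, id_name = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map from TSV
#' @param path TSV with columns probe_id, gene_symbol
#' @return named character vector (probe id -> gene symbol)
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    stop("probe map must have columns 'probe_id' and 'gene_symbol'")
  }
  stats::setNames(as.character(df$gene_symbol), as.character(df$probe_id))
}

#' Write a probe-to-gene map to TSV
#' @param map named character vector (probe id -> gene symbol) or a
#'   data.frame with columns probe_id, gene_symbol
#' @param path output file
#' @export
write_probe_map <- function(map, path) {
  if (!is.data.frame(map)) {
    map <- data.frame(probe_id = names(map), gene_symbol = unname(map),
                      stringsAsFactors = FALSE)
  }
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#' @param path TSV with columns sample_id, class, subtype
#' @return data.frame
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "subtype")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns ", paste(need, collapse = ", "))
  }
  if (!all(df$class %in% c("healthy", "malignant"))) {
    stop("annotation 'class' must be 'healthy' or 'malignant'")
  }
  df
}

#' Write a sample annotation table to TSV
#' @param annotation data.frame with sample_id, class, subtype
#' @param path output file
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' @param path GMT file
#' @return named list of character vectors, with a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("GMT line(s) without members: ", which(bad)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output file
#' @param descriptions optional named character vector of set descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) stop("gene sets must be named")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read immunohistochemistry staining calls from TSV
#' @param path TSV with columns core_id, patient_id, subtype, marker,
#'   lymphoid_call, stromal_call
#' @return data.frame of class `staining_table`
#' @export
read_staining <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("core_id", "patient_id", "subtype", "marker", "lymphoid_call", "stromal_call")
  if (!all(need %in% names(df))) {
    stop("staining table must have columns ", paste(need, collapse = ", "))
  }
  class(df) <- c("staining_table", "data.frame")
  df
}

#' Write immunohistochemistry staining calls to TSV
#' @param records a `staining_table` data.frame
#' @param path output file
#' @export
write_staining <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth record as JSON
#' @param truth the `truth` element of a simulated cohort
#' @param path output file
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation truth record from JSON
#' @param path JSON file written by [write_truth()]
#' @return list
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
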