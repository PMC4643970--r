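# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean of strictly positive values
#' @param x numeric vector, all > 0
#' @return the geometric mean
#' @keywords internal
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires finite, strictly positive values")
  }
  exp(mean(log(x)))
}

# Half-up percentage rounding: 62.5 -> 63, matching how clinical tables are
# typically rounded (base R's round() is half-even and would give 62).
pct_round <- function(x) floor(x + 0.5)

# Validate an expression matrix: numeric, finite, strictly positive values,
# unique non-empty row and column names.
check_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(what, " must be a numeric matrix")
  }
  rn <- rownames(mat)
  cn <- colnames(mat)
  if (is.null(rn) || anyNA(rn) || any(rn == "") || anyDuplicated(rn)) {
    stop(what, " must have unique, non-empty row names")
  }
  if (is.null(cn) || anyNA(cn) || any(cn == "") || anyDuplicated(cn)) {
    stop(what, " must have unique, non-empty column names")
  }
  if (any(!is.finite(mat))) {
    stop(what, " contains non-finite values; rows with missing signal must be removed, not imputed")
  }
  if (any(mat <= 0)) {
    stop(what, " contains non-positive values; signal must be positive on the linear scale")
  }
  invisible(mat)
}

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("'", name, "' must lie in [0, 1]")
  }
  invisible(x)
}

check_open_unit <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop("'", name, "' must be a single value in (0, 1)")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) < 1L || any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    stop("'", name, "' must contain integer counts >= ", min)
  }
  invisible(x)
}
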