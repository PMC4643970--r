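# Reference study conditions: the cohort structure, the 21-gene pan-subtype
# signature with its per-subtype fold-changes, the per-subtype CAV1-High
# probabilities, and the tissue-microarray staining counts. These are the
# defaults the synthetic cohort emulates.

#' Mature T-cell lymphoma subtypes covered by the analysis
#' @return character vector of subtype labels
#' @export
tcl_subtypes <- function() c("AITL", "ALCL", "ATLL", "HSTL", "PTCL-NOS")

#' Default malignant cohort sizes per subtype
#'
#' 187 biopsy samples across the five subtypes (43 AITL, 45 ALCL, 13 ATLL,
#' 8 HSTL, 78 PTCL-NOS), profiled against 52 healthy CD4+/CD8+ T-cell
#' controls.
#' @return named integer vector of per-subtype sample counts
#' @export
default_subtype_sizes <- function() {
  c(AITL = 43L, ALCL = 45L, ATLL = 13L, HSTL = 8L, `PTCL-NOS` = 78L)
}

#' The 21-gene pan-subtype signature and its per-subtype fold-changes
#'
#' Signed linear-scale fold-changes (malignant vs healthy) for the six genes
#' up-regulated and fifteen genes down-regulated across all five mature
#' T-cell lymphoma subtypes. Positive values are ratios of group geometric
#' means; down-regulation is printed as the negative reciprocal ratio
#' (so -3.01 means healthy is 3.01-fold above malignant).
#'
#' @return a data.frame with column `gene` and one signed fold-change column
#'   per subtype ([tcl_subtypes()])
#' @export
pan_signature_foldchanges <- function() {
  df <- data.frame(
    gene = c("CAV1", "CCNB2", "THY1", "TNFRSF21", "ENAH", "PSEN2",
             "CD3G", "TNFRSF14", "RICTOR", "LAT", "CD5", "IL23A", "ITK",
             "STAT5A", "TSC22D3", "UBASH3A", "PRKCQ", "FOXP1", "PAG1",
             "BCL10", "PDE4B"),
    AITL = c(16.33, 7.55, 13.65, 6.38, 5.62, 2.94,
             -3.01, -1.49, -2.42, -2.91, -4.12, -3.26, -3.67,
             -2.14, -5.66, -2.43, -2.98, -4.90, -3.81, -4.96, -4.21),
    ALCL = c(12.52, 8.93, 12.98, 6.27, 5.36, 4.77,
             -6.81, -1.58, -4.36, -3.61, -6.55, -3.50, -10.78,
             -2.11, -6.63, -4.27, -8.26, -3.96, -2.32, -7.82, -3.55),
    ATLL = c(38.17, 13.99, 9.46, 5.34, 2.52, 2.26,
             -1.65, -1.69, -1.75, -1.92, -2.10, -2.23, -2.36,
             -2.50, -2.56, -2.86, -3.58, -3.69, -4.30, -6.54, -7.44),
    HSTL = c(34.41, 9.65, 2.46, 9.30, 22.63, 3.39,
             -2.02, -1.99, -2.25, -3.76, -17.27, -4.51, -2.70,
             -2.63, -4.07, -6.97, -2.92, -3.40, -3.69, -7.15, -3.42),
    `PTCL-NOS` = c(16.33, 7.55, 13.65, 6.38, 5.62, 2.94,
                   -3.00, -1.49, -2.42, -2.91, -4.11, -3.26, -3.67,
                   -2.14, -5.66, -2.43, -2.98, -4.90, -3.81, -4.96, -4.21),
    check.names = FALSE
  )
  df
}

#' Per-subtype probability of a malignant sample being CAV1-High
#'
#' Observed CAV1-High fractions per subtype (77% AITL, 47% ALCL, 85% ATLL,
#' 75% HSTL, 69% PTCL-NOS), used as the planted mixture weights of the
#' bimodal CAV1 model in the simulator.
#' @return named numeric vector of probabilities
#' @export
default_cav1_high_prob <- function() {
  c(AITL = 0.77, ALCL = 0.47, ATLL = 0.85, HSTL = 0.75, `PTCL-NOS` = 0.69)
}

#' Reference tissue-microarray lymphoid staining counts
#'
#' Patient-level lymphoid-positive counts per subtype and marker for the
#' 65-patient tissue microarray (8 AITL, 14 ALCL, 43 PTCL-NOS), for the four
#' markers BCL10, CAV1, GILZ and CD90. Used as the default marginals of
#' [simulate_ihc_table()].
#' @return data.frame with columns subtype, marker, n_positive, n_total
#' @export
default_ihc_counts <- function() {
  data.frame(
    subtype = rep(c("ALCL", "AITL", "PTCL-NOS"), each = 4L),
    marker = rep(c("BCL10", "CAV1", "GILZ", "CD90"), times = 3L),
    n_positive = c(13L, 6L, 13L, 5L,
                   7L, 5L, 8L, 6L,
                   39L, 25L, 40L, 18L),
    n_total = c(rep(14L, 4L), rep(8L, 4L), rep(43L, 4L))
  )
}
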