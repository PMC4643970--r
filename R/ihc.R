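# Tissue-microarray staining summaries: per-subtype, per-marker lymphoid
# positivity percentages at the patient level, with pooled per-marker
# fractions; stromal positivity is tabulated separately.

LYMPHOID_CALLS <- c("positive", "light", "negative")
STROMAL_CALLS <- c("positive", "light", "negative", "none-recorded")

#' Summarize tissue-microarray staining calls
#'
#' A patient is lymphoid-positive for a marker iff any of their cores is
#' scored positive (or light, which reconciles with how light calls are
#' counted in the reference tables); `patient_rule = "all"` requires every
#' core positive instead. Percentages are rounded half-up to whole percent.
#'
#' @param records a `staining_table` data.frame (see [read_staining()])
#' @param patient_rule `"any"` (default) or `"all"` core(s) positive
#' @param light_positive count "light" calls as positive (default TRUE)
#' @return an object of class `staining_summary`: `per_subtype` and
#'   `pooled` lymphoid data.frames, plus `stromal` per-subtype counts
#' @export
summarize_staining <- function(records, patient_rule = c("any", "all"),
                               light_positive = TRUE) {
  patient_rule <- match.arg(patient_rule)
  records <- as.data.frame(records)
  need <- c("patient_id", "subtype", "marker", "lymphoid_call", "stromal_call")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  bad <- !(records$lymphoid_call %in% LYMPHOID_CALLS)
  if (any(bad)) {
    stop("unknown lymphoid call '", records$lymphoid_call[which(bad)[1L]],
         "' in record ", which(bad)[1L])
  }
  bad_s <- !(records$stromal_call %in% STROMAL_CALLS)
  if (any(bad_s)) {
    stop("unknown stromal call '", records$stromal_call[which(bad_s)[1L]],
         "' in record ", which(bad_s)[1L])
  }
  pos_calls <- if (light_positive) c("positive", "light") else "positive"
  is_pos <- records$lymphoid_call %in% pos_calls

  key <- interaction(records$subtype, records$marker, records$patient_id, drop = TRUE)
  agg_fun <- if (patient_rule == "any") any else all
  patient_pos <- tapply(is_pos, key, agg_fun)
  meta <- records[match(names(patient_pos), as.character(key)), c("subtype", "marker")]

  per <- stats::aggregate(cbind(n_positive = as.integer(patient_pos),
                                n_patients = rep(1L, length(patient_pos))),
                          by = list(subtype = meta$subtype, marker = meta$marker),
                          FUN = sum)
  per$percent <- pct_round(100 * per$n_positive / per$n_patients)
  per <- per[order(per$subtype, per$marker), ]
  rownames(per) <- NULL

  pooled <- stats::aggregate(cbind(n_positive = per$n_positive,
                                   n_patients = per$n_patients),
                             by = list(marker = per$marker), FUN = sum)
  pooled$percent <- pct_round(100 * pooled$n_positive / pooled$n_patients)

  strom_pos <- tapply(records$stromal_call == "positive" |
                        (light_positive & records$stromal_call == "light"),
                      key, agg_fun)
  stromal <- stats::aggregate(cbind(n_positive = as.integer(strom_pos),
                                    n_patients = rep(1L, length(strom_pos))),
                              by = list(subtype = meta$subtype, marker = meta$marker),
                              FUN = sum)
  stromal$percent <- pct_round(100 * stromal$n_positive / stromal$n_patients)
  stromal <- stromal[order(stromal$subtype, stromal$marker), ]
  rownames(stromal) <- NULL

  out <- list(per_subtype = per, pooled = pooled, stromal = stromal,
              patient_rule = patient_rule, light_positive = light_positive)
  class(out) <- "staining_summary"
  out
}

#' @export
print.staining_summary <- function(x, ...) {
  cat(sprintf("Staining summary (patient rule: %s core positive; light %s positive)\n",
              x$patient_rule, if (x$light_positive) "counts as" else "excluded from"))
  cat("  lymphoid positivity by subtype:\n")
  for (i in seq_len(nrow(x$per_subtype))) {
    r <- x$per_subtype[i, ]
    cat(sprintf("    %-10s %-6s %3d%% (%d/%d)\n", r$subtype, r$marker,
                r$percent, r$n_positive, r$n_patients))
  }
  cat("  pooled per marker:\n")
  for (i in seq_len(nrow(x$pooled))) {
    r <- x$pooled[i, ]
    cat(sprintf("    %-6s %3d%% (%d/%d)\n", r$marker, r$percent,
                r$n_positive, r$n_patients))
  }
  invisible(x)
}

#' Write a staining summary to TSV
#' @param summary a `staining_summary`
#' @param path output file
#' @export
write_staining_summary <- function(summary, path) {
  utils::write.table(summary$per_subtype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
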