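# Method-assessment statistics: reproducibility-ratio curves, intra-to-inter
# ratio, event-level confusion labels, gene-level aggregation.

#' Reproducibility-ratio curve
#'
#' `RR(n)` is the fraction of the top n events of the first ranked list that
#' also appear among the top n events of the second; the reproducibility
#' ratio of the comparison is `RR(N)` with N the length of the first list.
#'
#' @param list1,list2 character vectors of event identifiers ranked by
#'   significance (most significant first); identifiers must be unique
#'   within each list.
#' @return numeric vector `RR(1..length(list1))` (empty for an empty
#'   `list1`).
#' @export
rr_curve <- function(list1, list2) {
  stopifnot(!anyDuplicated(list1), !anyDuplicated(list2))
  n_a <- length(list1)
  if (n_a == 0) return(numeric(0))
  vapply(seq_len(n_a), function(n) {
    length(intersect(list1[seq_len(n)], head(list2, n))) / n
  }, numeric(1))
}

#' Collapse overlapping LSVs in a ranked list
#'
#' Two LSVs overlap when they share at least one junction; walking the list
#' from the top, an LSV is skipped if an overlapping one is already ranked.
#'
#' @param ids ranked LSV identifiers.
#' @param junctions list (parallel to `ids`) of character vectors of junction
#'   keys per LSV.
#' @return logical vector: keep this entry?
#' @export
collapse_overlapping <- function(ids, junctions) {
  seen <- character(0)
  keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    if (any(junctions[[k]] %in% seen)) next
    keep[k] <- TRUE
    seen <- c(seen, junctions[[k]])
  }
  keep
}

#' Intra-to-inter ratio
#'
#' Ratio of the number of significant events in a same-condition comparison
#' to the number in a between-condition comparison; a proxy for FDR on real
#' data.  `NA` (missing) when the inter count is zero.
#'
#' @param n_intra,n_inter non-negative significant-event counts.
#' @return the ratio, or `NA_real_`.
#' @export
iir <- function(n_intra, n_inter) {
  if (n_intra < 0 || n_inter < 0) stop("counts must be non-negative")
  if (n_inter == 0) return(NA_real_)
  n_intra / n_inter
}

#' Label one event against ground truth
#'
#' Applies the TP/TN/FP/FN conjunctions on the event-level maxima: TP when
#' the tool reports |dPSI| >= 20% with p <= 0.05 and the true |dPSI| >= 20%;
#' TN when the tool reports < 5% with p > 0.05 and truth < 5%; FP/FN for the
#' two discordant combinations; everything else (truth in \[5%, 20%) or tool
#' dPSI/p conflict) is Ambiguous.
#'
#' @param dpsi_tool max |dPSI| reported over the event's edges.
#' @param p_tool the tool's p value for the event.
#' @param dpsi_gt max ground-truth |dPSI| over the event's edges.
#' @param thresholds `c(changing, nonchanging, alpha)`.
#' @return one of `"TP"`, `"TN"`, `"FP"`, `"FN"`, `"Ambiguous"`.
#' @export
label_event <- function(dpsi_tool, p_tool, dpsi_gt,
                        thresholds = c(0.20, 0.05, 0.05)) {
  chg <- thresholds[1]; nochg <- thresholds[2]; alpha <- thresholds[3]
  tool_pos <- dpsi_tool >= chg && p_tool <= alpha
  tool_neg <- dpsi_tool < nochg && p_tool > alpha
  if (tool_pos && dpsi_gt >= chg) return("TP")
  if (tool_neg && dpsi_gt < nochg) return("TN")
  if (tool_pos && dpsi_gt < nochg) return("FP")
  if (tool_neg && dpsi_gt >= chg) return("FN")
  "Ambiguous"
}

#' Aggregate event labels to a gene label
#'
#' The gene takes the highest-priority label present among its events, in
#' the order FP > FN > TP > TN; a gene whose events are all Ambiguous is
#' excluded (`NA`).
#'
#' @param event_labels character vector of event labels for one gene.
#' @return one of `"FP"`, `"FN"`, `"TP"`, `"TN"`, or `NA_character_`.
#' @export
gene_label <- function(event_labels) {
  for (lab in c("FP", "FN", "TP", "TN")) {
    if (lab %in% event_labels) return(lab)
  }
  NA_character_
}

#' Confusion summary over gene labels
#'
#' @param labels character vector of gene labels (`TP`/`TN`/`FP`/`FN`; `NA`
#'   entries are dropped).
#' @return list with `totals`, `FDR` = FP/(FP+TP), `FNR` = FN/(FN+TP), and
#'   `MCC`; zero-denominator quantities are `NA`.
#' @export
confusion_summary <- function(labels) {
  labels <- labels[!is.na(labels)]
  tp <- sum(labels == "TP"); tn <- sum(labels == "TN")
  fp <- sum(labels == "FP"); fn <- sum(labels == "FN")
  fdr <- if (fp + tp > 0) fp / (fp + tp) else NA_real_
  fnr <- if (fn + tp > 0) fn / (fn + tp) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  list(totals = c(TP = tp, TN = tn, FP = fp, FN = fn),
       FDR = fdr, FNR = fnr, MCC = mcc)
}
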