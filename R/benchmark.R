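#' Shuffled decoy sequences
#'
#' Builds one decoy per input sequence by uniformly permuting its residues
#' (Fisher-Yates via `sample`), preserving length and composition while
#' destroying any homology signal. Decoy ids get a `_shuf` suffix.
#'
#' @param targets named character vector of sequences
#' @param seed RNG seed
#' @param suffix id suffix for decoys
#' @return named character vector of decoys
#' @export
shuffle_decoys <- function(targets, seed = 1L, suffix = "_shuf") {
  if (length(targets) == 0L) stop("no sequences to shuffle")
  set.seed(as.integer(seed))
  out <- vapply(targets, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  names(out) <- paste0(names(targets), suffix)
  out
}

#' Label query-target pairs by alignment E-value strata
#'
#' Stratifies trusted pairwise E-values into the evaluation classes:
#' `true_strong` (E <= strong_cut), `true_weak` (E <= weak_cut but not
#' strong), `decoy_low_sim` (E >= decoy_cut) and `unlabeled` (between
#' weak_cut and decoy_cut, excluded from both recall and filtration).
#' Strong pairs also count as weak when curves are computed at the weak
#' stratum.
#'
#' @param evalues data.frame with columns `query_id`, `target_id`, `evalue`
#' @param strong_cut,weak_cut,decoy_cut E-value cutoffs (defaults 1e-10,
#'   1e-3, 10)
#' @return truth table data.frame: `query_id`, `target_id`, `label`,
#'   `evalue`
#' @export
label_truth <- function(evalues, strong_cut = 1e-10, weak_cut = 1e-3,
                        decoy_cut = 10) {
  stopifnot(all(c("query_id", "target_id", "evalue") %in% names(evalues)))
  if (any(evalues$evalue < 0)) stop("E-values must be non-negative")
  key <- paste(evalues$query_id, evalues$target_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (query, target) pair in E-value table")
  e <- evalues$evalue
  label <- ifelse(e <= strong_cut, "true_strong",
           ifelse(e <= weak_cut, "true_weak",
           ifelse(e >= decoy_cut, "decoy_low_sim", "unlabeled")))
  data.frame(query_id = evalues$query_id, target_id = evalues$target_id,
             label = label, evalue = e, stringsAsFactors = FALSE)
}

## true_strong pairs satisfy the true_weak stratum as well.
label_matches <- function(label, want) {
  label == want | (want == "true_weak" & label == "true_strong")
}

#' Recall-versus-filtration curve
#'
#' Sweeps a score threshold over the distinct hit scores (descending) and,
#' at each, reports recall (fraction of true pairs with score >= threshold)
#' and filtration (fraction of decoy pairs with score < threshold). Truth
#' pairs absent from the hit list are treated as score -Inf: filtered at
#' every threshold, never recalled. The curve is monotone: recall
#' non-increasing and filtration non-decreasing as the threshold rises.
#'
#' @param hits data.frame with `query_id`, `target_id`, `score`
#' @param truth truth table from [label_truth()] (or the simulator)
#' @param true_label stratum counted for recall (default `"true_strong"`;
#'   `"true_weak"` includes strong pairs)
#' @param decoy_label stratum counted for filtration (default
#'   `"decoy_shuffled"`)
#' @return data.frame of curve points: `threshold`, `recall`, `filtration`
#' @export
recall_filtration_curve <- function(hits, truth,
                                    true_label = "true_strong",
                                    decoy_label = "decoy_shuffled") {
  tp <- truth[label_matches(truth$label, true_label), , drop = FALSE]
  dp <- truth[label_matches(truth$label, decoy_label), , drop = FALSE]
  if (nrow(tp) == 0L) stop("no true pairs in truth table for label ", true_label)
  if (nrow(dp) == 0L) stop("no decoy pairs in truth table for label ", decoy_label)
  score_of <- function(tab) {
    key <- paste(tab$query_id, tab$target_id, sep = "\r")
    hkey <- paste(hits$query_id, hits$target_id, sep = "\r")
    s <- hits$score[match(key, hkey)]
    s[is.na(s)] <- -Inf
    s
  }
  st <- score_of(tp); sd_ <- score_of(dp)
  thresholds <- sort(unique(hits$score), decreasing = TRUE)
  if (length(thresholds) == 0L) thresholds <- 0
  pts <- vapply(thresholds, function(th)
    c(recall = mean(st >= th), filtration = mean(sd_ < th)),
    numeric(2))
  data.frame(threshold = thresholds, recall = pts["recall", ],
             filtration = pts["filtration", ])
}

#' Recall at a filtration level
#'
#' Step-function read-out of a curve: recall at the smallest threshold whose
#' filtration reaches `level` (no interpolation).
#'
#' @param curve data.frame from [recall_filtration_curve()]
#' @param level required filtration in `[0, 1]`
#' @return recall at that threshold
#' @export
recall_at_filtration <- function(curve, level) {
  stopifnot(nrow(curve) >= 1L)
  ok <- curve$filtration >= level
  if (!any(ok))
    stop(sprintf("filtration level %.3f not achievable (max %.3f)",
                 level, max(curve$filtration)))
  cand <- curve[ok, , drop = FALSE]
  cand$recall[which.min(cand$threshold)]
}
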