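# Rank-based ROC analysis of single VOI-element features between two
# diagnostic groups: one AUC per (region, element), ranked descending.

#' Mann-Whitney AUC
#'
#' Nonparametric area under the ROC curve: the probability that a random
#' positive-class score exceeds a random negative-class score, with ties
#' counted one half. Computed from the rank sum, so it is invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores_neg,scores_pos Finite, non-empty score vectors for the
#'   negative and positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores_neg, scores_pos) {
  if (length(scores_neg) == 0L || length(scores_pos) == 0L) {
    stopf("both groups must be non-empty")
  }
  if (!all(is.finite(scores_neg)) || !all(is.finite(scores_pos))) {
    stopf("scores must be finite")
  }
  n_neg <- length(scores_neg)
  n_pos <- length(scores_pos)
  r <- rank(c(scores_neg, scores_pos))
  (sum(r[n_neg + seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Rank VOI-element features by group discrimination
#'
#' Computes one AUC per (region, element) feature between the two groups.
#' The clinically positive class is the second entry of `group_pair`; when a
#' feature's raw AUC falls below 0.5 it is reported as `1 - AUC` with
#' `orientation = -1`, so AUC magnitudes are comparable regardless of
#' whether an element rises or falls with atrophy. Results are sorted by
#' descending AUC with deterministic lexicographic (region, element)
#' tie-breaks. Features that are missing for any subject are skipped and
#' logged.
#'
#' @param features A [voi_feature_table()].
#' @param group_pair Character pair `c(negative, positive)`, e.g.
#'   `c("NL", "AD")`.
#' @return `data.frame(rank, element, region, auc, orientation, n_neg,
#'   n_pos)` sorted by rank.
#' @export
rank_regions <- function(features, group_pair) {
  if (length(group_pair) != 2L) stopf("group_pair must have two entries")
  if (!all(group_pair %in% features$group)) {
    stopf("group(s) not present in the feature table: %s",
          paste(setdiff(group_pair, features$group), collapse = ", "))
  }
  sub <- features[features$group %in% group_pair, , drop = FALSE]
  n_subj_neg <- length(unique(sub$subject_id[sub$group == group_pair[1]]))
  n_subj_pos <- length(unique(sub$subject_id[sub$group == group_pair[2]]))
  if (n_subj_neg < 2L || n_subj_pos < 2L) {
    stopf("need at least 2 subjects per group")
  }
  keys <- unique(sub[, c("region", "element")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- sub$region == keys$region[i] & sub$element == keys$element[i]
    vals <- sub$value[sel]
    grps <- sub$group[sel]
    if (anyNA(vals)) {
      cpc_log("feature %s|%s has missing values; skipped",
              keys$region[i], keys$element[i])
      next
    }
    a <- auc_mann_whitney(vals[grps == group_pair[1]],
                          vals[grps == group_pair[2]])
    orientation <- 1
    if (a < 0.5) { a <- 1 - a; orientation <- -1 }
    rows[[length(rows) + 1L]] <- data.frame(
      element = keys$element[i], region = keys$region[i], auc = a,
      orientation = orientation, n_neg = n_subj_neg, n_pos = n_subj_pos,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stopf("no usable features")
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$region, out$element), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
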