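# Segmentation scoring against ground-truth labels (synthetic clouds carry
# them). Instance matching follows the majority-overlap convention: a
# predicted cluster "correctly segments" a true leaf when each holds the
# majority of the other.

#' Point-level precision/recall/F1 for the stem class
#'
#' @param predicted logical or "stem"/other labels for every point
#' @param truth ground-truth labels ("stem" vs anything else)
#' @return named numeric vector: precision, recall, f1
#' @export
stemF1 <- function(predicted, truth) {
  pred <- if (is.logical(predicted)) predicted else predicted == "stem"
  tru <- truth == "stem"
  tp <- sum(pred & tru)
  prec <- if (sum(pred)) tp / sum(pred) else 0
  rec <- if (sum(tru)) tp / sum(tru) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' Leaf-instance recall and precision by majority overlap
#'
#' A true leaf is correctly segmented when some predicted cluster contains
#' the majority of that leaf's points and the leaf provides the majority of
#' that cluster's points. Recall = correct / true leaves; precision =
#' correct / predicted clusters.
#'
#' @param pred_labels integer predicted leaf labels (0 = unassigned/dropped)
#' @param true_labels character ground-truth labels (\code{"leaf_<k>"} for
#'   leaves; other values are ignored for matching but predicted clusters
#'   dominated by them still count against precision)
#' @return named numeric vector: recall, precision, n_true, n_pred, n_correct
#' @export
leafInstanceScore <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels))
  true_ids <- unique(grep("^leaf_", true_labels, value = TRUE))
  pred_ids <- setdiff(unique(pred_labels), 0L)
  n_true <- length(true_ids); n_pred <- length(pred_ids)
  correct <- 0L
  for (tl in true_ids) {
    ti <- true_labels == tl
    if (!sum(ti)) next
    tab <- table(pred_labels[ti & pred_labels > 0])
    if (!length(tab)) next
    best <- names(tab)[which.max(tab)]
    if (tab[[best]] <= sum(ti) / 2) next          # cluster must hold most of the leaf
    ci <- pred_labels == as.integer(best)
    if (sum(true_labels[ci] == tl) > sum(ci) / 2)  # leaf must dominate the cluster
      correct <- correct + 1L
  }
  c(recall = if (n_true) correct / n_true else NA_real_,
    precision = if (n_pred) correct / n_pred else NA_real_,
    n_true = n_true, n_pred = n_pred, n_correct = correct)
}

#' Match predicted leaves to true leaves and compare areas
#'
#' @param pred_labels integer predicted leaf labels per point
#' @param true_labels character ground-truth labels per point
#' @param pred_areas numeric areas indexed by predicted label
#' @param true_areas numeric areas indexed by true leaf number
#' @return data.frame (true_leaf, pred_cluster, true_area, pred_area,
#'   rel_error); unmatched true leaves get NA pred columns
#' @export
matchLeafAreas <- function(pred_labels, true_labels, pred_areas, true_areas) {
  true_ids <- sort(unique(as.integer(sub("^leaf_", "",
    grep("^leaf_", true_labels, value = TRUE)))))
  out <- data.frame(true_leaf = true_ids, pred_cluster = NA_integer_,
                    true_area = true_areas[true_ids],
                    pred_area = NA_real_, rel_error = NA_real_)
  for (r in seq_along(true_ids)) {
    ti <- true_labels == paste0("leaf_", true_ids[r])
    tab <- table(pred_labels[ti & pred_labels > 0])
    if (!length(tab)) next
    best <- as.integer(names(tab)[which.max(tab)])
    if (tab[[as.character(best)]] <= sum(ti) / 2) next
    out$pred_cluster[r] <- best
    if (best <= length(pred_areas)) {
      out$pred_area[r] <- pred_areas[best]
      out$rel_error[r] <- (pred_areas[best] - out$true_area[r]) /
        out$true_area[r]
    }
  }
  out
}
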