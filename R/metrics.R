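# Evaluation of a predicted optic-disc mask against ground truth:
# Jaccard overlap ratio, pixelwise precision/recall/F-score, and the
# >= 75%-overlap success rule with its accuracy rate.

#' Overlap ratio (Jaccard index)
#'
#' \eqn{T = |G \cap D| / |G \cup D|} between the ground-truth mask
#' \eqn{G} and the predicted mask \eqn{D}. A segmentation is counted
#' successful when \eqn{T \ge 0.75}.
#'
#' @param truth Ground-truth {0,1} matrix (non-empty).
#' @param predicted Predicted {0,1} matrix, congruent with
#'   \code{truth}.
#' @return Scalar in [0, 1] (0 for an empty prediction).
#' @export
overlap_ratio <- function(truth, predicted) {
  check_binary_mask(truth, "truth")
  check_binary_mask(predicted, "predicted")
  if (!all(dim(truth) == dim(predicted)))
    stop("masks must have the same shape", call. = FALSE)
  if (sum(truth) == 0)
    stop("`truth` mask is empty", call. = FALSE)
  inter <- sum(truth == 1 & predicted == 1)
  uni <- sum(truth == 1 | predicted == 1)
  inter / uni
}

#' Pixelwise precision, recall and F-score
#'
#' Counts pixels: tp (in both masks), fp (predicted only), fn (truth
#' only); \code{precision = tp/(tp+fp)}, \code{recall = tp/(tp+fn)},
#' \code{F = 2 pr/(p+r)} (0 when \code{p + r = 0}). On masks the
#' F-score equals the Dice coefficient, so it never falls below the
#' Jaccard overlap ratio.
#'
#' @inheritParams overlap_ratio
#' @return An \code{evaluation_scores} list: \code{overlap_t},
#'   \code{precision}, \code{recall}, \code{f_score}, \code{success}
#'   (\code{overlap_t >= 0.75}), \code{tp}, \code{fp}, \code{fn}.
#' @export
precision_recall_f <- function(truth, predicted) {
  check_binary_mask(truth, "truth")
  check_binary_mask(predicted, "predicted")
  if (!all(dim(truth) == dim(predicted)))
    stop("masks must have the same shape", call. = FALSE)
  if (sum(truth) == 0)
    stop("`truth` mask is empty", call. = FALSE)
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  t <- overlap_ratio(truth, predicted)
  structure(list(overlap_t = t, precision = precision, recall = recall,
                 f_score = f, success = t >= 0.75,
                 tp = tp, fp = fp, fn = fn),
            class = "evaluation_scores")
}

#' Accuracy rate of a batch of segmentations
#'
#' Percentage of segmentations whose overlap ratio reaches the 0.75
#' success threshold.
#'
#' @param scores A non-empty list of \code{evaluation_scores}, or a
#'   numeric vector of overlap ratios.
#' @return Percentage in [0, 100].
#' @export
accuracy_rate <- function(scores) {
  if (length(scores) == 0)
    stop("`scores` must be non-empty", call. = FALSE)
  success <- if (is.numeric(scores)) {
    scores >= 0.75
  } else {
    vapply(scores, function(s) isTRUE(s$success), logical(1))
  }
  100 * mean(success)
}

#' Majority-vote consensus of annotator masks
#'
#' Combines two or more ground-truth masks into a consensus: a pixel is
#' foreground when at least half of the annotators marked it (ties go
#' to foreground).
#'
#' @param masks List of >= 2 congruent {0,1} matrices.
#' @return A {0,1} consensus matrix.
#' @export
majority_vote_mask <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("`masks` must be a list of at least two masks", call. = FALSE)
  for (m in masks) check_binary_mask(m)
  d <- dim(masks[[1L]])
  for (m in masks) if (!all(dim(m) == d))
    stop("masks must have the same shape", call. = FALSE)
  (Reduce(`+`, masks) * 2 >= length(masks)) + 0
}
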