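#' Voxel-wise confusion counts between predicted and truth masks
#'
#' @param predicted,truth congruent binary grids (any nonzero value counts as
#'   positive).
#' @return An object of class \code{confusion_counts}: list with integer
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion_from_masks <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)) ||
      length(predicted) != length(truth))
    abort_invalid_input("predicted and truth masks must have the same shape")
  p <- as.logical(predicted != 0); t <- as.logical(truth != 0)
  confusion_counts(TP = sum(p & t), TN = sum(!p & !t),
                   FP = sum(p & !t), FN = sum(!p & t))
}

#' @rdname confusion_from_masks
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    abort_invalid_input("confusion counts must be nonnegative integers")
  if (sum(v) == 0) abort_invalid_input("confusion counts are all zero")
  v <- round(v)
  structure(list(TP = v[["TP"]], TN = v[["TN"]], FP = v[["FP"]],
                 FN = v[["FN"]]), class = "confusion_counts")
}

#' Sensitivity, specificity, overall performance and Dice from counts
#'
#' Computes sensitivity = TP/(TP+FN), specificity = TN/(FP+TN) and overall
#' performance = (TP+TN)/(TP+TN+FP+FN), plus the Dice overlap
#' 2TP/(2TP+FP+FN). A metric whose denominator is zero (e.g. sensitivity
#' with no true positives in the reference) is reported as \code{NaN} with a
#' warning, never silently as 0.
#'
#' @param c a \code{confusion_counts}.
#' @return A one-row data.frame with columns \code{sensitivity},
#'   \code{specificity}, \code{overall_performance}, \code{dice}.
#' @examples
#' eq7_metrics(confusion_counts(TP = 8, FN = 2, TN = 85, FP = 5))
#' @export
eq7_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator); reported as NaN",
                      what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  total <- c$TP + c$TN + c$FP + c$FN
  data.frame(
    sensitivity = safe_div(c$TP, c$TP + c$FN, "sensitivity"),
    specificity = safe_div(c$TN, c$FP + c$TN, "specificity"),
    overall_performance = (c$TP + c$TN) / total,
    dice = safe_div(2 * c$TP, 2 * c$TP + c$FP + c$FN, "dice"))
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2 TP / (2 TP + FP + FN)}. Two empty masks are defined to overlap
#' perfectly (1.0), with a warning.
#'
#' @inheritParams confusion_from_masks
#' @return A number in [0, 1].
#' @export
dice_coefficient <- function(predicted, truth) {
  cc <- confusion_from_masks(predicted, truth)
  if (cc$TP + cc$FP + cc$FN == 0) {
    warning("both masks are empty; Dice defined as 1.0", call. = FALSE)
    return(1.0)
  }
  2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, ties counting one half; computed from midranks so tied scores
#' are handled exactly. The curve sweeps thresholds over the unique scores
#' (predict positive when score >= threshold), yielding points from (0,0) to
#' (1,1).
#'
#' @param scores numeric vector of continuous scores (higher = more
#'   positive).
#' @param labels binary vector (0/1 or logical) of true classes, congruent
#'   with \code{scores}. Both classes must be present.
#' @return List with \code{auc} and \code{curve}, a data.frame with columns
#'   \code{threshold}, \code{fpr}, \code{tpr}.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    abort_invalid_input("'scores' and 'labels' must have equal length")
  if (any(!is.finite(scores)))
    abort_invalid_input("'scores' must be finite")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort_invalid_input("both classes must be present for ROC analysis")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(scores >= t & labels == 0L),
                      numeric(1)) / n_neg),
    tpr = c(0, vapply(thr, function(t) sum(scores >= t & labels == 1L),
                      numeric(1)) / n_pos))
  list(auc = auc, curve = curve)
}

#' Category counts as percentages
#'
#' Cohort-style summaries: each category's share of the total, as a
#' percentage reported to one decimal place.
#'
#' @param category_counts named nonnegative numeric vector of counts.
#' @return A data.frame with columns \code{category}, \code{count},
#'   \code{percent} (rounded to one decimal).
#' @examples
#' summarize_counts(c(male = 73, female = 43))
#' @export
summarize_counts <- function(category_counts) {
  counts <- as.numeric(category_counts)
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0))
    abort_invalid_input("counts must be nonnegative numbers")
  total <- sum(counts)
  if (total <= 0) abort_invalid_input("total count must be positive")
  labels <- names(category_counts)
  if (is.null(labels)) labels <- as.character(seq_along(counts))
  data.frame(category = labels, count = counts,
             percent = round(100 * counts / total, 1))
}

#' Evaluate one or more predicted masks against truth masks
#'
#' Convenience wrapper producing a metrics table (one row per pair), suitable
#' for writing as the CSV the CLI's \code{evaluate} subcommand emits.
#'
#' @param predicted,truth binary grids, or lists of congruent binary grids.
#' @param ids optional row identifiers.
#' @return A data.frame of confusion counts and metrics.
#' @export
evaluate_masks <- function(predicted, truth, ids = NULL) {
  if (!is.list(predicted)) predicted <- list(predicted)
  if (!is.list(truth)) truth <- list(truth)
  if (length(predicted) != length(truth))
    abort_invalid_input("need as many predicted masks as truth masks")
  if (is.null(ids)) ids <- seq_along(predicted)
  rows <- lapply(seq_along(predicted), function(i) {
    cc <- confusion_from_masks(predicted[[i]], truth[[i]])
    cbind(data.frame(id = ids[i], TP = cc$TP, TN = cc$TN, FP = cc$FP,
                     FN = cc$FN),
          eq7_metrics(cc))
  })
  do.call(rbind, rows)
}
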