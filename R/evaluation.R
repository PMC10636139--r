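#' Dice similarity coefficient between two binary masks
#'
#' \eqn{2|X \cap Y| / (|X| + |Y|)} over foreground pixels. Any nonzero pixel
#' counts as foreground, so instance masks can be passed directly. Two empty
#' masks score 1 by convention.
#'
#' @param pred,truth Integer matrices of identical dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have identical dimensions")
  }
  p <- pred != 0L
  t <- truth != 0L
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1)
  2 * sum(p & t) / denom
}

#' Object-level detection matching between two instance masks
#'
#' Matches predicted objects to ground-truth objects one-to-one, greedily in
#' descending IoU order among pairs with IoU at or above the threshold, and
#' derives detection precision, recall and F1. At the default threshold of
#' 0.5 the greedy matching is provably optimal (two disjoint predictions
#' cannot both overlap one truth object with IoU >= 0.5).
#'
#' Degenerate denominators (no predictions, or no truth objects) report the
#' affected metric as 0 and set `degenerate = TRUE`.
#'
#' @param pred,truth Integer instance masks of identical dimensions.
#' @param iou_threshold Minimum IoU for a valid match, in (0, 1).
#' @return A list of class `match_result` with `tp`, `fp`, `fn`, `pairs`
#'   (data frame: `gt_label`, `pred_label`, `iou`), `precision`, `recall`,
#'   `f1`, `degenerate`.
#' @export
match_objects <- function(pred, truth, iou_threshold = 0.5) {
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have identical dimensions")
  }
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  pred <- ensure_int_matrix(pred); truth <- ensure_int_matrix(truth)
  n_pred <- n_objects(pred); n_truth <- n_objects(truth)
  pairs <- iou_pairs(pred, truth)
  pairs <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
  # deterministic greedy order: IoU desc, then labels
  pairs <- pairs[order(-pairs$iou, pairs$gt_label, pairs$pred_label), ,
                 drop = FALSE]
  used_gt <- logical(max(truth, 1L)); used_pr <- logical(max(pred, 1L))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g <- pairs$gt_label[k]; p <- pairs$pred_label[k]
    if (!used_gt[g] && !used_pr[p]) {
      keep[k] <- TRUE
      used_gt[g] <- TRUE
      used_pr[p] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  tp <- nrow(pairs)
  fp <- n_pred - tp
  fn <- n_truth - tp
  degenerate <- (tp + fp == 0L) || (tp + fn == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "match_result")
}

# All (gt, pred) label pairs with nonzero pixel overlap and their IoU.
iou_pairs <- function(pred, truth) {
  both <- which(pred > 0L & truth > 0L)
  area_p <- tabulate(pred[pred > 0L])
  area_t <- tabulate(truth[truth > 0L])
  if (length(both) == 0L) {
    return(data.frame(gt_label = integer(0), pred_label = integer(0),
                      iou = numeric(0)))
  }
  key_p <- pred[both]
  key_t <- truth[both]
  kmax <- max(key_p) + 1L
  key <- as.numeric(key_t) * kmax + key_p
  inter <- table(key)
  key_u <- as.numeric(names(inter))
  gt <- floor(key_u / kmax)
  pr <- key_u - gt * kmax
  inter <- as.vector(inter)
  iou <- inter / (area_t[gt] + area_p[pr] - inter)
  data.frame(gt_label = as.integer(gt), pred_label = as.integer(pr),
             iou = iou)
}

#' Confusion matrix and accuracy for image classifications
#'
#' Cross-tabulates consensus (truth) labels against predicted labels over a
#' fixed, ordered class list and reports overall accuracy (trace / total).
#' Rows are truth, columns are prediction.
#'
#' @param truth_labels,pred_labels Equal-length character vectors.
#' @param classes Ordered class list; every label must be one of these.
#' @return A list of class `confusion_matrix` with `classes`, `counts`
#'   (square integer matrix) and `accuracy`.
#' @export
confusion_and_accuracy <- function(truth_labels, pred_labels,
                                   classes = size_class_levels) {
  if (length(truth_labels) != length(pred_labels)) {
    stop("truth and prediction label lists must have equal length")
  }
  bad <- setdiff(unique(c(truth_labels, pred_labels)), classes)
  if (length(bad) > 0) {
    stop("labels outside the class list: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(truth_labels, levels = classes),
                  factor(pred_labels, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  total <- sum(counts)
  structure(list(classes = classes, counts = counts,
                 accuracy = if (total > 0) sum(diag(counts)) / total else NA_real_),
            class = "confusion_matrix")
}

#' Accuracy of a confusion matrix given as counts
#'
#' Convenience for published result tables: takes a square matrix of counts
#' (rows = truth, columns = prediction) and returns trace / total.
#'
#' @param counts Square numeric matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
confusion_accuracy <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  sum(diag(counts)) / sum(counts)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted)\n")
  print(x$counts)
  cat(sprintf("accuracy: %.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Load one of the shipped benchmark confusion matrices
#'
#' The package ships the published image-level confusion matrices of the
#' canine and feline lymphoma test sets (two segmentation backends and three
#' expert raters per species) under `inst/extdata/confusion/`, so that the
#' reported accuracies can be recomputed with [confusion_accuracy()].
#'
#' @param name Table name, e.g. `"canine_unetpp"`, `"feline_stardist"`,
#'   `"canine_expert_2"`.
#' @return A 3x3 integer matrix (rows = consensus truth, columns = predicted).
#' @export
load_confusion_table <- function(name) {
  path <- system.file("extdata", "confusion", paste0(name, ".csv"),
                      package = "nucmorph")
  if (path == "") stop("unknown confusion table: ", name)
  m <- as.matrix(utils::read.csv(path))
  dimnames(m) <- list(truth = colnames(m), predicted = colnames(m))
  m
}
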