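#' Threshold search grid
#'
#' Per-parameter (lower, upper, step) ranges for the brute-force search over
#' classification thresholds. The defaults are the ranges used to derive the
#' optimized thresholds: small_lower 1.00-1.29, small_upper 1.18-1.24,
#' intermediate_upper 1.35-1.51, large_upper 2.00-2.59, all in steps of 0.01
#' (multipliers of the reference diameter).
#'
#' @param small_lower,small_upper,intermediate_upper,large_upper Numeric
#'   vectors `c(lower, upper, step)`; `step` defaults to 0.01 when omitted.
#' @return A list of class `threshold_grid`.
#' @export
threshold_grid <- function(small_lower = c(1.00, 1.29, 0.01),
                           small_upper = c(1.18, 1.24, 0.01),
                           intermediate_upper = c(1.35, 1.51, 0.01),
                           large_upper = c(2.00, 2.59, 0.01)) {
  fix <- function(r) {
    if (length(r) == 2L) r <- c(r, 0.01)
    stopifnot(length(r) == 3L, r[3] > 0, r[1] <= r[2])
    r
  }
  structure(list(small_lower = fix(small_lower), small_upper = fix(small_upper),
                 intermediate_upper = fix(intermediate_upper),
                 large_upper = fix(large_upper)),
            class = "threshold_grid")
}

grid_values <- function(range3) {
  # smallest number of decimals that represents the step exactly
  digits <- 0L
  while (digits < 10L &&
         abs(range3[3] * 10^digits - round(range3[3] * 10^digits)) > 1e-9) {
    digits <- digits + 1L
  }
  round(seq(range3[1], range3[2] + range3[3] / 2, by = range3[3]), digits)
}

#' Enumerate candidate threshold sets from a grid
#'
#' Takes the Cartesian product of the four discretized parameter ranges and
#' keeps the candidates that are valid threshold sets, i.e. strictly ordered
#' `small_lower < small_upper < intermediate_upper < large_upper`. Values are
#' materialized as exact decimals at the step's precision so boundary
#' comparisons are reproducible across platforms. Rows are in lexicographic
#' order of the four parameters.
#'
#' @param grid A [threshold_grid()].
#' @return A data frame with columns `small_lower`, `small_upper`,
#'   `intermediate_upper`, `large_upper`, one row per candidate.
#' @export
enumerate_candidates <- function(grid) {
  stopifnot(inherits(grid, "threshold_grid"))
  v <- lapply(grid, grid_values)
  cand <- expand.grid(large_upper = v$large_upper,
                      intermediate_upper = v$intermediate_upper,
                      small_upper = v$small_upper,
                      small_lower = v$small_lower,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; reversing the column order
  # above and back here yields lexicographic order in the natural ordering
  cand <- cand[, c("small_lower", "small_upper", "intermediate_upper",
                   "large_upper")]
  keep <- cand$small_lower < cand$small_upper &
    cand$small_upper < cand$intermediate_upper &
    cand$intermediate_upper < cand$large_upper
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("empty candidate set: no strictly ordered threshold combination ",
         "exists in the grid")
  }
  rownames(cand) <- NULL
  cand
}

#' Labeled per-image diameter measurements
#'
#' Bundles per-nucleus diameter measurements with one expert consensus label
#' per image, the input of the threshold optimization.
#'
#' @param measurements Data frame with columns `image_id` and `diameter_um`.
#' @param labels Data frame with columns `image_id` and `consensus_label`
#'   (values in small/intermediate/large), one row per image.
#' @param reference A [reference_size()] the ratios are computed against.
#' @return A list of class `measurement_set` with `diameters` (list of
#'   numeric vectors, one per image), `labels` (named character vector), and
#'   `reference`.
#' @export
measurement_set <- function(measurements, labels,
                            reference = reference_size("dog")) {
  stopifnot(all(c("image_id", "diameter_um") %in% names(measurements)),
            all(c("image_id", "consensus_label") %in% names(labels)),
            inherits(reference, "reference_size"))
  if (anyDuplicated(labels$image_id)) stop("duplicate image_id in labels")
  if (!all(labels$consensus_label %in% size_class_levels)) {
    stop("consensus_label values must be small/intermediate/large")
  }
  ids <- as.character(labels$image_id)
  if (!all(as.character(measurements$image_id) %in% ids)) {
    stop("measurements contain image_id values without a label")
  }
  diam <- split(measurements$diameter_um, as.character(measurements$image_id))
  diam <- diam[ids]
  if (any(vapply(diam, length, integer(1)) == 0L) || anyNA(names(diam))) {
    stop("every labeled image needs at least one measurement")
  }
  lab <- stats::setNames(as.character(labels$consensus_label), ids)
  structure(list(diameters = diam, labels = lab, reference = reference),
            class = "measurement_set")
}

# Per-image majority prediction for a single threshold set; "unclassifiable"
# when no nucleus falls in the classifiable range.
predict_images <- function(thresholds, data) {
  vapply(seq_along(data$diameters), function(i) {
    cls <- classify_nucleus(data$diameters[[i]], data$reference, thresholds)
    tryCatch(classify_image(cls)$majority_class,
             error = function(e) "unclassifiable")
  }, character(1))
}

#' Score one threshold set by macro F1 of image majority classes
#'
#' Every measured diameter is classified with [classify_nucleus()], each
#' image takes the majority class of its nuclei (ties toward the larger
#' class), and the predictions are compared with the consensus labels by
#' macro-averaged F1 over the three classes. Images whose nuclei all fall
#' outside the classifiable range predict "unclassifiable", which counts
#' against recall of their true class.
#'
#' @param thresholds A [size_thresholds()].
#' @param data A [measurement_set()].
#' @return Macro F1 in `[0, 1]`.
#' @export
score_candidate <- function(thresholds, data) {
  stopifnot(inherits(data, "measurement_set"))
  pred <- predict_images(thresholds, data)
  macro_f1(unname(data$labels), pred, size_class_levels)
}

# Macro F1 over `classes`; predictions outside `classes` count as wrong.
macro_f1 <- function(truth, pred, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  }, numeric(1))
  mean(f1)
}

#' Brute-force threshold optimization
#'
#' Exhaustively scores every candidate of the grid with [score_candidate()]'s
#' scoring rule and returns the best. The search is vectorized: per-image
#' counts of ratios below each grid value are precomputed once, so each
#' candidate's class counts are two subtractions per class. Results are
#' identical to scoring candidates one by one (this is asserted in the test
#' suite) and deterministic: among equally scoring candidates the first in
#' enumeration order is returned and all ties are listed.
#'
#' @param grid A [threshold_grid()].
#' @param data A [measurement_set()].
#' @return A list of class `optimization_result` with `best_thresholds`
#'   (a [size_thresholds()]), `best_f1`, `n_candidates_evaluated`, and
#'   `ties` (data frame of all candidates attaining `best_f1`).
#' @export
optimize_thresholds <- function(grid, data) {
  stopifnot(inherits(grid, "threshold_grid"), inherits(data, "measurement_set"))
  cand <- enumerate_candidates(grid)
  nc <- nrow(cand)
  vals <- sort(unique(unlist(cand, use.names = FALSE)))
  ia <- match(cand$small_lower, vals)
  ib <- match(cand$small_upper, vals)
  ic <- match(cand$intermediate_upper, vals)
  id <- match(cand$large_upper, vals)

  n_img <- length(data$diameters)
  truth <- unname(data$labels)
  ref <- data$reference$reference_diameter_um
  # per-candidate true/false-positive/negative accumulators per class
  tp <- matrix(0L, nc, 3L); fp <- matrix(0L, nc, 3L); fn <- matrix(0L, nc, 3L)
  for (i in seq_len(n_img)) {
    rho <- data$diameters[[i]] / ref
    below <- vapply(vals, function(v) sum(rho < v), integer(1))
    below_eq <- vapply(vals, function(v) sum(rho <= v), integer(1))
    n_small <- below[ib] - below[ia]
    n_inter <- below[ic] - below[ib]
    n_large <- below_eq[id] - below[ic]
    # majority with ties toward the larger class; 0 = unclassifiable
    pred <- integer(nc)
    pred[n_small > 0L | n_inter > 0L | n_large > 0L] <- 1L
    pred[n_inter >= n_small & pred > 0L] <- 2L
    pred[n_large >= n_inter & n_large >= n_small & pred > 0L] <- 3L
    t_i <- match(truth[i], size_class_levels)
    for (cl in 1:3) {
      hits <- pred == cl
      if (cl == t_i) {
        tp[, cl] <- tp[, cl] + hits
        fn[, cl] <- fn[, cl] + !hits
      } else {
        fp[, cl] <- fp[, cl] + hits
      }
    }
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  score <- rowMeans(f1)
  best <- which.max(score)
  ties <- cand[score == score[best], , drop = FALSE]
  rownames(ties) <- NULL
  structure(list(
    best_thresholds = size_thresholds(cand$small_lower[best],
                                      cand$small_upper[best],
                                      cand$intermediate_upper[best],
                                      cand$large_upper[best]),
    best_f1 = score[best],
    n_candidates_evaluated = nc,
    ties = ties
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  b <- x$best_thresholds
  cat("Threshold optimization result\n")
  cat(sprintf("  candidates evaluated: %d\n", x$n_candidates_evaluated))
  cat(sprintf("  best macro F1:        %.4f\n", x$best_f1))
  cat(sprintf("  best thresholds:      %.2f / %.2f / %.2f / %.2f\n",
              b$small_lower, b$small_upper, b$intermediate_upper,
              b$large_upper))
  if (nrow(x$ties) > 1L) {
    cat(sprintf("  ties at best score:   %d\n", nrow(x$ties)))
  }
  invisible(x)
}
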