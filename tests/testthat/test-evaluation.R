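test_that("dice score follows its closed form and conventions", {
  a <- matrix(0L, 10, 20); a[4:6, 3:12] <- 1L
  expect_equal(dice_score(a, a), 1)
  b <- matrix(0L, 10, 20); b[8:9, 15:18] <- 1L
  expect_equal(dice_score(a, b), 0)
  # pred = left half of a 100-pixel strip
  strip <- matrix(0L, 5, 110); strip[3, 6:105] <- 1L
  half <- matrix(0L, 5, 110); half[3, 6:55] <- 1L
  expect_equal(dice_score(half, strip), 2 * 50 / (50 + 100))
  expect_equal(dice_score(half, strip), dice_score(strip, half))
  expect_equal(dice_score(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice_score(a, matrix(0L, 3, 3)), "dimensions")
})

test_that("object matching counts detections one-to-one", {
  scene <- small_scene(seed = 41, n = 20L)
  m <- scene$mask
  expect_equal(match_objects(m, m)$f1, 1)
  expect_identical(match_objects(m, m)$tp, 20L)
  # empty prediction: degenerate metrics reported as zero
  none <- match_objects(matrix(0L, nrow(m), ncol(m)), m)
  expect_identical(none$fn, 20L)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)
  expect_true(none$degenerate)
  # delete 4 objects, add 2 spurious blobs
  pred <- m
  pred[pred %in% 1:4] <- 0L
  pred[2:4, 2:4] <- 98L
  pred[2:4, 8:10] <- 99L
  pred <- nucmorph:::relabel_contiguous(pred)
  res <- match_objects(pred, m)
  expect_identical(res$tp, 16L)
  expect_identical(res$fn, 4L)
  expect_identical(res$fp, 2L)
  expect_equal(res$f1, 2 * 16 / (2 * 16 + 2 + 4))
  # metrics are invariant to label permutation of either mask
  perm <- sample(20)
  m_perm <- m; m_perm[m > 0L] <- perm[m[m > 0L]]
  expect_equal(match_objects(pred, m_perm)$f1, res$f1)
})

test_that("greedy matching equals exhaustive optimal assignment", {
  set.seed(99)
  for (trial in 1:12) {
    # <= 8 truth objects, jittered/corrupted predictions
    truth <- matrix(0L, 60, 60)
    n_t <- sample(4:8, 1)
    grid_pts <- as.matrix(expand.grid(seq(8, 52, by = 11), seq(8, 52, by = 11)))
    centers <- grid_pts[sample(nrow(grid_pts), n_t), , drop = FALSE]
    for (k in seq_len(n_t)) {
      truth[centers[k, 1] + (-3:3), centers[k, 2] + (-3:3)] <- k
    }
    pred <- matrix(0L, 60, 60)
    for (k in seq_len(n_t)) {
      if (runif(1) < 0.2) next  # missed detection
      dr <- sample(-3:3, 1); dc <- sample(-3:3, 1)
      rr <- pmin(pmax(centers[k, 1] + dr + (-3:3), 1), 60)
      cc <- pmin(pmax(centers[k, 2] + dc + (-3:3), 1), 60)
      pred[rr, cc] <- k
    }
    pred <- nucmorph:::relabel_contiguous(pred)
    for (thr in c(0.3, 0.5)) {
      res <- match_objects(pred, truth, thr)
      oracle <- oracle_best_matching(nucmorph:::iou_pairs(pred, truth),
                                     n_objects(truth), n_objects(pred), thr)
      expect_identical(res$tp, oracle$tp)
    }
  }
})

test_that("confusion matrices and accuracy follow the count definitions", {
  truth <- c("small", "small", "intermediate", "large", "large")
  pred <- c("small", "intermediate", "intermediate", "large", "small")
  cm <- confusion_and_accuracy(truth, pred)
  expect_identical(sum(cm$counts), 5L)
  expect_identical(cm$counts["small", "intermediate"], 1L)
  expect_equal(cm$accuracy, 3 / 5)
  # identity predictions give a diagonal matrix and accuracy 1
  cid <- confusion_and_accuracy(truth, truth)
  expect_equal(cid$accuracy, 1)
  expect_identical(sum(cid$counts) - sum(diag(cid$counts)), 0L)
  expect_error(confusion_and_accuracy(truth, c(pred[-5], "huge")), "class list")
  expect_error(confusion_and_accuracy(truth, pred[-1]), "equal length")
  # accuracy equals the prevalence-weighted mean of per-class recalls
  set.seed(6)
  t2 <- sample(c("small", "intermediate", "large"), 60, replace = TRUE)
  p2 <- sample(c("small", "intermediate", "large"), 60, replace = TRUE)
  cm2 <- confusion_and_accuracy(t2, p2)
  recalls <- diag(cm2$counts) / rowSums(cm2$counts)
  prevalence <- rowSums(cm2$counts) / sum(cm2$counts)
  expect_equal(cm2$accuracy, sum(recalls * prevalence, na.rm = TRUE))
})

test_that("the shipped benchmark tables load as 3x3 count matrices", {
  m <- load_confusion_table("canine_unetpp")
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(sum(m), 25L)
  expect_error(load_confusion_table("no_such_table"), "unknown")
})
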