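# Shape rasterizers and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's internal code paths.

raster_disk <- function(radius, pad = 6L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    sel <- (i - ctr)^2 + (seq_len(n) - ctr)^2 <= radius^2
    m[i, sel] <- 1L
  }
  m
}

raster_square <- function(side, pad = 5L) {
  n <- side + 2L * pad
  m <- matrix(0L, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- 1L
  m
}

# Connected random blob grown by accretion from a seed pixel (4-connected
# growth keeps it valid under any labeling convention).
random_blob <- function(n_px, size = 40L) {
  m <- matrix(0L, size, size)
  ctr <- as.integer(size / 2)
  m[ctr, ctr] <- 1L
  frontier <- matrix(c(ctr, ctr), ncol = 2)
  while (sum(m) < n_px) {
    fg <- which(m == 1L, arr.ind = TRUE)
    k <- fg[sample(nrow(fg), 1L), ]
    step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample(4L, 1L), ]
    p <- k + step
    if (all(p >= 2L) && all(p <= size - 1L)) m[p[1], p[2]] <- 1L
  }
  m
}

# Border pixels by the 4-neighbor definition, computed with explicit loops.
oracle_border <- function(mask, label = 1L) {
  fg <- which(mask == label, arr.ind = TRUE)
  is_b <- vapply(seq_len(nrow(fg)), function(k) {
    i <- fg[k, 1]; j <- fg[k, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) ||
          mask[ii, jj] != label) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  fg[is_b, , drop = FALSE]
}

# Exhaustive O(n^2) maximum pairwise distance.
oracle_max_dist <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(0)
  best <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# Independent macro F1 from an explicit per-class confusion computation.
oracle_macro_f1 <- function(truth, pred, classes) {
  per_class <- sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  })
  mean(per_class)
}

# Exhaustive optimal one-to-one assignment between gt and pred objects:
# maximizes the number of matched pairs with IoU >= threshold, breaking
# count ties by total IoU. Feasible for <= 8 objects.
oracle_best_matching <- function(iou_df, n_gt, n_pred, thr) {
  iou_df <- iou_df[iou_df$iou >= thr, , drop = FALSE]
  best <- list(tp = 0L, total = 0)
  recurse <- function(rows, used_pred, tp, total) {
    if (tp > best$tp || (tp == best$tp && total > best$total)) {
      best <<- list(tp = tp, total = total)
    }
    if (length(rows) == 0L) return()
    r <- rows[1]
    recurse(rows[-1], used_pred, tp, total)  # skip this pair
    p <- iou_df$pred_label[r]
    if (!(p %in% used_pred)) {
      g <- iou_df$gt_label[r]
      remaining <- rows[-1]
      remaining <- remaining[iou_df$gt_label[remaining] != g]
      recurse(remaining, c(used_pred, p), tp + 1L, total + iou_df$iou[r])
    }
  }
  recurse(seq_len(nrow(iou_df)), integer(0), 0L, 0)
  best
}

# Nested-loop enumeration oracle for the threshold grid.
oracle_grid_count <- function(sl, su, iu, lu) {
  vals <- function(r) round(seq(r[1], r[2] + r[3] / 2, by = r[3]), 6)
  count <- 0L
  for (a in vals(sl)) for (b in vals(su)) {
    if (a >= b) next
    for (cc in vals(iu)) {
      if (b >= cc) next
      for (d in vals(lu)) if (cc < d) count <- count + 1L
    }
  }
  count
}

small_scene <- function(seed, n = 40L, mix = c(1/3, 1/3, 1/3),
                        merged = 0, size = 512L) {
  generate_scene(generator_config(
    image_size_px = c(size, size), n_objects = n,
    class_mix = stats::setNames(mix, c("small", "intermediate", "large")),
    merged_pair_fraction = merged, seed = seed))
}
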