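single_point_grid <- function(a, b, cc, d, step = 0.01) {
  threshold_grid(c(a, a, step), c(b, b, step), c(cc, cc, step), c(d, d, step))
}

test_that("candidate enumeration respects the strict ordering constraint", {
  g1 <- single_point_grid(1.0, 1.2, 1.4, 2.0)
  expect_identical(nrow(enumerate_candidates(g1)), 1L)
  # overlapping 7-value ranges for the two small limits: 7*6/2 ordered pairs
  g2 <- threshold_grid(c(1.18, 1.24, 0.01), c(1.18, 1.24, 0.01),
                       c(1.40, 1.40, 0.01), c(2.00, 2.00, 0.01))
  expect_identical(nrow(enumerate_candidates(g2)), 21L)
  # full default grid equals the nested-loop oracle
  cand <- enumerate_candidates(threshold_grid())
  expect_identical(nrow(cand),
                   oracle_grid_count(c(1.00, 1.29, 0.01), c(1.18, 1.24, 0.01),
                                     c(1.35, 1.51, 0.01), c(2.00, 2.59, 0.01)))
  expect_true(all(cand$small_lower < cand$small_upper &
                  cand$small_upper < cand$intermediate_upper &
                  cand$intermediate_upper < cand$large_upper))
  # lexicographic order and exact decimal materialization
  expect_false(is.unsorted(cand$small_lower))
  expect_identical(cand$small_lower, round(cand$small_lower, 2))
  expect_error(enumerate_candidates(
    threshold_grid(c(1.3, 1.3, 0.01), c(1.2, 1.2, 0.01),
                   c(1.4, 1.4, 0.01), c(2, 2, 0.01))), "empty")
})

perfect_set <- function(n_images = 9L, seed = 1L) {
  # every image's measurements strictly inside its labeled class band
  with_seed_ms <- generate_measurement_set(n_images = n_images, seed = seed,
                                           noise_sd_um = 0)
  with_seed_ms
}

test_that("scoring is exact on separable and degenerate data", {
  ref <- reference_size("dog")
  ms <- measurement_set(
    data.frame(image_id = rep(c("a", "b", "c"), each = 4),
               diameter_um = c(4.3, 4.4, 4.5, 4.6,      # small band
                               5.2, 5.3, 5.4, 5.5,      # intermediate band
                               7.0, 7.5, 8.0, 8.5) ),   # large band
    data.frame(image_id = c("a", "b", "c"),
               consensus_label = c("small", "intermediate", "large")), ref)
  expect_equal(score_candidate(size_thresholds(), ms), 1.0)
  # one image labeled small whose nuclei all classify large
  ms0 <- measurement_set(
    data.frame(image_id = "a", diameter_um = c(7, 7.5, 8)),
    data.frame(image_id = "a", consensus_label = "small"), ref)
  expect_equal(score_candidate(size_thresholds(), ms0), 0.0)
  # an image with no classifiable nucleus counts as wrong for its class
  ms_un <- measurement_set(
    data.frame(image_id = c("a", "b"), diameter_um = c(50, 4.3)),
    data.frame(image_id = c("a", "b"),
               consensus_label = c("large", "small")), ref)
  # macro F1: small perfect (1), intermediate absent (0), large unclassified (0)
  expect_equal(score_candidate(size_thresholds(), ms_un), 1 / 3)
})

test_that("macro F1 equals an independent confusion-based computation", {
  set.seed(33)
  ms <- generate_measurement_set(n_images = 30L, seed = 7, noise_sd_um = 0.3)
  # flip ~10% of labels to add disagreement
  labs <- ms$labels
  flip <- sample(length(labs), 3)
  labs[flip] <- c("large", "small", "intermediate")[
    match(labs[flip], c("small", "intermediate", "large"))]
  ms$labels <- labs
  for (th in list(size_thresholds(), boxplot_thresholds(),
                  size_thresholds(1.05, 1.2, 1.45, 2.1))) {
    pred <- vapply(seq_along(ms$diameters), function(i) {
      cls <- classify_nucleus(ms$diameters[[i]], ms$reference, th)
      counts <- table(factor(cls, levels = c("small", "intermediate", "large")))
      if (sum(counts) == 0) return("unclassifiable")
      names(counts)[max(which(counts == max(counts)))]
    }, character(1))
    expect_equal(score_candidate(th, ms),
                 oracle_macro_f1(unname(ms$labels), pred,
                                 c("small", "intermediate", "large")),
                 tolerance = 1e-12)
  }
})

test_that("the vectorized search agrees with one-by-one scoring", {
  ms <- generate_measurement_set(n_images = 20L, seed = 5, noise_sd_um = 0.25)
  grid <- threshold_grid(c(1.00, 1.06, 0.02), c(1.18, 1.24, 0.02),
                         c(1.35, 1.51, 0.04), c(2.0, 2.4, 0.1))
  cand <- enumerate_candidates(grid)
  res <- optimize_thresholds(grid, ms)
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    score_candidate(size_thresholds(cand$small_lower[i], cand$small_upper[i],
                                    cand$intermediate_upper[i],
                                    cand$large_upper[i]), ms)
  }, numeric(1))
  expect_equal(res$best_f1, max(scores), tolerance = 1e-12)
  best_first <- which(scores == max(scores))[1]
  expect_equal(unlist(res$best_thresholds, use.names = FALSE),
               unname(unlist(cand[best_first, ])))
  expect_identical(res$n_candidates_evaluated, nrow(cand))
  # the optimum dominates random grid members
  set.seed(12)
  for (i in sample(nrow(cand), 50)) {
    expect_gte(res$best_f1 + 1e-12, scores[i])
  }
})

test_that("optimization recovers generator band edges and is deterministic", {
  ms <- generate_measurement_set(n_images = 30L, seed = 11, noise_sd_um = 0)
  grid <- threshold_grid(c(0.98, 1.04, 0.01), c(1.18, 1.24, 0.01),
                         c(1.46, 1.51, 0.01), c(2.20, 2.30, 0.01))
  res <- optimize_thresholds(grid, ms)
  expect_equal(unlist(res$best_thresholds, use.names = FALSE),
               c(1.00, 1.21, 1.50, 2.24), tolerance = 1e-9)
  expect_equal(res$best_f1, 1.0)
  # single-candidate grid returns that candidate with its score
  g1 <- single_point_grid(1.0, 1.21, 1.5, 2.24)
  r1 <- optimize_thresholds(g1, ms)
  expect_equal(r1$best_f1, score_candidate(r1$best_thresholds, ms))
  # duplicating every image leaves the optimum unchanged
  meas2 <- do.call(rbind, lapply(c("x", "y"), function(suf) {
    data.frame(image_id = paste0(rep(names(ms$diameters),
                                     lengths(ms$diameters)), suf),
               diameter_um = unlist(ms$diameters, use.names = FALSE))
  }))
  labs2 <- data.frame(image_id = c(paste0(names(ms$labels), "x"),
                                   paste0(names(ms$labels), "y")),
                      consensus_label = unname(c(ms$labels, ms$labels)))
  res2 <- optimize_thresholds(grid, measurement_set(meas2, labs2, ms$reference))
  expect_identical(unlist(res2$best_thresholds),
                   unlist(res$best_thresholds))
  # determinism of repeated runs
  res3 <- optimize_thresholds(grid, ms)
  expect_identical(res3$best_f1, res$best_f1)
  expect_identical(res3$ties, res$ties)
})
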