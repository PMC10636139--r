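#' Object filter configuration
#'
#' Size and shape limits used to exclude invalid objects before nuclear-size
#' classification. Defaults: objects smaller than 1 micrometre squared are
#' removed (labeling artifacts), there is no upper area limit (oversized
#' nuclei are instead excluded downstream when their size ratio exceeds the
#' largest classification threshold), and objects must have circularity
#' strictly above 0.5 to count as plausibly elliptical nuclei rather than
#' merged or fragmented segments.
#'
#' @param min_area_um2 Lower area limit in micrometre squared (default 1).
#' @param max_area_um2 Optional upper area limit; `Inf` disables it.
#' @param circularity_threshold Keep objects with circularity strictly above
#'   this value; must lie in (0, 1). Default 0.5.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_area_um2 = 1, max_area_um2 = Inf,
                          circularity_threshold = 0.5) {
  stopifnot(min_area_um2 >= 0, max_area_um2 > min_area_um2,
            circularity_threshold > 0, circularity_threshold < 1)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 circularity_threshold = circularity_threshold),
            class = "filter_config")
}

#' Filter invalid objects by size and shape
#'
#' Applies the checks in a fixed order — too small, too large, then
#' non-elliptical (circularity) — so every excluded object gets a single
#' deterministic reason. An object is kept iff it passes all checks.
#'
#' @param features Data frame from [compute_features()].
#' @param config A [filter_config()].
#' @return A list of class `filter_result` with elements `kept` (integer
#'   labels), `excluded` (data frame of `label`, `reason` in
#'   `too_small` / `too_large` / `non_elliptical`), and `dropout_rate`
#'   (excluded / total; 0 for empty input).
#' @export
filter_objects <- function(features, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(features)
  reason <- rep(NA_character_, n)
  too_small <- features$area_um2 < config$min_area_um2
  too_large <- features$area_um2 > config$max_area_um2
  non_ellip <- features$circularity <= config$circularity_threshold
  reason[non_ellip] <- "non_elliptical"
  reason[too_large] <- "too_large"
  reason[too_small] <- "too_small"   # size reasons take precedence over shape
  excl <- !is.na(reason)
  structure(list(
    kept = features$label[!excl],
    excluded = data.frame(label = features$label[excl],
                          reason = reason[excl], row.names = NULL),
    dropout_rate = if (n > 0) sum(excl) / n else 0
  ), class = "filter_result")
}
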