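#' Per-nucleus geometric features
#'
#' Measures every labeled object of an instance mask. For each object the
#' following are computed:
#'
#' * `area_px`, `area_um2`: pixel count \eqn{A} and physical area
#'   \eqn{A \cdot s^2} for pixel size \eqn{s} (micrometre per pixel).
#' * `hull_area_px`: number of pixels whose centers lie inside or on the
#'   convex hull of the object's pixel centers.
#' * `max_border_distance_px`: maximum Euclidean distance \eqn{F} between
#'   centers of border pixels (a border pixel has at least one 4-neighbor
#'   outside the object).
#' * `solidity_ratio`: \eqn{r_1 = A / A_{hull}}, the convex-hull solidity.
#' * `circle_ratio`: \eqn{r_2 = A / (\pi (F/2)^2)}, area relative to the
#'   circle whose diameter is the maximum border-pixel distance. Single-pixel
#'   objects (where \eqn{F = 0}) get `circle_ratio = 1` by convention; they
#'   never survive the minimum-area filter.
#' * `circularity`: the arithmetic mean \eqn{(r_1 + r_2)/2}. A perfect circle
#'   scores 1 in both ratios; merged or ragged objects score lower.
#' * `equivalent_diameter_um`: diameter of the circle of equal area,
#'   \eqn{d = 2\sqrt{A/\pi}\, s}, the size measure used for classification.
#' * `centroid_row`, `centroid_col`: pixel-center centroid, 0-based.
#'
#' `circle_ratio` may marginally exceed 1 on coarse rasters; it is reported
#' as computed, not clamped.
#'
#' @param mask Integer instance mask (labels `1..n`, background 0). A binary
#'   mask is accepted and labeled first.
#' @param um_per_pixel Pixel resolution in micrometre per pixel (default 0.25).
#' @return A data frame with one row per label, in ascending label order,
#'   with the columns listed above plus `label`.
#' @export
compute_features <- function(mask, um_per_pixel = 0.25) {
  stopifnot(is.matrix(mask), um_per_pixel > 0)
  mask <- ensure_int_matrix(mask)
  labs_all <- sort(unique(as.vector(mask)))
  labs_all <- labs_all[labs_all > 0L]
  if (length(labs_all) == 0L) {
    return(empty_features())
  }
  if (!identical(labs_all, seq_along(labs_all))) {
    stop("instance mask labels must be contiguous 1..n; use read_mask() or ",
         "label_connected_components()")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0L)
  lab <- mask[fg]
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  # border detection in one pass: any 4-neighbor with a different value
  # (other objects and the image edge both count as outside)
  p <- matrix(-1L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
  is_border <- ctr > 0L & (
    p[1:nr, 2:(nc + 1L)] != ctr | p[3:(nr + 2L), 2:(nc + 1L)] != ctr |
    p[2:(nr + 1L), 1:nc] != ctr | p[2:(nr + 1L), 3:(nc + 2L)] != ctr)
  border_flag <- is_border[fg]

  n <- length(labs_all)
  s <- um_per_pixel
  area_px <- tabulate(lab, nbins = n)
  centroid_row <- rowsum(as.numeric(rows), lab)[, 1] / area_px - 1
  centroid_col <- rowsum(as.numeric(cols), lab)[, 1] / area_px - 1

  ord <- order(lab)
  coords_by <- split_coords(rows[ord], cols[ord], lab[ord], n)
  bord <- border_flag[ord]
  hull_area <- numeric(n)
  fmax <- numeric(n)
  off <- 0L
  for (k in seq_len(n)) {
    nk <- area_px[k]
    idx <- (off + 1L):(off + nk)
    pr <- coords_by$row[idx]; pc <- coords_by$col[idx]
    hull_area[k] <- hull_pixel_count(pr, pc)
    bsel <- bord[idx]
    fmax[k] <- max_pairwise_distance(pr[bsel], pc[bsel])
    off <- off + nk
  }
  solidity <- area_px / hull_area
  circle_ratio <- ifelse(fmax > 0, area_px / (pi * (fmax / 2)^2), 1)
  data.frame(
    label = seq_len(n),
    area_px = area_px,
    area_um2 = area_px * s^2,
    hull_area_px = hull_area,
    max_border_distance_px = fmax,
    solidity_ratio = solidity,
    circle_ratio = circle_ratio,
    circularity = (solidity + circle_ratio) / 2,
    equivalent_diameter_um = 2 * sqrt(area_px / pi) * s,
    centroid_row = centroid_row,
    centroid_col = centroid_col,
    row.names = NULL
  )
}

empty_features <- function() {
  data.frame(label = integer(0), area_px = integer(0), area_um2 = numeric(0),
             hull_area_px = numeric(0), max_border_distance_px = numeric(0),
             solidity_ratio = numeric(0), circle_ratio = numeric(0),
             circularity = numeric(0), equivalent_diameter_um = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0))
}

# Pack per-label coordinates contiguously (input already ordered by label).
split_coords <- function(rows, cols, lab, n) {
  list(row = rows, col = cols)
}

#' Maximum border-pixel distance of one object
#'
#' Maximum Euclidean distance between the centers of an object's border
#' pixels. Border pixels are object pixels with at least one non-object
#' 4-neighbor; for convenience this function accepts any pixel set and
#' computes the maximum pairwise distance of the given centers (the caller
#' selects the border). Returns 0 for a single pixel.
#'
#' The maximum pairwise distance is attained between convex-hull vertices,
#' so the hull is taken first and only hull vertex pairs are compared.
#'
#' @param rows,cols Integer pixel coordinates (same length).
#' @return Maximum pairwise Euclidean distance in pixel units.
#' @export
max_border_distance <- function(rows, cols) {
  max_pairwise_distance(rows, cols)
}

max_pairwise_distance <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1L) return(0)
  if (n > 3L) {
    h <- grDevices::chull(cols, rows)
    rows <- rows[h]; cols <- cols[h]
    n <- length(rows)
    if (n == 1L) return(0)  # all points identical
  }
  d2 <- outer(rows, rows, "-")^2 + outer(cols, cols, "-")^2
  sqrt(max(d2))
}

# Exact count of lattice points (pixel centers) inside or on the convex hull
# of the given integer points, via Pick's theorem: I + B = A + B/2 + 1.
# Degenerate (collinear) hulls fall back to lattice points on the segment.
hull_pixel_count <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(1)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) == 1L) return(1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hv <- pts[h, , drop = FALSE]
  m <- nrow(hv)
  nxt <- c(2:m, 1L)[seq_len(m)]
  if (m == 1L) return(1)
  x <- hv[, 2]; y <- hv[, 1]
  if (m == 2L) {
    return(gcd_int(abs(y[2] - y[1]), abs(x[2] - x[1])) + 1)
  }
  area2 <- abs(sum(x * y[nxt] - x[nxt] * y))          # twice shoelace area
  if (area2 == 0) {  # collinear despite >2 hull points
    dr <- max(rows) - min(rows); dc <- max(cols) - min(cols)
    return(gcd_int(dr, dc) + 1)
  }
  b <- sum(mapply(gcd_int, abs(y[nxt] - y), abs(x[nxt] - x)))
  area2 / 2 + b / 2 + 1
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  if (a == 0L) 1L else a
}

#' Write a per-object feature table to CSV
#'
#' @param features Data frame from [compute_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
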