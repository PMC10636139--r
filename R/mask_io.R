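#' Read a segmentation mask from a PNG or TIFF file
#'
#' Reads a single-channel raster and returns it as an integer matrix. In
#' `"binary"` mode any nonzero pixel becomes 1; in `"instance"` mode the
#' nonzero values are relabeled to the contiguous set `1..n` (preserving the
#' order of the original values), so the result is a valid instance mask
#' whatever label values the file happened to store.
#'
#' Multi-channel rasters are accepted only when all channels are identical
#' (a grayscale image saved as RGB); otherwise an error is raised.
#'
#' @param path Path to a PNG or TIFF file.
#' @param mode `"binary"` or `"instance"`.
#' @return An integer matrix; 0 is background. In binary mode values are
#'   exactly 0/1; in instance mode labels are `1..n_objects`.
#' @seealso [write_mask()], [label_connected_components()]
#' @export
read_mask <- function(path, mode = c("instance", "binary")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    x <- round(x * (2^depth - 1))
  } else {
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  }
  if (length(dim(x)) == 3L) {
    ch <- dim(x)[3]
    for (k in seq_len(ch - 1L)) {
      if (!isTRUE(all.equal(x[, , k], x[, , k + 1L]))) {
        stop("multi-channel image with differing channels cannot be ",
             "interpreted as a mask: ", path)
      }
    }
    x <- x[, , 1L]
  }
  m <- matrix(as.integer(round(x)), nrow = nrow(x), ncol = ncol(x))
  if (mode == "binary") {
    m[m != 0L] <- 1L
    m
  } else {
    relabel_contiguous(m)
  }
}

#' Write a mask to a PNG or TIFF file
#'
#' Writes an integer mask losslessly. Bit depth is chosen from the label
#' range: 8-bit when the maximum value is at most 255, 16-bit otherwise.
#' 16-bit output requires TIFF (the PNG writer used here is 8-bit only);
#' asking for a `.png` with more than 255 labels is an error.
#'
#' @param mask Integer matrix (binary or instance mask).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  mask <- ensure_int_matrix(mask)
  if (any(mask < 0L)) stop("mask values must be non-negative")
  mx <- max(mask, 0L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (mx > 255L) {
      stop("mask has ", mx, " > 255 labels; PNG output here is 8-bit, ",
           "use a .tif path instead")
    }
    png::writePNG(mask / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    bits <- if (mx > 255L) 16L else 8L
    if (mx > 65535L) stop("mask has more than 65535 labels")
    tiff::writeTIFF(mask / (2^bits - 1), path, bits.per.sample = bits,
                    compression = "none")
  } else {
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  }
  invisible(path)
}

#' Label connected components of a binary mask
#'
#' Assigns a unique positive integer to every maximal 8-connected foreground
#' region of a binary mask, so that each nucleus can be measured and
#' classified individually. Labels are issued in raster-scan order (row-major)
#' of each component's first pixel, which makes the labeling deterministic.
#'
#' The implementation is a run-length two-pass algorithm: foreground runs are
#' extracted per row, runs in adjacent rows are merged with union-find when
#' their column ranges touch or overlap (including diagonally, giving
#' 8-connectivity), and components are then relabeled in raster order.
#'
#' @param mask Integer matrix; any nonzero pixel is foreground.
#' @return Integer matrix of the same shape with labels `0..n_objects`.
#' @export
label_connected_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- ensure_int_matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  # per-row foreground runs
  row_l <- vector("list", nr)
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ] != 0L)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    row_l[[i]] <- cbind(row = i, s = starts[keep], e = ends[keep])
  }
  runs <- do.call(rbind, row_l)
  if (is.null(runs)) return(matrix(0L, nr, nc))
  n_runs <- nrow(runs)
  parent <- seq_len(n_runs)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  # run index ranges per row (runs are already sorted by row, then column)
  first_of_row <- match(seq_len(nr), runs[, "row"])
  counts <- tabulate(runs[, "row"], nbins = nr)
  for (i in 2:max(2L, nr)) {
    if (nr < 2L) break
    if (counts[i] == 0L || counts[i - 1L] == 0L) next
    a <- first_of_row[i]; na <- counts[i]        # current row runs
    b <- first_of_row[i - 1L]; nb <- counts[i - 1L]  # previous row runs
    ai <- 0L; bi <- 0L
    while (ai < na && bi < nb) {
      ra <- a + ai; rb <- b + bi
      # 8-connectivity: ranges extended by one column must overlap
      if (runs[ra, "s"] <= runs[rb, "e"] + 1L &&
          runs[ra, "e"] >= runs[rb, "s"] - 1L) {
        fa <- find(ra); fb <- find(rb)
        if (fa != fb) parent[max(fa, fb)] <- min(fa, fb)
      }
      # advance the run that ends first (keep the other for more overlaps)
      if (runs[ra, "e"] < runs[rb, "e"]) ai <- ai + 1L else bi <- bi + 1L
    }
  }
  root <- vapply(seq_len(n_runs), find, integer(1))
  # order components by raster position of their first pixel
  comp_ids <- unique(root)
  first_pos <- vapply(comp_ids, function(cid) {
    sel <- which(root == cid)[1L]  # runs sorted in raster order already
    (runs[sel, "row"] - 1L) * nc + runs[sel, "s"]
  }, integer(1))
  comp_lab <- integer(max(comp_ids))
  comp_lab[comp_ids[order(first_pos)]] <- seq_along(comp_ids)
  out <- matrix(0L, nr, nc)
  lab_per_run <- comp_lab[root]
  for (k in seq_len(n_runs)) {
    out[runs[k, "row"], runs[k, "s"]:runs[k, "e"]] <- lab_per_run[k]
  }
  out
}

#' Number of objects in an instance mask
#'
#' @param mask Integer instance mask with contiguous labels `1..n`.
#' @return Integer count of distinct nonzero labels.
#' @export
n_objects <- function(mask) {
  u <- unique(as.vector(mask))
  length(u[u > 0L])
}

# Relabel nonzero values to the contiguous set 1..n (sorted by original value).
relabel_contiguous <- function(mask) {
  vals <- sort(unique(as.vector(mask)))
  vals <- vals[vals > 0L]
  if (length(vals) == 0L) return(mask)
  lut <- integer(max(vals))
  lut[vals] <- seq_along(vals)
  pos <- mask > 0L
  mask[pos] <- lut[mask[pos]]
  mask
}

ensure_int_matrix <- function(mask) {
  if (!is.integer(mask)) {
    storage.mode(mask) <- "integer"
  }
  mask
}
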