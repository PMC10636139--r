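#' Overlay rendering specification
#'
#' Colors follow the workflow's fixed scheme: small nuclei red, intermediate
#' yellow, large white; in the kept-vs-filtered panel kept objects are white
#' and filtered objects red.
#'
#' @param colors Named list of RGB triplets in `[0, 1]` for `small`,
#'   `intermediate`, `large`, `excluded_size`, `filtered`, `kept`.
#' @param opacity Blending weight of the object color over the background
#'   image in fill mode, in `(0, 1]`.
#' @param mode `"fill"` or `"outline"`.
#' @return A list of class `overlay_spec`.
#' @export
overlay_spec <- function(colors = list(small = c(1, 0, 0),
                                       intermediate = c(1, 1, 0),
                                       large = c(1, 1, 1),
                                       excluded_size = c(0.4, 0.4, 0.4),
                                       filtered = c(1, 0, 0),
                                       kept = c(1, 1, 1)),
                         opacity = 0.6, mode = c("fill", "outline")) {
  mode <- match.arg(mode)
  stopifnot(opacity > 0, opacity <= 1)
  structure(list(colors = colors, opacity = opacity, mode = mode),
            class = "overlay_spec")
}

# Paint labeled objects onto an RGB array with per-label colors.
paint_labels <- function(rgb, mask, labels, color, opacity, outline = FALSE) {
  if (length(labels) == 0L) return(rgb)
  sel <- mask %in% labels
  if (outline) {
    nr <- nrow(mask); nc <- ncol(mask)
    p <- matrix(-1L, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- mask
    ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
    border <- ctr > 0L & (
      p[1:nr, 2:(nc + 1L)] != ctr | p[3:(nr + 2L), 2:(nc + 1L)] != ctr |
      p[2:(nr + 1L), 1:nc] != ctr | p[2:(nr + 1L), 3:(nc + 2L)] != ctr)
    sel <- sel & border
  }
  idx <- which(sel)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[idx] <- (1 - opacity) * plane[idx] + opacity * color[ch]
    rgb[, , ch] <- plane
  }
  rgb
}

#' Render the workflow's visual outputs
#'
#' Writes three deterministic images: a per-nucleus classification overlay
#' (small red, intermediate yellow, large white), a kept-vs-filtered panel
#' (kept white, filtered red), and a class-distribution bar chart. When no
#' RGB tile is supplied, objects are painted on a neutral dark background.
#'
#' @param mask Integer instance mask the report was computed from.
#' @param report An `image_report` from [run_workflow()].
#' @param out_prefix Path prefix; files `<prefix>_classes.png`,
#'   `<prefix>_filtered.png`, `<prefix>_distribution.png` are written.
#' @param image Optional RGB array (`height x width x 3`, values in 0-1)
#'   matching the mask dimensions.
#' @param spec An [overlay_spec()].
#' @return Character vector of the three file paths, invisibly.
#' @export
render_overlays <- function(mask, report, out_prefix, image = NULL,
                            spec = overlay_spec()) {
  stopifnot(inherits(report, "image_report"), inherits(spec, "overlay_spec"))
  mask <- ensure_int_matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  if (is.null(image)) {
    base <- array(0.15, dim = c(nr, nc, 3))
    op <- 1  # no backdrop to blend with
  } else {
    if (!identical(dim(image)[1:2], dim(mask))) {
      stop("image and mask dimensions differ")
    }
    base <- image
    op <- spec$opacity
  }
  outline <- spec$mode == "outline"
  pn <- report$per_nucleus
  cls_img <- base
  for (cl in c("small", "intermediate", "large", "excluded_size")) {
    cls_img <- paint_labels(cls_img, mask, pn$label[pn$class == cl],
                            spec$colors[[cl]], op, outline)
  }
  filt_img <- base
  filt_img <- paint_labels(filt_img, mask, report$filter$kept,
                           spec$colors$kept, op, outline)
  filt_img <- paint_labels(filt_img, mask, report$filter$excluded$label,
                           spec$colors$filtered, op, outline)
  paths <- paste0(out_prefix, c("_classes.png", "_filtered.png",
                                "_distribution.png"))
  png::writePNG(cls_img, paths[1])
  png::writePNG(filt_img, paths[2])
  grDevices::png(paths[3], width = 640, height = 480)
  graphics::barplot(report$class_counts, col = c("red3", "gold", "grey95"),
                    main = "Nuclear size class distribution",
                    ylab = "nuclei",
                    sub = sprintf("majority: %s | dropout: %.1f%%",
                                  report$majority_class,
                                  100 * report$dropout_rate))
  grDevices::dev.off()
  invisible(paths)
}
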