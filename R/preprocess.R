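#' Read a leaf image from disk
#'
#' Thin wrapper over [EBImage::readImage()] (PNG, TIFF, JPEG). The returned
#' object keeps EBImage's \code{[x, y(, channel)]} indexing, which the whole
#' package uses: x is the column, y the row, y grows downward, 1-based.
#'
#' @param path image file path.
#' @return An \code{EBImage::Image}.
#' @export
read_leaf_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  EBImage::readImage(path)
}

# Coerce raster input (Image, matrix, array, binary_leaf) to a grayscale
# intensity matrix [x, y] in [0, 1].
as_gray_matrix <- function(image) {
  if (inherits(image, "binary_leaf")) return(matrix(as.numeric(image$mask), nrow = nrow(image$mask)))
  if (inherits(image, "Image")) {
    if (EBImage::colorMode(image) == EBImage::Color)
      image <- EBImage::channel(image, "gray")
    image <- EBImage::imageData(image)
  }
  if (length(dim(image)) == 3) {
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  }
  m <- as.matrix(image)
  if (is.logical(m)) m <- m * 1
  if (max(m) > 1) m <- m / 255
  m
}

#' Segment a leaf image into a binary mask
#'
#' Thresholds the image (Otsu or fixed), picks the foreground as the
#' intensity class that does not dominate the image border, keeps the largest
#' connected component, fills interior holes, and (by default) rescales the
#' mask so its longest side matches the configured working scale with a clear
#' 2 px border. All later pixel-unit thresholds assume this working scale.
#'
#' @param image an \code{EBImage::Image}, matrix or array; leaf on a
#'   contrasting background.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold intensity cutoff for \code{method = "fixed"}; either in
#'   \code{[0, 1]} or on the 0--255 scale.
#' @param standardize rescale to the working size (recommended; pixel-unit
#'   magnitude thresholds are calibrated to it).
#' @param config a [leaf_config()].
#' @return An object of class \code{binary_leaf}: list with \code{mask}
#'   (logical \code{[x, y]} matrix), \code{width}, \code{height},
#'   \code{source_path}.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     standardize = TRUE, config = leaf_config()) {
  method <- match.arg(method)
  src <- attr(image, "source_path")
  g <- as_gray_matrix(image)
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(g, colormode = "Grayscale"))
  } else {
    if (is.null(threshold)) stop("method 'fixed' needs a threshold")
    if (threshold > 1) threshold / 255 else threshold
  }
  high <- g > thr
  border <- c(high[1, ], high[nrow(high), ], high[, 1], high[, ncol(high)])
  fg <- if (mean(border) > 0.5) !high else high
  if (!any(fg)) stop("empty segmentation")
  W <- nrow(fg); H <- ncol(fg)
  touches <- c(any(fg[1, ]), any(fg[W, ]), any(fg[, 1]), any(fg[, H]))
  if (all(touches)) stop("segmentation failure: foreground touches all borders")

  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  ld <- EBImage::imageData(lab)
  if (max(ld) > 1) {
    tab <- tabulate(ld[ld > 0])
    fg <- ld == which.max(tab)
  }
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0.5

  if (standardize) fg <- standardize_mask(fg, config$standard_size)
  structure(list(mask = fg, width = nrow(fg), height = ncol(fg),
                 source_path = src),
            class = "binary_leaf")
}

# Rescale a mask so the longest image side equals `size`, with a clear 2 px
# border. A mask already at the working size with a clear border is returned
# unchanged (makes binarisation idempotent).
standardize_mask <- function(mask, size) {
  W <- nrow(mask); H <- ncol(mask)
  border_clear <- !any(mask[1:2, ]) && !any(mask[(W - 1):W, ]) &&
                  !any(mask[, 1:2]) && !any(mask[, (H - 1):H])
  if (max(W, H) == size && border_clear) return(mask)
  inner <- size - 4L
  sc <- inner / max(W, H)
  w2 <- max(1L, as.integer(round(W * sc))); h2 <- max(1L, as.integer(round(H * sc)))
  rs <- EBImage::resize(EBImage::Image(mask * 1), w = w2, h = h2)
  m2 <- EBImage::imageData(rs) > 0.5
  out <- matrix(FALSE, w2 + 4L, h2 + 4L)
  out[2 + seq_len(w2), 2 + seq_len(h2)] <- m2
  out
}

#' Trace the closed clockwise boundary of a binary leaf
#'
#' Orders the 8-connected boundary pixels of the single foreground component
#' along the contour, clockwise in image coordinates (y down). The starting
#' point is arbitrary; consecutive duplicates are removed and the last point
#' is adjacent to the first.
#'
#' @param bin a \code{binary_leaf} (or logical mask matrix).
#' @return Object of class \code{leaf_contour}: list with \code{points}
#'   (n x 2 matrix, columns x, y) and \code{n}.
#' @export
trace_boundary <- function(bin) {
  mask <- if (inherits(bin, "binary_leaf")) bin$mask else bin
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) > 1) stop("ambiguous boundary: more than one component")
  if (max(lab) < 1) stop("ambiguous boundary: empty mask")
  oc <- EBImage::ocontour(lab)[[1]] + 1  # ocontour is 0-based
  # drop consecutive duplicates (UniqueCur semantics), including the wrap
  keep <- c(TRUE, rowSums(abs(diff(oc))) > 0)
  oc <- oc[keep, , drop = FALSE]
  if (nrow(oc) > 1 && all(oc[1, ] == oc[nrow(oc), ])) oc <- oc[-nrow(oc), , drop = FALSE]
  # enforce clockwise orientation on screen (y down): shoelace area > 0
  x <- oc[, 1]; y <- oc[, 2]
  sa <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (sa < 0) oc <- oc[nrow(oc):1, , drop = FALSE]
  colnames(oc) <- c("x", "y")
  structure(list(points = oc, n = nrow(oc)), class = "leaf_contour")
}

#' Incircle centre of a leaf mask
#'
#' Returns the interior point with maximal distance to the background (the
#' centre of the largest inscribed circle). This, not the area centroid, is
#' the reference point of the shape signature: for bent or lobed leaves the
#' area centroid can fall outside the blade and produce spurious signature
#' oscillations. Ties are broken by smallest row, then smallest column.
#'
#' @param bin a \code{binary_leaf} (or logical mask matrix).
#' @return Object of class \code{leaf_centroid}: list with \code{cx},
#'   \code{cy}, \code{incircle_radius} (pixels).
#' @export
incircle_centroid <- function(bin) {
  mask <- if (inherits(bin, "binary_leaf")) bin$mask else bin
  if (!any(mask)) stop("empty mask")
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  mx <- max(dm)
  idx <- which(dm == mx)
  W <- nrow(dm)
  xs <- (idx - 1L) %% W + 1L
  ys <- (idx - 1L) %/% W + 1L
  o <- order(ys, xs)[1]
  structure(list(cx = xs[o], cy = ys[o], incircle_radius = mx),
            class = "leaf_centroid")
}

#' Remove a petiole from a leaf mask
#'
#' Looks for a narrow elongated protrusion (width below
#' \code{width_frac} of the incircle diameter, length above
#' \code{min_len_frac} of the incircle radius) and cuts it at its narrowest
#' cross-section via a morphological opening; everything else removed by the
#' opening (teeth, tip pixels) is restored. A no-op when no such protrusion
#' exists. Off by default in the pipeline: apex/base disambiguation does not
#' require the petiole.
#'
#' @param bin a \code{binary_leaf}.
#' @param width_frac maximum petiole width as a fraction of the incircle
#'   diameter.
#' @param min_len_frac minimum petiole length as a fraction of the incircle
#'   radius.
#' @return A \code{binary_leaf} (unchanged if no petiole found).
#' @export
remove_petiole <- function(bin, width_frac = 0.15, min_len_frac = 0.25) {
  stopifnot(inherits(bin, "binary_leaf"))
  cen <- incircle_centroid(bin)
  w_thr <- max(3, width_frac * 2 * cen$incircle_radius)
  brush_size <- 2 * ceiling(w_thr / 2) + 1
  op <- EBImage::opening(EBImage::Image(bin$mask * 1),
                         EBImage::makeBrush(brush_size, shape = "disc"))
  removed <- bin$mask & !(EBImage::imageData(op) > 0.5)
  if (!any(removed)) return(bin)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(removed * 1)))
  min_len <- min_len_frac * cen$incircle_radius
  best <- NULL; best_len <- 0
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) < 4) next
    W <- nrow(lab)
    xs <- (idx - 1L) %% W + 1L; ys <- (idx - 1L) %/% W + 1L
    len <- max(diff(range(xs)), diff(range(ys))) + 1
    mean_width <- length(idx) / len
    if (len >= min_len && mean_width <= w_thr && len > best_len) {
      best <- idx; best_len <- len
    }
  }
  if (is.null(best)) return(bin)
  mask <- bin$mask
  mask[best] <- FALSE
  # keep the largest remaining component, refill holes
  lab2 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab2) > 1) {
    tab <- tabulate(lab2[lab2 > 0])
    mask <- lab2 == which.max(tab)
  }
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  structure(list(mask = mask, width = nrow(mask), height = ncol(mask),
                 source_path = bin$source_path),
            class = "binary_leaf")
}

#' Write a binary mask as a PNG
#' @param bin a \code{binary_leaf}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_mask_png <- function(bin, path) {
  EBImage::writeImage(EBImage::Image(bin$mask * 1), path)
  invisible(path)
}

#' Write a contour as CSV (one x,y row per boundary point)
#' @param contour a \code{leaf_contour}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(contour$points), path, row.names = FALSE)
  invisible(path)
}

#' Write a contour + centroid record as JSON
#' @param contour a \code{leaf_contour}.
#' @param centroid a \code{leaf_centroid}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_contour_json <- function(contour, centroid, path) {
  jsonlite::write_json(list(points = unname(contour$points),
                            centroid = c(centroid$cx, centroid$cy),
                            incircle_radius = centroid$incircle_radius),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
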