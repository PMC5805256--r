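#' Detect margin teeth from the small-threshold signature
#'
#' Re-runs peak/valley detection at a small magnitude threshold (default 2
#' pixels: 1 picks up rasterisation zig-zags, larger misses fine teeth) and
#' removes every small extremum that coincides with a large-threshold
#' extremum (lobe tip, sinus, apex, base) within a proximity tolerance; the
#' remainder are the margin teeth.
#'
#' @param signature a \code{leaf_signature}.
#' @param consolidated the large-threshold \code{consolidated_extrema}.
#' @param small_threshold magnitude threshold for teeth, default 2.
#' @param match_tol proximity tolerance as a fraction of contour length.
#' @return List with \code{teeth_peaks}, \code{teeth_valleys} (contour
#'   indices) and \code{small_peaks}, \code{small_valleys} (before the
#'   exclusion).
#' @export
detect_teeth <- function(signature, consolidated, small_threshold = 2,
                         match_tol = 0.01) {
  small <- find_extrema(signature, small_threshold)
  n <- length(signature$dist)
  tol <- max(1, round(match_tol * n))
  drop_near <- function(cand, big) {
    if (!length(cand) || !length(big)) return(cand)
    keep <- vapply(cand, function(i) all(cyclic_dist(i, big, n) > tol), logical(1))
    cand[keep]
  }
  sp <- as.integer(small$peaks[, "index"])
  sv <- as.integer(small$valleys[, "index"])
  list(teeth_peaks = drop_near(sp, consolidated$peak_positions),
       teeth_valleys = drop_near(sv, consolidated$valley_positions),
       small_peaks = sp, small_valleys = sv)
}

#' Ripples ratio of a leaf mask
#'
#' Smooths the silhouette with a morphological disk filter (opening then
#' closing) and returns the area changed by the smoothing divided by the
#' leaf area. Near zero for an entire (smooth) margin; teeth raise it.
#'
#' @param bin a \code{binary_leaf} (or logical mask).
#' @param smoothing_radius disk radius in pixels; \code{NULL} uses
#'   incircle_radius / 8.
#' @return The ratio (numeric scalar) with the smoothed mask attached as
#'   attribute \code{"smoothed"}.
#' @export
ripples_ratio <- function(bin, smoothing_radius = NULL) {
  mask <- if (inherits(bin, "binary_leaf")) bin$mask else bin
  if (!any(mask)) stop("empty mask")
  if (is.null(smoothing_radius)) {
    smoothing_radius <- incircle_centroid(mask)$incircle_radius / 8
  }
  sz <- 2 * max(1, round(smoothing_radius)) + 1
  brush <- EBImage::makeBrush(sz, shape = "disc")
  img <- EBImage::Image(mask * 1)
  sm <- EBImage::closing(EBImage::opening(img, brush), brush)
  smm <- EBImage::imageData(sm) > 0.5
  ratio <- sum(xor(mask, smm)) / sum(mask)
  attr(ratio, "smoothed") <- smm
  ratio
}

#' Measure the geometry of a single tooth
#'
#' A tooth is the contour segment from its left valley over its peak to its
#' right valley. The flank chords peak-left valley and peak-right valley are
#' the lengths A and B; the tooth area is the polygon enclosed by the
#' segment and the valley-valley chord; the triangle area is that of the
#' peak/valleys triangle; the tooth height is the peak's perpendicular
#' distance from the chord; and the chord midpoint's distance to the midrib
#' axis anchors the diminutive ratio.
#'
#' @param contour a \code{leaf_contour}.
#' @param peak,left_valley,right_valley contour indices of the tooth triple
#'   (cyclically ordered left_valley, peak, right_valley).
#' @param midrib_axis list with \code{p0}, \code{p1}: two points on the
#'   midrib (pole-to-pole) line, or \code{NULL} to skip that distance.
#' @return Object of class \code{tooth_measurement}: \code{A}, \code{B},
#'   \code{tooth_area}, \code{triangle_area}, \code{L_teeth},
#'   \code{L_teeth2midrib}, plus the three indices.
#' @export
measure_tooth <- function(contour, peak, left_valley, right_valley,
                          midrib_axis = NULL) {
  pts <- contour$points
  P <- pts[peak, ]; L <- pts[left_valley, ]; R <- pts[right_valley, ]
  A <- sqrt(sum((P - L)^2)); B <- sqrt(sum((P - R)^2))
  cross <- (P[1] - L[1]) * (R[2] - L[2]) - (P[2] - L[2]) * (R[1] - L[1])
  triangle_area <- abs(cross) / 2
  chord <- sqrt(sum((R - L)^2))
  if (triangle_area < 1e-9 || chord < 1e-9) stop("degenerate tooth: collinear points")
  seg <- pts[cyclic_span(left_valley, right_valley, contour$n), , drop = FALSE]
  x <- seg[, 1]; y <- seg[, 2]
  tooth_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  L_teeth <- 2 * triangle_area / chord
  mid <- (L + R) / 2
  L2m <- if (is.null(midrib_axis)) NA_real_ else {
    v <- midrib_axis$p1 - midrib_axis$p0
    abs((mid[1] - midrib_axis$p0[1]) * v[2] - (mid[2] - midrib_axis$p0[2]) * v[1]) /
      sqrt(sum(v^2))
  }
  structure(list(peak_index = peak, left_valley_index = left_valley,
                 right_valley_index = right_valley,
                 A = A, B = B, tooth_area = tooth_area,
                 triangle_area = triangle_area,
                 L_teeth = L_teeth, L_teeth2midrib = L2m),
            class = "tooth_measurement")
}

#' Diminutive-tooth test
#'
#' The ratio of tooth height to the tooth's distance from the midrib
#' separates diminutive teeth (ratio under 1/16) from regular teeth; a ratio
#' beyond 1/8 is lobe-scale and not a tooth at all.
#'
#' @param tooth a \code{tooth_measurement} with finite
#'   \code{L_teeth2midrib}.
#' @return List with \code{ratio_dt}, \code{diminutive}, \code{lobe_scale}.
#' @export
diminutive_test <- function(tooth) {
  stopifnot(inherits(tooth, "tooth_measurement"))
  if (!is.finite(tooth$L_teeth2midrib) || tooth$L_teeth2midrib <= 0)
    stop("L_teeth2midrib must be positive")
  r <- tooth$L_teeth / tooth$L_teeth2midrib
  list(ratio_dt = r, diminutive = r < 1 / 16, lobe_scale = r > 1 / 8)
}

#' Tooth type from flank symmetry and triangularity
#'
#' Unequal flank chords mark a saw-like tooth (type 1). For symmetric teeth
#' the triangularity (tooth area over peak/valleys triangle area) separates
#' angular shark teeth (type 2, triangularity at most 1) from rounded teeth
#' (type 3).
#'
#' @param tooth a \code{tooth_measurement}.
#' @param equal_tol tolerance on \code{abs(A/B - 1)} for "approximately
#'   equal" flanks.
#' @return \code{"type1"}, \code{"type2"} or \code{"type3"}.
#' @export
tooth_type <- function(tooth, equal_tol = 0.3) {
  stopifnot(inherits(tooth, "tooth_measurement"))
  if (abs(tooth$A / tooth$B - 1) > equal_tol) return("type1")
  if (tooth$tooth_area / tooth$triangle_area <= 1) "type2" else "type3"
}

# Geometric re-centre of a tooth peak: the segment point farthest from the
# valley-valley chord (the curvature maximum of the tooth curve). The raw
# signature peak drifts off-centre where the underlying outline has a radial
# gradient; the chord-distance maximum does not.
recenter_tooth_peak <- function(contour, left_valley, right_valley) {
  segi <- cyclic_span(left_valley, right_valley, contour$n)
  seg <- contour$points[segi, , drop = FALSE]
  L <- seg[1, ]; R <- seg[nrow(seg), ]
  v <- R - L
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(segi[ceiling(length(segi) / 2)])
  v <- v / nv
  perp <- abs((seg[, 1] - L[1]) * v[2] - (seg[, 2] - L[2]) * v[1])
  segi[which.max(perp)]
}

# Flanking small valleys (cyclically nearest before and after a peak).
flanking_valleys <- function(peak, valleys, n) {
  if (length(valleys) < 2) return(NULL)
  before <- valleys[order((peak - valleys) %% n)][1]
  after <- valleys[order((valleys - peak) %% n)][1]
  if (before == after) return(NULL)
  list(left = before, right = after)
}

#' Classify the leaf margin
#'
#' Runs the full margin analysis: ripples ratio, small-threshold tooth
#' detection, per-tooth measurement against the midrib axis, diminutive and
#' type votes, and the final class. A margin is entire when the ripples
#' ratio is near zero or no usable teeth are found. Saw-like margins with a
#' strongly bimodal tooth-height distribution are doubly serrate; otherwise
#' the majority tooth type and majority diminutive flag map to
#' serrate/serrulate, dentate/denticulate, or crenate/crenulate.
#'
#' @param bin a \code{binary_leaf}.
#' @param contour a \code{leaf_contour}.
#' @param signature a \code{leaf_signature}.
#' @param consolidated the large-threshold \code{consolidated_extrema}.
#' @param midrib_axis list with \code{p0}, \code{p1} on the pole-to-pole
#'   line (from the apex/base stage), or \code{NULL} (teeth then skip the
#'   diminutive test and count as regular).
#' @param config a [leaf_config()].
#' @param min_teeth minimum usable tooth count for a toothed margin.
#' @param exclude_idx contour indices (typically the apex and base pole
#'   regions) whose teeth are excluded from the margin characterisation;
#'   near the poles the midrib distance vanishes and tooth ratios there say
#'   nothing about the margin.
#' @return Object of class \code{margin_features}: \code{ripples_ratio},
#'   \code{teeth_peaks}, \code{teeth_valleys}, \code{per_tooth},
#'   \code{ratio_dt} (median), \code{diminutive}, \code{tooth_type},
#'   \code{margin_class}, \code{tooth_heights}.
#' @export
classify_margin <- function(bin, contour, signature, consolidated,
                            midrib_axis = NULL, config = leaf_config(),
                            min_teeth = 5, exclude_idx = NULL) {
  rr <- ripples_ratio(bin, config$smoothing_radius)
  teeth <- detect_teeth(signature, consolidated, config$small_threshold,
                        config$teeth_match_tol)
  n <- contour$n
  per_tooth <- list(); types <- character(0); dims <- logical(0)
  ratios <- numeric(0); heights <- numeric(0); abr <- numeric(0); tri <- numeric(0)
  spans <- numeric(0)
  for (pk in teeth$teeth_peaks) {
    if (!is.null(exclude_idx) && pk %in% exclude_idx) next
    fl <- flanking_valleys(pk, teeth$small_valleys, n)
    if (is.null(fl)) next
    if (cyclic_dist(fl$left, fl$right, n) > 0.1 * n) next  # not a tooth-scale span
    pk2 <- recenter_tooth_peak(contour, fl$left, fl$right)
    tm <- tryCatch(measure_tooth(contour, pk2, fl$left, fl$right, midrib_axis),
                   error = function(e) NULL)
    if (is.null(tm)) next
    if (!is.null(midrib_axis)) {
      dt <- tryCatch(diminutive_test(tm), error = function(e) NULL)
      if (is.null(dt) || dt$lobe_scale) next    # lobe-scale excursion, not a tooth
      dims <- c(dims, dt$diminutive)
      ratios <- c(ratios, dt$ratio_dt)
    } else {
      dims <- c(dims, FALSE)
      ratios <- c(ratios, NA_real_)
    }
    types <- c(types, tooth_type(tm, config$equal_tol))
    heights <- c(heights, tm$L_teeth)
    abr <- c(abr, tm$A / tm$B)
    tri <- c(tri, tm$tooth_area / tm$triangle_area)
    spans <- c(spans, cyclic_dist(fl$left, fl$right, n))
    per_tooth[[length(per_tooth) + 1L]] <- tm
  }
  # where a tooth valley was missed two teeth merge into one span of double
  # width; merged spans distort every aggregate (including the tooth-order
  # test: a merged tooth mimics a big second-order tooth), so drop teeth
  # much wider than the leaf's median tooth first
  if (length(spans) >= 6) {
    keep <- spans <= 1.75 * stats::median(spans)
    per_tooth <- per_tooth[keep]
    types <- types[keep]; dims <- dims[keep]; ratios <- ratios[keep]
    heights <- heights[keep]; abr <- abr[keep]; tri <- tri[keep]
  }
  bimodal <- is_bimodal(heights, config$doubly_ratio)
  entire <- as.numeric(rr) < config$entire_tol || length(per_tooth) < min_teeth
  if (entire) {
    cls <- "entire"; maj_type <- "none"; maj_dim <- FALSE
  } else {
    # class decision on the median tooth: per-tooth chords are short (ten to
    # thirty pixels) so individual A/B and triangularity votes carry pixel
    # noise; the median is the majority tooth in the unimodal case and is
    # robust to the raster
    ab_med <- stats::median(abr)
    maj_type <- if (abs(ab_med - 1) > config$equal_tol) "type1"
      else if (stats::median(tri) <= 1) "type2" else "type3"
    maj_dim <- if (sum(is.finite(ratios))) stats::median(ratios, na.rm = TRUE) < 1 / 16
               else FALSE
    cls <- switch(maj_type,
      type1 = if (bimodal) "doubly_serrate"
              else if (maj_dim) "serrulate" else "serrate",
      type2 = if (maj_dim) "denticulate" else "dentate",
      type3 = if (maj_dim) "crenulate" else "crenate")
  }
  structure(list(ripples_ratio = as.numeric(rr),
                 teeth_peaks = teeth$teeth_peaks,
                 teeth_valleys = teeth$teeth_valleys,
                 per_tooth = per_tooth,
                 ratio_dt = if (length(ratios)) stats::median(ratios, na.rm = TRUE) else NA_real_,
                 diminutive = maj_dim, tooth_type = maj_type,
                 margin_class = cls, tooth_heights = heights),
            class = "margin_features")
}

# Two tooth orders (doubly serrate): at least two teeth stand clear of the
# typical tooth (1.55x the median height) and the big group's median height
# exceeds the small group's by `ratio`. Within a single-sized margin the
# height spread around the contour stays below the 1.55 cut, so no big group
# forms; stunted teeth from low-visibility zones only sit below the median
# and cannot trigger the test.
is_bimodal <- function(h, ratio = 1.8) {
  h <- h[is.finite(h)]
  if (length(h) < 8 || stats::sd(h) < 1e-6) return(FALSE)
  med <- stats::median(h)
  big <- h > 1.55 * med
  sum(big) >= 2 && stats::median(h[big]) / stats::median(h[!big]) >= ratio
}

#' Annotated margin image
#'
#' Writes a PNG of the mask with outward teeth marked by stars and inward
#' teeth (dents) by triangles.
#'
#' @param bin a \code{binary_leaf}.
#' @param contour a \code{leaf_contour}.
#' @param margin a \code{margin_features}.
#' @param file output PNG path.
#' @return \code{file}, invisibly.
#' @export
annotate_margin <- function(bin, contour, margin, file) {
  grDevices::png(file, width = bin$width, height = bin$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(1, bin$width), ylim = c(bin$height, 1),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(t(1 - bin$mask * 0.8)),
                        1, bin$height, bin$width, 1)
  if (length(margin$teeth_peaks))
    graphics::points(contour$points[margin$teeth_peaks, 1],
                     contour$points[margin$teeth_peaks, 2],
                     pch = 8, col = "red", cex = 0.8)
  if (length(margin$teeth_valleys))
    graphics::points(contour$points[margin$teeth_valleys, 1],
                     contour$points[margin$teeth_valleys, 2],
                     pch = 2, col = "blue", cex = 0.8)
  invisible(file)
}
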