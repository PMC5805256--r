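#' Run the full leaf analysis pipeline on one image
#'
#' Segments the image, traces the boundary, computes the every-boundary-point
#' centroid distance signature, consolidates peaks and valleys over the
#' magnitude thresholds, localises the poles (vertex-fan median for lobed
#' outlines; the signature's global maximum and its antipode for unlobed
#' ones), resolves apex versus base from the mid-vein widths, characterises
#' both tips with flank angles and the Centroid Contour Gradient, and
#' classifies the margin.
#'
#' @param image an \code{EBImage::Image} / matrix / array, or a list with
#'   \code{image} (e.g. a [generate_leaf()] record).
#' @param config a [leaf_config()].
#' @param remove_petiole run petiole removal before analysis.
#' @return Object of class \code{leaf_analysis} with components \code{bin},
#'   \code{contour}, \code{centroid}, \code{signature}, \code{consolidated},
#'   \code{counts}, \code{poles}, \code{apex}, \code{base}, \code{margin}.
#' @export
analyze_leaf <- function(image, config = leaf_config(), remove_petiole = FALSE) {
  if (is.list(image) && !inherits(image, "Image") && !is.null(image$image))
    image <- image$image
  bin <- binarize(image, config = config)
  if (remove_petiole) bin <- remove_petiole(bin)
  # the raster is carried at the mask's working scale for vein measurement
  img_std <- rescale_image_to(image, bin)
  contour <- trace_boundary(bin)
  centroid <- incircle_centroid(bin)
  signature <- ccd_ebp(contour, centroid, bin, normalise = config$normalise_dist)
  consolidated <- consolidate_extrema(signature, config$thresholds)
  counts <- count_lobes_sinuses(consolidated)

  regions <- locate_poles(contour, centroid, signature, consolidated, config)
  poles <- disambiguate_apex_base(img_std, bin, contour, regions, centroid,
                                  config$window_positions)

  apex_pts <- contour$points[poles$apex_part, , drop = FALSE]
  base_pts <- contour$points[poles$base_part, , drop = FALSE]
  apex <- tryCatch(
    classify_apex_type(apex_pts, contour$points[poles$apex_point, ], config),
    error = function(e) list(label = NA_character_, apex_angle = NA_real_,
                             ccg = NULL, error = conditionMessage(e)))
  base <- tryCatch(
    classify_base_type(base_pts, contour$points[poles$base_point, ],
                       signature$dist[poles$base_part], config),
    error = function(e) list(label = NA_character_, base_angle = NA_real_,
                             ccg = NULL, error = conditionMessage(e)))

  axis <- list(p0 = contour$points[poles$apex_point, ],
               p1 = contour$points[poles$base_point, ])
  if (is.null(config$smoothing_radius))
    config$smoothing_radius <- centroid$incircle_radius / 8
  margin <- classify_margin(bin, contour, signature, consolidated,
                            midrib_axis = axis, config = config,
                            exclude_idx = c(poles$apex_part, poles$base_part))

  structure(list(bin = bin, contour = contour, centroid = centroid,
                 signature = signature, consolidated = consolidated,
                 counts = counts, poles = poles, apex = apex, base = base,
                 margin = margin, config = config),
            class = "leaf_analysis")
}

# Pole localisation: vertex fan + north/south split when at least 3 maxima
# with unequal angles exist and the resulting poles are roughly antipodal;
# otherwise the signature's global maximum and the point half the contour
# away act as poles with fixed-fraction regions. Pole regions are clamped to
# a plausible tip size (the apex covers about a quarter of the leaf, never
# more) before the curvature stages see them.
locate_poles <- function(contour, centroid, signature, consolidated, config) {
  maxima <- consolidated$peak_positions
  minima <- consolidated$valley_positions
  n <- contour$n
  half <- max(3L, floor(config$pole_region_frac * n / 2))
  seg <- function(p) ((p - 1 + (-half:half)) %% n) + 1
  clamp_part <- function(part, pole) {
    if (length(part) < max(7, 0.04 * n) || length(part) > 0.35 * n) seg(pole) else part
  }
  if (length(maxima) >= 3) {
    res <- tryCatch({
      fan <- build_vertex_fan(maxima, contour, centroid)
      fan <- split_north_south(fan, config$thres_norm)
      ps <- select_poles(fan)
      extract_pole_regions(contour, ps$NP, ps$SP, minima, config$pole_region_frac)
    }, error = function(e) NULL)
    if (!is.null(res) &&
        cyclic_dist(res$np_point, res$sp_point, n) >= n / 4) {
      res$part_np <- clamp_part(res$part_np, res$np_point)
      res$part_sp <- clamp_part(res$part_sp, res$sp_point)
      return(res)
    }
  }
  p1 <- which.max(signature$dist)
  p2 <- ((p1 - 1 + n %/% 2) %% n) + 1
  list(part_np = seg(p1), part_sp = seg(p2), np_point = p1, sp_point = p2)
}

# Resize an image to match the standardised mask dimensions (nearest scale),
# so vein windows measured on the mask line up with the raster.
rescale_image_to <- function(image, bin) {
  img <- if (inherits(image, "Image")) image else EBImage::Image(as_gray_matrix(image))
  d <- dim(img)
  if (d[1] == bin$width && d[2] == bin$height) return(img)
  sc <- (bin$width - 4) / max(d[1], d[2])
  w2 <- max(1L, round(d[1] * sc)); h2 <- max(1L, round(d[2] * sc))
  rs <- EBImage::resize(img, w = w2, h = h2)
  # pad to the mask canvas with background white
  if (length(dim(rs)) == 3) {
    out <- array(1, dim = c(bin$width, bin$height, dim(rs)[3]))
    out[2 + seq_len(w2), 2 + seq_len(h2), ] <- EBImage::imageData(rs)
  } else {
    out <- matrix(1, bin$width, bin$height)
    out[2 + seq_len(w2), 2 + seq_len(h2)] <- EBImage::imageData(rs)
  }
  EBImage::Image(out, colormode = if (length(dim(rs)) == 3) "Color" else "Grayscale")
}
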