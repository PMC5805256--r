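#' Vertex fan over the detected local maxima
#'
#' Connects the incircle centre to each local maximum of the signature (in
#' contour order) and computes the vertex angle between each pair of
#' consecutive rays by the law of cosines, including the wrap-around vertex
#' (last ray back to the first). For a star-shaped outline the angles
#' partition the full turn, so they sum to 360 degrees.
#'
#' @param maxima integer contour indices of the local maxima (from
#'   [consolidate_extrema()]), in contour order.
#' @param contour a \code{leaf_contour}.
#' @param centroid a \code{leaf_centroid}.
#' @return Object of class \code{vertex_fan}: list with \code{maxima}
#'   (indices), \code{points} (coordinates), \code{angles} (degrees, one per
#'   consecutive pair, wrap included), \code{centroid}; \code{norm_angles},
#'   \code{region_labels} and membership slots are filled by
#'   [split_north_south()].
#' @export
build_vertex_fan <- function(maxima, contour, centroid) {
  if (length(maxima) < 2) stop("insufficient maxima")
  maxima <- sort(as.integer(maxima))
  pts <- contour$points[maxima, , drop = FALSE]
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  d1 <- sqrt((pts[, 1] - centroid$cx)^2 + (pts[, 2] - centroid$cy)^2)
  d2 <- d1[nxt]
  d12 <- sqrt((pts[, 1] - pts[nxt, 1])^2 + (pts[, 2] - pts[nxt, 2])^2)
  cosv <- (d1^2 + d2^2 - d12^2) / (2 * d1 * d2)
  angles <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  structure(list(maxima = maxima, points = pts, angles = angles,
                 centroid = centroid,
                 norm_angles = NULL, region_labels = NULL,
                 north_members = NULL, south_members = NULL),
            class = "vertex_fan")
}

#' Split local maxima into north and south regions by vertex angle
#'
#' Min-max normalises the vertex angles; angles above \code{thres_norm} are
#' labelled north, the rest south. Both maxima flanking a vertex inherit its
#' region, and where a maximum would belong to both regions the smaller
#' region's membership is subtracted from the larger one. On an elongated
#' leaf the sparse-maxima (large-angle) region faces one pole and the dense
#' region the other; which one is the apex is decided later from the
#' mid-vein.
#'
#' @param fan a \code{vertex_fan}.
#' @param thres_norm normalised-angle cutoff, default 0.5.
#' @return The fan with \code{norm_angles}, \code{region_labels},
#'   \code{north_members}, \code{south_members} filled.
#' @export
split_north_south <- function(fan, thres_norm = 0.5) {
  stopifnot(inherits(fan, "vertex_fan"))
  v <- fan$angles
  if (diff(range(v)) < 1e-9) stop("degenerate fan: all vertex angles equal")
  vn <- (v - min(v)) / (max(v) - min(v))
  lab <- ifelse(vn > thres_norm, "north", "south")
  n <- length(v)
  nxt <- c(2:n, 1)
  north <- south <- logical(n)
  for (j in seq_len(n)) {
    if (lab[j] == "north") north[c(j, nxt[j])] <- TRUE
    else south[c(j, nxt[j])] <- TRUE
  }
  if (sum(south) > sum(north)) south <- south & !north else north <- north & !south
  fan$norm_angles <- vn
  fan$region_labels <- lab
  fan$north_members <- north
  fan$south_members <- south
  fan
}

# Order the TRUE entries of a cyclic membership vector as a contiguous run
# (rotated past a gap if one exists).
cyclic_run <- function(members) {
  n <- length(members)
  idx <- which(members)
  if (!length(idx)) return(integer(0))
  if (length(idx) == n) return(idx)
  gaps <- which(!members)
  start <- gaps[length(gaps)] %% n + 1
  ord <- ((start - 1 + 0:(n - 1)) %% n) + 1
  ord[members[ord]]
}

#' Select the north and south pole maxima
#'
#' Within each region the median member (leaves being roughly symmetric, the
#' middle maximum faces the pole) is the pole: the single middle element for
#' an odd member count, the two middle elements for an even count.
#'
#' @param fan a \code{vertex_fan} after [split_north_south()].
#' @return List with \code{NP} and \code{SP}: contour indices (length 1
#'   or 2) of the north and south pole maxima.
#' @export
select_poles <- function(fan) {
  stopifnot(inherits(fan, "vertex_fan"), !is.null(fan$north_members))
  pick <- function(members) {
    run <- cyclic_run(members)
    m <- length(run)
    if (m == 0) stop("pole selection failed: empty region")
    if (m %% 2 == 0 && m > 1) run[c(m / 2, m / 2 + 1)] else run[ceiling(m / 2)]
  }
  list(NP = fan$maxima[pick(fan$north_members)],
       SP = fan$maxima[pick(fan$south_members)])
}

# Cyclic index sequence from a to b (inclusive) along a contour of length n.
cyclic_span <- function(a, b, n) {
  if (a <= b) a:b else c(a:n, 1:b)
}

# Cyclic distance between contour indices.
cyclic_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

#' Extract the contour segments around the two poles
#'
#' For a single-point pole the segment runs between the nearest signature
#' minima on either side; for a two-point pole, between the minima flanking
#' the outer points. Leaves without usable flanking minima (entire, unlobed
#' outlines) fall back to a fixed fraction of the contour length centred on
#' the pole.
#'
#' @param contour a \code{leaf_contour}.
#' @param NP,SP pole contour indices (length 1 or 2) from [select_poles()].
#' @param minima contour indices of the signature minima (sinuses).
#' @param frac fallback segment length as a fraction of the contour.
#' @return List with \code{part_np}, \code{part_sp} (integer index vectors,
#'   clockwise contiguous) and \code{np_point}, \code{sp_point} (the single
#'   contour index best representing each pole).
#' @export
extract_pole_regions <- function(contour, NP, SP, minima, frac = 1 / 8) {
  n <- contour$n
  segment <- function(pole) {
    lo <- min(pole); hi <- max(pole)
    if (length(pole) == 2 && (hi - lo) > n / 2) { lo <- max(pole); hi <- min(pole) } # wrap pair
    if (length(minima) >= 2) {
      before <- minima[order(((lo - minima) %% n))][1]
      after <- minima[order(((minima - hi) %% n))][1]
      if (before != after) return(cyclic_span(before, after, n))
    }
    half <- max(3L, floor(frac * n / 2))
    mid <- if (length(pole) == 1) pole else {
      # cyclic midpoint of the pair
      d <- (hi - lo) %% n
      ((lo - 1 + d %/% 2) %% n) + 1
    }
    ((mid - 1 + (-half:half)) %% n) + 1
  }
  part_np <- segment(NP)
  part_sp <- segment(SP)
  pole_point <- function(pole) {
    if (length(pole) == 1) return(pole)
    lo <- min(pole); hi <- max(pole)
    if ((hi - lo) > n / 2) { d <- (lo - hi) %% n; ((hi - 1 + d %/% 2) %% n) + 1 }
    else ((lo - 1 + (hi - lo) %/% 2) %% n) + 1
  }
  list(part_np = part_np, part_sp = part_sp,
       np_point = pole_point(NP), sp_point = pole_point(SP))
}

# Sample image values (gray matrix or [x,y,3] array) at real coordinates by
# nearest neighbour; returns NA outside the canvas.
sample_image <- function(img, xs, ys) {
  d <- dim(img)
  xi <- round(xs); yi <- round(ys)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
  if (length(d) == 3) {
    out <- matrix(NA_real_, length(xs), d[3])
    for (k in seq_len(d[3])) out[ok, k] <- img[cbind(xi[ok], yi[ok], k)]
    out
  } else {
    out <- rep(NA_real_, length(xs))
    out[ok] <- img[cbind(xi[ok], yi[ok])]
    out
  }
}

#' Mid-vein width inside a pole window
#'
#' Measures the mean cross-axis width (pixels) of the mid-vein inside a
#' square window oriented along the pole-to-pole axis. Vein pixels are found
#' by discretised hue: the window's foreground hue histogram (24 bins) is
#' dominated by the blade colour, and coherent runs in clearly different bins
#' are the vein. On grayscale input an intensity ridge (deviation from the
#' blade's median intensity) is used instead.
#'
#' @param image \code{EBImage::Image}, matrix or array.
#' @param mask logical foreground mask.
#' @param center window centre, \code{c(x, y)}.
#' @param axis unit vector \code{c(x, y)} of the pole-to-pole axis.
#' @param side window side length, pixels.
#' @return Mean vein width in pixels; error \code{"vein undetectable"} when
#'   no coherent vein is present in the window.
#' @export
measure_midvein_width <- function(image, mask, center, axis, side) {
  img <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  ax <- axis / sqrt(sum(axis^2))
  px <- c(-ax[2], ax[1])
  half <- floor(side / 2)
  us <- -half:half; vs <- -half:half
  U <- rep(us, each = length(vs)); V <- rep(vs, length(us))
  X <- center[1] + U * ax[1] + V * px[1]
  Y <- center[2] + U * ax[2] + V * px[2]
  fg <- sample_image(mask * 1, X, Y)
  fg[is.na(fg)] <- 0
  fg <- fg > 0.5
  if (sum(fg) < 20) stop("vein undetectable: window off the blade")
  vein <- rep(FALSE, length(X))
  if (length(dim(img)) == 3) {
    vals <- sample_image(img, X, Y)
    vals[is.na(vals)] <- 1
    hsv <- grDevices::rgb2hsv(t(pmin(pmax(vals, 0), 1)), maxColorValue = 1)
    hue_bin <- floor(hsv[1, ] * 24) %% 24
    body <- as.integer(names(which.max(table(hue_bin[fg]))))
    db <- pmin((hue_bin - body) %% 24, (body - hue_bin) %% 24)
    vein[fg] <- db[fg] >= 2
  } else {
    vals <- sample_image(img, X, Y)
    med <- median(vals[fg], na.rm = TRUE)
    vein[fg] <- abs(vals[fg] - med) > 0.08
  }
  if (sum(vein) < 5) stop("vein undetectable")
  # width = mean run of vein pixels per cross-axis row (rows indexed by u)
  rows <- split(vein, U)
  w <- vapply(rows, sum, numeric(1))
  w <- w[w > 0]
  if (length(w) < 0.2 * length(us)) stop("vein undetectable: no coherent stripe")
  mean(w)
}

#' Resolve which pole region is the apex and which the base
#'
#' The mid-vein is wider where it meets the petiole, so the pole whose
#' quarter-length window shows the wider vein is the base. Windows of side
#' equal to the incircle radius are centred a quarter of the pole-to-pole
#' axis inward from each pole. When no vein can be measured (grayscale input
#' without a vein ridge) an optional tip-sharpness fallback assigns the apex
#' to the pole with the smaller flank opening angle.
#'
#' @param image the leaf image (colour preferred).
#' @param bin the \code{binary_leaf}.
#' @param contour a \code{leaf_contour}.
#' @param regions output of [extract_pole_regions()].
#' @param centroid a \code{leaf_centroid}.
#' @param window_positions fractions along the axis (from each pole inward)
#'   at which the windows sit.
#' @param fallback \code{"sharpness"} (default) or \code{"error"}.
#' @return Object of class \code{pole_regions}: the input regions plus
#'   \code{apex_part}, \code{base_part}, \code{apex_point}, \code{base_point},
#'   \code{apex_is_north}, \code{vein_widths}, \code{aligned_angle} (degrees
#'   to rotate the image counter-clockwise so the apex points up).
#' @export
disambiguate_apex_base <- function(image, bin, contour, regions, centroid,
                                   window_positions = c(0.25, 0.75),
                                   fallback = c("sharpness", "error")) {
  fallback <- match.arg(fallback)
  pn <- contour$points[regions$np_point, ]
  ps <- contour$points[regions$sp_point, ]
  axis_vec <- ps - pn
  L <- sqrt(sum(axis_vec^2))
  side <- max(9, round(centroid$incircle_radius))
  widths <- tryCatch({
    wn <- measure_midvein_width(image, bin$mask,
            pn + window_positions[1] * axis_vec, axis_vec, side)
    ws <- measure_midvein_width(image, bin$mask,
            pn + window_positions[2] * axis_vec, axis_vec, side)
    c(north = wn, south = ws)
  }, error = function(e) e)
  if (inherits(widths, "error")) {
    if (fallback == "error") stop(widths)
    an <- tryCatch(fit_flank_angle(contour$points[regions$part_np, , drop = FALSE],
                                   contour$points[regions$np_point, ])$angle,
                   error = function(e) 180)
    as_ <- tryCatch(fit_flank_angle(contour$points[regions$part_sp, , drop = FALSE],
                                    contour$points[regions$sp_point, ])$angle,
                    error = function(e) 180)
    apex_is_north <- an <= as_
    widths <- c(north = NA_real_, south = NA_real_)
  } else {
    # wider vein = base
    apex_is_north <- widths["south"] > widths["north"]
  }
  apex_part <- if (apex_is_north) regions$part_np else regions$part_sp
  base_part <- if (apex_is_north) regions$part_sp else regions$part_np
  apex_point <- if (apex_is_north) regions$np_point else regions$sp_point
  base_point <- if (apex_is_north) regions$sp_point else regions$np_point
  ap <- contour$points[apex_point, ]
  th <- atan2(-(ap[2] - centroid$cy), ap[1] - centroid$cx) * 180 / pi
  structure(c(regions, list(apex_part = apex_part, base_part = base_part,
                            apex_point = apex_point, base_point = base_point,
                            apex_is_north = unname(apex_is_north),
                            vein_widths = widths,
                            aligned_angle = 90 - th)),
            class = "pole_regions")
}

# Total-least-squares flank fit: split a pole region at the tip, fit a line
# to each flank, return the opening angle and per-flank straightness
# (rms residual / flank length).
fit_flank_angle <- function(region_pts, tip_xy) {
  n <- nrow(region_pts)
  if (n < 7) stop("region too short for flank fit")
  d2tip <- (region_pts[, 1] - tip_xy[1])^2 + (region_pts[, 2] - tip_xy[2])^2
  it <- which.min(d2tip)
  lo <- region_pts[seq_len(max(it - 1, 1)), , drop = FALSE]
  hi <- region_pts[seq(min(it + 1, n), n), , drop = FALSE]
  if (nrow(lo) < 3 || nrow(hi) < 3) stop("region too short for flank fit")
  fit <- function(p) {
    pc <- prcomp(p)
    v <- pc$rotation[, 1]
    ctr <- colMeans(p)
    if (sum(v * (ctr - tip_xy)) < 0) v <- -v       # orient away from the tip
    len <- diff(range(p %*% pc$rotation[, 1]))
    list(v = v, straightness = pc$sdev[2] / max(len, 1e-9), len = len)
  }
  fl <- fit(lo); fr <- fit(hi)
  ang <- acos(pmin(1, pmax(-1, sum(fl$v * fr$v)))) * 180 / pi
  list(angle = ang, straightness = c(fl$straightness, fr$straightness),
       flank_lengths = c(fl$len, fr$len))
}

#' Centroid Contour Gradient of a pole region
#'
#' Samples one boundary point of the region per interval angle in
#' \code{{0, theta, ..., 90}} about the region centroid (the midpoint of the
#' region's end chord), on the right side of the tip axis, and returns the
#' absolute gradients between consecutive sampled points measured in the
#' local frame (x along the chord, y toward the tip). Sampling is done with
#' polar angles rather than the tangent form, which is singular at 90
#' degrees; a vertical chord's gradient is capped at \code{g_max}.
#'
#' @param region_pts coordinates of the region's contour points (in order).
#' @param tip_xy coordinates of the tip (pole point).
#' @param theta interval angle in degrees; must divide 90.
#' @param g_max cap for vertical-chord gradients.
#' @return Object of class \code{ccg_vector}: list with \code{theta},
#'   \code{angles}, \code{points} (local coordinates of the sampled points),
#'   \code{gradients} (length \code{90/theta}), \code{side}.
#' @export
ccg <- function(region_pts, tip_xy, theta = 15, g_max = 1000) {
  stopifnot(90 %% theta == 0)
  ctr <- (region_pts[1, ] + region_pts[nrow(region_pts), ]) / 2
  ay <- tip_xy - ctr
  ny <- sqrt(sum(ay^2)); if (ny < 1e-9) stop("incomplete CCG: degenerate region")
  ay <- ay / ny
  axr <- c(-ay[2], ay[1])   # right side of the tip axis
  dx <- region_pts[, 1] - ctr[1]; dy <- region_pts[, 2] - ctr[2]
  X <- dx * axr[1] + dy * axr[2]
  Y <- dx * ay[1] + dy * ay[2]
  alpha <- atan2(Y, X) * 180 / pi
  targets <- seq(0, 90, by = theta)
  idx <- integer(length(targets)); miss <- numeric(length(targets))
  for (j in seq_along(targets)) {
    d <- abs(alpha - targets[j])
    idx[j] <- which.min(d); miss[j] <- min(d)
  }
  if (any(miss > theta / 2))
    stop("incomplete CCG: no boundary point near angle ",
         paste(targets[miss > theta / 2], collapse = ", "))
  gx <- diff(X[idx]); gy <- diff(Y[idx])
  g <- ifelse(abs(gx) < 1e-9, g_max, pmin(abs(gy / gx), g_max))
  structure(list(theta = theta, angles = targets,
                 points = cbind(X = X[idx], Y = Y[idx]),
                 indices = idx, gradients = g, side = "right"),
            class = "ccg_vector")
}

#' Classify the apex curvature type
#'
#' Operationalises the botanical apex vocabulary from the flank geometry:
#' the intersection angle of the two fitted flank lines and their
#' straightness, with the Centroid Contour Gradient profile separating the
#' curved cases. An intersection angle under 45 degrees is acuminate; a
#' straight-flanked apex between 45 and 90 degrees is acute; straight flanks
#' beyond 90 degrees are obtuse (truncate when nearly flat); curved flanks
#' form a rounded apex unless the terminal gradient jumps abruptly
#' (cuspidate).
#'
#' @param region_pts coordinates of the apex region contour points.
#' @param tip_xy coordinates of the apex point.
#' @param config a [leaf_config()].
#' @return List with \code{label}, \code{apex_angle} (degrees),
#'   \code{straightness}, \code{ccg}, \code{confidence}.
#' @export
classify_apex_type <- function(region_pts, tip_xy, config = leaf_config()) {
  ff <- fit_flank_angle(region_pts, tip_xy)
  cg <- tryCatch(ccg(region_pts, tip_xy, config$ccg_interval, config$g_max),
                 error = function(e) NULL)
  straight <- all(ff$straightness < config$straight_tol)
  a <- ff$angle
  label <-
    if (a < 45) "acuminate"
    else if (a <= 90 && straight) "acute"
    else if (straight) { if (a > 150) "truncate" else "obtuse" }
    else {
      g <- if (is.null(cg)) numeric(0) else cg$gradients
      if (length(g) >= 3 && g[length(g)] > 4 * stats::median(g[-length(g)]) &&
          g[length(g)] >= 0.9 * config$g_max) "cuspidate" else "rounded"
    }
  conf <- min(1, abs(a - 45) / 45, abs(a - 90) / 45)
  list(label = label, apex_angle = a, straightness = ff$straightness,
       ccg = cg, confidence = round(0.5 + conf / 2, 2))
}

#' Classify the base curvature type
#'
#' A central notch in the region's centroid-distance profile (two rounded
#' shoulders around a dip) marks a cordate base. Otherwise the flank
#' geometry applies: tapering flanks under 45 degrees are attenuate,
#' straight flanks between 45 and 90 degrees cuneate, straight flanks beyond
#' 90 degrees obtuse (oblique when the tip axis is strongly asymmetric to
#' the flank bisector), and curved flanks rounded.
#'
#' @param region_pts coordinates of the base region contour points.
#' @param tip_xy coordinates of the base point.
#' @param region_dist signature values over the region (same order).
#' @param config a [leaf_config()].
#' @return List with \code{label}, \code{base_angle}, \code{straightness},
#'   \code{ccg}, \code{notch_depth}, \code{confidence}.
#' @export
classify_base_type <- function(region_pts, tip_xy, region_dist = NULL,
                               config = leaf_config()) {
  notch <- 0
  if (!is.null(region_dist) && length(region_dist) >= 24) {
    # running-mean smoothing wipes out tooth ripples but keeps the wide
    # central dip of a cordate notch; the window must exceed a tooth period
    n <- length(region_dist)
    w <- max(3, floor(n / 4))
    sm <- stats::filter(region_dist, rep(1 / w, w), sides = 2)
    sm <- sm[!is.na(sm)]
    m <- length(sm)
    third <- floor(m / 3)
    mid_min <- min(sm[(third + 1):(m - third)])
    sh <- min(max(sm[1:third]), max(sm[(m - third + 1):m]))
    notch <- sh - mid_min
  }
  ff <- tryCatch(fit_flank_angle(region_pts, tip_xy), error = function(e) NULL)
  cg <- tryCatch(ccg(region_pts, tip_xy, config$ccg_interval, config$g_max),
                 error = function(e) NULL)
  if (notch > 6) {
    return(list(label = "cordate", base_angle = if (is.null(ff)) NA_real_ else ff$angle,
                straightness = if (is.null(ff)) NA_real_ else ff$straightness,
                ccg = cg, notch_depth = notch, confidence = 0.9))
  }
  if (is.null(ff))
    return(list(label = "rounded", base_angle = NA_real_, straightness = NA_real_,
                ccg = cg, notch_depth = notch, confidence = 0.5))
  straight <- all(ff$straightness < config$straight_tol)
  a <- ff$angle
  label <-
    if (a < 45) "attenuate"
    else if (a <= 90 && straight) "cuneate"
    else if (straight) "obtuse"
    else "rounded"
  conf <- min(1, abs(a - 45) / 45, abs(a - 90) / 45)
  list(label = label, base_angle = a, straightness = ff$straightness,
       ccg = cg, notch_depth = notch, confidence = round(0.5 + conf / 2, 2))
}

#' Rotate a leaf image so the apex points up
#'
#' Convenience wrapper over [EBImage::rotate()] using the alignment angle
#' from [disambiguate_apex_base()].
#'
#' @param image an \code{EBImage::Image}.
#' @param aligned_angle degrees (counter-clockwise) from
#'   \code{pole_regions$aligned_angle}.
#' @return The rotated \code{Image} (background filled with white).
#' @export
align_leaf <- function(image, aligned_angle) {
  EBImage::rotate(image, angle = -aligned_angle, bg.col = "white")
}
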