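#' Centroid contour distance signature at every boundary point
#'
#' Computes the Euclidean distance from the incircle centre to every contour
#' point (CCD-EBP). Unlike angle-sampled centroid contour distance (see
#' [ccd_sampled()]), no boundary point is skipped, so no local maximum or
#' minimum of the outline can be missed.
#'
#' @param contour a \code{leaf_contour}.
#' @param centroid a \code{leaf_centroid}.
#' @param mask optional logical mask used to verify the centroid lies inside
#'   the foreground.
#' @param normalise rescale distances to \code{[0, 100]} (magnitude
#'   thresholds then act on that scale rather than raw pixels).
#' @return Object of class \code{leaf_signature}: list with \code{dist}
#'   (numeric, one value per contour point), \code{centroid}, \code{contour},
#'   \code{normalised}.
#' @export
ccd_ebp <- function(contour, centroid, mask = NULL, normalise = FALSE) {
  stopifnot(inherits(contour, "leaf_contour"), inherits(centroid, "leaf_centroid"))
  if (!is.null(mask)) {
    m <- if (inherits(mask, "binary_leaf")) mask$mask else mask
    if (!m[round(centroid$cx), round(centroid$cy)]) stop("invalid centroid: outside foreground")
  }
  d <- sqrt((contour$points[, 1] - centroid$cx)^2 +
            (contour$points[, 2] - centroid$cy)^2)
  if (normalise) {
    rng <- range(d)
    d <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) * 100 else rep(0, length(d))
  }
  structure(list(dist = d, centroid = centroid, contour = contour,
                 normalised = isTRUE(normalise)),
            class = "leaf_signature")
}

#' Conventional angle-sampled centroid contour distance
#'
#' Reference mode: samples the contour at a fixed angular interval about the
#' centroid (e.g. every 10 degrees picks 36 boundary points) and returns
#' those points' centroid distances. Provided for comparison with the
#' every-boundary-point signature, whose point set it is a sparse subset of.
#'
#' @param contour a \code{leaf_contour}.
#' @param centroid a \code{leaf_centroid}.
#' @param interval angular interval in degrees (must divide 360).
#' @return List with \code{indices} (contour indices, one per sampled angle),
#'   \code{angles} (degrees), \code{dist}.
#' @export
ccd_sampled <- function(contour, centroid, interval = 10) {
  stopifnot(360 %% interval == 0)
  ang <- atan2(-(contour$points[, 2] - centroid$cy),
               contour$points[, 1] - centroid$cx) * 180 / pi
  ang <- (ang + 360) %% 360
  targets <- seq(0, 360 - interval, by = interval)
  idx <- vapply(targets, function(a) {
    d <- abs(ang - a)
    which.min(pmin(d, 360 - d))
  }, integer(1))
  d <- sqrt((contour$points[idx, 1] - centroid$cx)^2 +
            (contour$points[idx, 2] - centroid$cy)^2)
  list(indices = idx, angles = targets, dist = d)
}

#' Peak and valley detection at one magnitude threshold
#'
#' Alternating-mode scan: while looking for a maximum, the running maximum is
#' recorded as a peak once the signal drops more than \code{delta} below it,
#' after which the scan switches to looking for a minimum (and symmetrically
#' back). On cyclic signals the array is first rotated to start at its global
#' minimum and scanned across the wrap, so closed-contour signatures have no
#' start/end artifacts; reported indices refer to the original ordering.
#'
#' @param signature a \code{leaf_signature} or plain numeric vector.
#' @param delta positive magnitude threshold: the minimum excursion for an
#'   oscillation to count.
#' @param cyclic treat the signal as closed (default for signatures).
#' @return Object of class \code{extrema_set}: list with \code{delta},
#'   \code{peaks} and \code{valleys} (two-column matrices: index, value),
#'   sorted by index.
#' @export
find_extrema <- function(signature, delta, cyclic = TRUE) {
  stopifnot(delta > 0)
  x <- if (inherits(signature, "leaf_signature")) signature$dist else as.numeric(signature)
  n <- length(x)
  empty <- function() structure(list(delta = delta,
      peaks = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("index", "value"))),
      valleys = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("index", "value")))),
      class = "extrema_set")
  if (n < 3 || diff(range(x)) < delta) return(empty())

  if (cyclic) {
    shift <- which.min(x)
    xs <- x[c(shift:n, seq_len(shift - 1))]
    scan <- c(xs, xs)  # two laps cover the wrap; events dedupe by position
    map <- function(i) ((i - 1 + shift - 1) %% n) + 1
    lim <- 2L * n
  } else {
    scan <- x
    map <- identity
    lim <- n
  }

  ev_pos <- integer(0); ev_typ <- character(0)
  seen <- logical(n + 1L)
  mn <- Inf; mx <- -Inf; mnpos <- NA_integer_; mxpos <- NA_integer_
  lookformax <- TRUE
  for (i in seq_len(lim)) {
    this <- scan[i]
    if (this > mx) { mx <- this; mxpos <- i }
    if (this < mn) { mn <- this; mnpos <- i }
    if (lookformax) {
      if (this < mx - delta) {
        p <- map(mxpos)
        if (cyclic && seen[p]) break
        seen[p] <- TRUE
        ev_pos <- c(ev_pos, p); ev_typ <- c(ev_typ, "peak")
        mn <- this; mnpos <- i
        lookformax <- FALSE
      }
    } else {
      if (this > mn + delta) {
        p <- map(mnpos)
        if (cyclic && seen[p]) break
        seen[p] <- TRUE
        ev_pos <- c(ev_pos, p); ev_typ <- c(ev_typ, "valley")
        mx <- this; mxpos <- i
        lookformax <- TRUE
      }
    }
  }
  if (!length(ev_pos)) return(empty())
  if (cyclic && length(ev_pos) > 1 && ev_typ[1] == ev_typ[length(ev_typ)])
    { ev_pos <- ev_pos[-length(ev_pos)]; ev_typ <- ev_typ[-length(ev_typ)] }
  pk <- ev_pos[ev_typ == "peak"]; vl <- ev_pos[ev_typ == "valley"]
  pk <- sort(unique(pk)); vl <- sort(unique(vl))
  structure(list(delta = delta,
                 peaks = cbind(index = pk, value = x[pk]),
                 valleys = cbind(index = vl, value = x[vl])),
            class = "extrema_set")
}

# First-encounter mode: among values of maximal frequency, the one appearing
# earliest in the sequence wins.
mode_first <- function(v) {
  u <- unique(v)
  u[which.max(vapply(u, function(z) sum(v == z), numeric(1)))]
}

#' Consolidate extrema over multiple magnitude thresholds
#'
#' Runs [find_extrema()] at each threshold and stabilises the peak and valley
#' counts by taking their mode across thresholds (multimodal cases resolve to
#' the first mode encountered). Extremum positions are taken from the first
#' threshold whose peak and valley counts both equal the modes; if no
#' threshold matches both, from the first matching the peak mode.
#'
#' @param signature a \code{leaf_signature} (or numeric vector).
#' @param thresholds magnitude thresholds, default \code{c(15,25,35,45,55)}
#'   pixels at the standardised working scale.
#' @param cyclic passed to [find_extrema()].
#' @return Object of class \code{consolidated_extrema}: list with
#'   \code{thresholds}, \code{peak_counts}, \code{valley_counts},
#'   \code{mod_peak}, \code{mod_valley}, \code{chosen_threshold},
#'   \code{peak_positions}, \code{valley_positions}, \code{peak_values},
#'   \code{valley_values}.
#' @export
consolidate_extrema <- function(signature, thresholds = c(15, 25, 35, 45, 55),
                                cyclic = TRUE) {
  stopifnot(length(thresholds) >= 1)
  runs <- lapply(thresholds, function(d) find_extrema(signature, d, cyclic = cyclic))
  np <- vapply(runs, function(r) nrow(r$peaks), numeric(1))
  nv <- vapply(runs, function(r) nrow(r$valleys), numeric(1))
  mod_peak <- mode_first(np)
  mod_valley <- mode_first(nv)
  j <- which(np == mod_peak & nv == mod_valley)
  j <- if (length(j)) j[1] else which(np == mod_peak)[1]
  structure(list(thresholds = thresholds, peak_counts = np, valley_counts = nv,
                 mod_peak = as.integer(mod_peak), mod_valley = as.integer(mod_valley),
                 chosen_threshold = thresholds[j],
                 peak_positions = as.integer(runs[[j]]$peaks[, "index"]),
                 valley_positions = as.integer(runs[[j]]$valleys[, "index"]),
                 peak_values = unname(runs[[j]]$peaks[, "value"]),
                 valley_values = unname(runs[[j]]$valleys[, "value"])),
            class = "consolidated_extrema")
}

#' Lobe and sinus counts from consolidated extrema
#'
#' The stabilised peak count is the lobe count and the valley count the sinus
#' count; an unlobed (entire outline) leaf legitimately reports zero of each.
#'
#' @param consolidated a \code{consolidated_extrema}.
#' @return List with \code{lobes}, \code{sinuses}, \code{peak_positions},
#'   \code{valley_positions}.
#' @export
count_lobes_sinuses <- function(consolidated) {
  stopifnot(inherits(consolidated, "consolidated_extrema"))
  list(lobes = consolidated$mod_peak,
       sinuses = consolidated$mod_valley,
       peak_positions = consolidated$peak_positions,
       valley_positions = consolidated$valley_positions)
}

#' Export a signature as CSV (index, dist)
#' @param signature a \code{leaf_signature}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_signature_csv <- function(signature, path) {
  utils::write.csv(data.frame(index = seq_along(signature$dist),
                              dist = signature$dist),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot a signature with marked peaks and valleys
#'
#' Draws the centroid-distance profile against the boundary point index and
#' marks consolidated peaks (red) and valleys (green).
#'
#' @param signature a \code{leaf_signature}.
#' @param consolidated optional \code{consolidated_extrema} to mark.
#' @param file optional PNG path; when given the plot is written there.
#' @return \code{NULL}, invisibly.
#' @export
plot_signature <- function(signature, consolidated = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 420)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(signature$dist, type = "l",
                 xlab = "boundary point (clockwise)",
                 ylab = "distance to incircle centre (px)",
                 main = "CCD-EBP shape signature")
  if (!is.null(consolidated)) {
    graphics::points(consolidated$peak_positions,
                     signature$dist[consolidated$peak_positions],
                     col = "red", pch = 19)
    graphics::points(consolidated$valley_positions,
                     signature$dist[consolidated$valley_positions],
                     col = "darkgreen", pch = 17)
  }
  invisible(NULL)
}
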