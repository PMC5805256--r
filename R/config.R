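#' Pipeline run configuration
#'
#' Collects every tunable constant of the feature-extraction pipeline in one
#' place. The defaults are the published working values of the method: five
#' magnitude thresholds \code{c(15, 25, 35, 45, 55)} (in pixels, at the
#' standardised working scale) for lobe/sinus detection, a small magnitude
#' threshold of 2 for margin teeth, a normalised vertex-angle split of 0.5,
#' and a Centroid Contour Gradient interval angle of 15 degrees.
#'
#' @param thresholds numeric vector of magnitude thresholds (pixels) used for
#'   lobe/sinus peak-valley consolidation.
#' @param small_threshold magnitude threshold (pixels) for margin teeth.
#' @param thres_norm cutoff in (0,1) on normalised vertex angles separating
#'   the north from the south region.
#' @param ccg_interval interval angle theta (degrees) for the Centroid Contour
#'   Gradient; must divide 90.
#' @param standard_size working scale: masks are rescaled so the longest side
#'   equals this many pixels before any threshold in pixel units is applied.
#' @param equal_tol tolerance on \code{abs(A/B - 1)} under which the two tooth
#'   flanks count as equal length.
#' @param entire_tol ripples-ratio value below which a margin is "entire".
#' @param smoothing_radius disk radius (pixels) for the margin-smoothing
#'   filter; \code{NULL} means incircle_radius / 8, chosen per leaf.
#' @param teeth_match_tol fraction of contour length within which a
#'   small-threshold extremum is identified with a large-threshold one (and
#'   therefore excluded from the teeth set).
#' @param pole_region_frac fraction of the contour length used for an apex or
#'   base segment when no flanking sinus minima exist (entire, unlobed leaf).
#' @param g_max cap for a Centroid Contour Gradient value on a vertical chord.
#' @param doubly_ratio tooth-height bimodality ratio above which a saw-toothed
#'   margin is declared doubly serrate.
#' @param straight_tol flank line-fit rms residual, as a fraction of flank
#'   length, under which a flank counts as straight.
#' @param window_positions positions along the pole-to-pole axis (fractions of
#'   its length) at which the mid-vein width windows are centred.
#' @param normalise_dist if \code{TRUE}, the signature is rescaled to
#'   \code{[0, 100]} before thresholding (thresholds then act on that scale);
#'   default applies thresholds to raw pixel distances.
#' @param seed integer seed recorded with the config for provenance.
#' @return A list of class \code{leaf_config}.
#' @export
leaf_config <- function(thresholds = c(15, 25, 35, 45, 55),
                        small_threshold = 2,
                        thres_norm = 0.5,
                        ccg_interval = 15,
                        standard_size = 512,
                        equal_tol = 0.3,
                        entire_tol = 0.005,
                        smoothing_radius = NULL,
                        teeth_match_tol = 0.01,
                        pole_region_frac = 1 / 8,
                        g_max = 1000,
                        doubly_ratio = 1.8,
                        straight_tol = 0.02,
                        window_positions = c(0.25, 0.75),
                        normalise_dist = FALSE,
                        seed = 1L) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0),
            small_threshold > 0,
            thres_norm > 0, thres_norm < 1,
            ccg_interval > 0, 90 %% ccg_interval == 0,
            standard_size >= 64)
  structure(list(
    thresholds = as.numeric(thresholds),
    small_threshold = small_threshold,
    thres_norm = thres_norm,
    ccg_interval = ccg_interval,
    standard_size = as.integer(standard_size),
    equal_tol = equal_tol,
    entire_tol = entire_tol,
    smoothing_radius = smoothing_radius,
    teeth_match_tol = teeth_match_tol,
    pole_region_frac = pole_region_frac,
    g_max = g_max,
    doubly_ratio = doubly_ratio,
    straight_tol = straight_tol,
    window_positions = window_positions,
    normalise_dist = isTRUE(normalise_dist),
    seed = as.integer(seed)
  ), class = "leaf_config")
}

#' Read a flat key=value config file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting with
#' \code{#} are ignored. Vector values are comma separated. Unknown keys are
#' an error. Values override the defaults of [leaf_config()].
#'
#' @param path text file path.
#' @return A \code{leaf_config}.
#' @export
read_leaf_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (anyNA(num)) val else num
  }
  unknown <- setdiff(names(args), names(formals(leaf_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(leaf_config, args)
}
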