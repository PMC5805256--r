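# Shared fixtures (built once per test run) and independent oracles.

.leaf_cache <- new.env(parent = emptyenv())

cached_analysis <- function(key, spec) {
  if (is.null(.leaf_cache[[key]])) {
    .leaf_cache[[key]] <- analyze_leaf(generate_leaf(spec))
  }
  .leaf_cache[[key]]
}

# Standard five-lobed leaf used across modules.
lobed_spec <- function(rotation = 0) {
  leaf_spec(n_lobes = 5, lobe_amplitude = 0.18, elongation = 1.25,
            apex_type = "rounded", base_type = "rounded",
            vein_stripe = TRUE, rotation = rotation)
}

# Small labelled dataset with extracted features, built once per run.
with_seed_records <- function() {
  if (is.null(.leaf_cache$ds)) {
    ds <- generate_dataset(3, 6, seed = 19, train_frac = 2 / 3)
    feats <- lapply(ds$records, function(r)
      extract_features(r, species_label = r$species))
    .leaf_cache$ds <- list(feats = feats,
                           splits = vapply(ds$records, function(r) r$split,
                                           character(1)))
  }
  .leaf_cache$ds
}

# Minimal contour/centroid constructors for geometric unit tests.
fake_contour <- function(pts) structure(list(points = pts, n = nrow(pts)),
                                        class = "leaf_contour")
fake_centroid <- function(cx, cy, r = 1) structure(
  list(cx = cx, cy = cy, incircle_radius = r), class = "leaf_centroid")

# Rasterise a filled disc as a logical [x, y] mask.
disc_mask <- function(size, cx, cy, r) {
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- matrix(rep(seq_len(size), each = size), size, size)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# O(n^2) reference extrema scan: alternating segments whose maxima/minima are
# recomputed from scratch with whole-segment max()/min() calls (no running
# state), the stated independent oracle for find_extrema's linear mode.
oracle_extrema <- function(x, delta) {
  n <- length(x)
  peaks <- integer(0); valleys <- integer(0)
  mode_max <- TRUE
  s <- 1
  repeat {
    if (s > n) break
    found <- FALSE
    for (t in s:n) {
      seg <- x[s:t]
      if (mode_max) {
        m <- max(seg)
        if (x[t] < m - delta) {
          p <- s + which.max(seg) - 1L
          peaks <- c(peaks, p)
          s <- t  # next segment starts where the drop was confirmed
          mode_max <- FALSE
          found <- TRUE
          break
        }
      } else {
        m <- min(seg)
        if (x[t] > m + delta) {
          p <- s + which.min(seg) - 1L
          valleys <- c(valleys, p)
          s <- t
          mode_max <- TRUE
          found <- TRUE
          break
        }
      }
    }
    if (!found) break
  }
  list(peaks = as.integer(peaks), valleys = as.integer(valleys))
}

# Brute-force distance-to-background for every foreground pixel (small masks
# only): the oracle for the incircle centre.
oracle_incircle <- function(mask) {
  fg <- which(mask); bg <- which(!mask)
  W <- nrow(mask)
  fx <- (fg - 1L) %% W + 1L; fy <- (fg - 1L) %/% W + 1L
  bx <- (bg - 1L) %% W + 1L; by <- (bg - 1L) %/% W + 1L
  best <- -Inf; bi <- NA
  for (i in seq_along(fg)) {
    d <- min(sqrt((bx - fx[i])^2 + (by - fy[i])^2))
    if (d > best + 1e-12) { best <- d; bi <- i }
    else if (abs(d - best) <= 1e-12) {
      # tie-break smallest y then x
      if (fy[i] < fy[bi] || (fy[i] == fy[bi] && fx[i] < fx[bi])) bi <- i
    }
  }
  list(cx = fx[bi], cy = fy[bi], r = best)
}
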