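# Evaluate code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Specification of a synthetic leaf
#'
#' Parameters of the polar leaf model
#' \deqn{r(\phi) = R \, E(\phi) \, (1 + a\cos(k\phi') + t\,(w(m\phi') - 1/2))}
#' where \eqn{E} is an elongation/apex/base envelope, \eqn{a} the lobe
#' amplitude with \eqn{k} lobes phased so one lobe sits on the apex,
#' and \eqn{w} a tooth waveform of frequency \eqn{m}. All amplitudes are
#' fractions of the local envelope radius, so the tooth amplitude is also
#' (to first order) the tooth-height to midrib-distance ratio on the leaf
#' flanks, which is what the margin taxonomy thresholds (1/16, 1/8) act on.
#'
#' @param n_lobes number of lobes (0 = unlobed).
#' @param lobe_amplitude lobe amplitude as a fraction of envelope radius.
#' @param teeth_count number of margin teeth around the whole contour
#'   (0 = entire margin).
#' @param teeth_waveform one of \code{"saw"} (asymmetric, serrate-like),
#'   \code{"triangular"} (symmetric shark-tooth, dentate-like),
#'   \code{"rounded"} (rectified sine, crenate-like).
#' @param teeth_amplitude tooth amplitude as a fraction of envelope radius;
#'   below 1/16 the teeth are diminutive by construction.
#' @param doubly if \code{TRUE}, every fourth tooth is amplified 2.2-fold
#'   (sharing its valleys with the neighbouring teeth), giving the two tooth
#'   orders of a doubly serrate margin.
#' @param apex_type target apex label: \code{"acuminate"}, \code{"acute"},
#'   \code{"rounded"}, \code{"obtuse"}, \code{"truncate"}, \code{"cuspidate"}.
#' @param base_type target base label: \code{"attenuate"}, \code{"cuneate"},
#'   \code{"rounded"}, \code{"cordate"}, \code{"obtuse"}, \code{"oblique"}.
#' @param apex_flank_angle full intersection angle (degrees) of the apex
#'   flanks for wedge-shaped apices; \code{NULL} picks a per-type default
#'   (28 for acuminate, 70 for acute, 110 for obtuse).
#' @param elongation leaf length / width ratio.
#' @param petiole attach a narrow petiole at the base tip.
#' @param vein_stripe paint a darker mid-vein stripe (wider at the base,
#'   tapering toward the apex) into a colour image.
#' @param rotation rotation of the whole leaf, degrees counter-clockwise.
#' @param scale leaf length (longest extent) in pixels; the canvas adds a
#'   30 px margin.
#' @param seed integer recorded in the spec (leaf rendering itself is
#'   deterministic; the seed identifies dataset jitter provenance).
#' @return A list of class \code{leaf_spec}.
#' @export
leaf_spec <- function(n_lobes = 0, lobe_amplitude = 0.18,
                      teeth_count = 0, teeth_waveform = c("saw", "triangular", "rounded"),
                      teeth_amplitude = 0.07, doubly = FALSE,
                      apex_type = "acute", base_type = "cuneate",
                      apex_flank_angle = NULL,
                      elongation = 1.6, petiole = FALSE, vein_stripe = FALSE,
                      rotation = 0, scale = 482, seed = 1L) {
  teeth_waveform <- match.arg(teeth_waveform)
  apex_type <- match.arg(apex_type,
    c("acuminate", "acute", "rounded", "obtuse", "truncate", "cuspidate"))
  base_type <- match.arg(base_type,
    c("attenuate", "cuneate", "rounded", "cordate", "obtuse", "oblique"))
  stopifnot(n_lobes >= 0, teeth_count >= 0, elongation >= 1,
            lobe_amplitude > 0, lobe_amplitude < 0.5,
            teeth_amplitude > 0, teeth_amplitude < 0.5)
  if (n_lobes > 0 && teeth_count > 0 && teeth_amplitude >= lobe_amplitude)
    stop("invalid spec: teeth_amplitude must be below lobe_amplitude")
  a <- if (n_lobes > 0) lobe_amplitude else 0
  t <- if (teeth_count > 0) teeth_amplitude * (1 + if (doubly) 2 else 0) else 0
  if (1 - a - t / 2 <= 0.05) stop("invalid spec: amplitudes produce a self-intersecting contour")
  structure(list(
    n_lobes = as.integer(n_lobes), lobe_amplitude = lobe_amplitude,
    teeth_count = as.integer(teeth_count), teeth_waveform = teeth_waveform,
    teeth_amplitude = teeth_amplitude, doubly = isTRUE(doubly),
    apex_type = apex_type, base_type = base_type,
    apex_flank_angle = apex_flank_angle,
    elongation = elongation, petiole = isTRUE(petiole),
    vein_stripe = isTRUE(vein_stripe),
    rotation = rotation, scale = scale, seed = as.integer(seed)
  ), class = "leaf_spec")
}

# Tooth waveforms on phase u in [0,1), value range [0,1].
tooth_wave <- function(u, waveform) {
  u <- u - floor(u)
  switch(waveform,
    saw = {
      p <- 0.78
      ifelse(u <= p, u / p, (1 - u) / (1 - p))
    },
    triangular = {
      # mild flank concavity keeps the enclosed area at or below the
      # peak/valley triangle, the defining property of shark-tooth margins
      p <- 0.5
      ifelse(u <= p, (u / p)^1.2, ((1 - u) / (1 - p))^1.2)
    },
    rounded = sin(pi * u),
    stop("unknown waveform"))
}

# Polar wedge: straight flanks meeting at radius h on the pole axis with full
# opening angle alpha (degrees). s = |sin phi| (>0 toward the pole),
# c = |cos phi|.
wedge_radius <- function(s, c, alpha, h = 1) {
  h / (s + c / tan(alpha / 2 * pi / 180))
}

# Envelope E(phi): ellipse cap modified by the apex (phi ~ +90 deg) and base
# (phi ~ -90 deg) shape. phi in radians, apex toward +pi/2.
leaf_envelope <- function(phi, spec) {
  W <- 1 / spec$elongation
  E <- W / sqrt(cos(phi)^2 + W^2 * sin(phi)^2)
  s <- sin(phi); cc <- abs(cos(phi))
  up <- s > 1e-9; dn <- s < -1e-9

  ang <- spec$apex_flank_angle
  E[up] <- switch(spec$apex_type,
    rounded = E[up],
    acute = pmin(E[up], wedge_radius(s[up], cc[up], if (is.null(ang)) 70 else ang)),
    acuminate = pmin(E[up], wedge_radius(s[up], cc[up], if (is.null(ang)) 28 else ang)),
    obtuse = pmin(E[up], wedge_radius(s[up], cc[up], if (is.null(ang)) 110 else ang)),
    truncate = pmin(E[up], 0.82 / s[up]),
    cuspidate = pmax(pmin(E[up], wedge_radius(s[up], cc[up], 95, 0.88)),
                     wedge_radius(s[up], cc[up], 11, 1)))

  sd_ <- -s
  E[dn] <- switch(spec$base_type,
    rounded = E[dn],
    cuneate = pmin(E[dn], wedge_radius(sd_[dn], cc[dn], 65)),
    attenuate = pmin(E[dn], wedge_radius(sd_[dn], cc[dn], 30)),
    obtuse = pmin(E[dn], wedge_radius(sd_[dn], cc[dn], 105)),
    cordate = {
      d <- ((phi[dn] + pi / 2 + pi) %% (2 * pi)) - pi  # angular offset from base pole
      E[dn] * (1 - 0.30 * exp(-(d / (12 * pi / 180))^2))
    },
    oblique = {
      d <- ((phi[dn] + pi / 2 + pi) %% (2 * pi)) - pi
      pmin(E[dn], wedge_radius(abs(sin(phi[dn] + 15 * pi / 180)),
                               abs(cos(phi[dn] + 15 * pi / 180)), 70))
    })
  E
}

# Radial profile r(phi)/R of the leaf silhouette.
leaf_radius <- function(phi, spec) {
  E <- leaf_envelope(phi, spec)
  rel <- rep(1, length(phi))
  d <- phi - pi / 2
  if (spec$n_lobes > 0)
    rel <- rel + spec$lobe_amplitude * cos(spec$n_lobes * d)
  if (spec$teeth_count > 0) {
    u <- (spec$teeth_count * d) / (2 * pi)
    w <- tooth_wave(u, spec$teeth_waveform)
    f <- if (spec$doubly) ifelse(floor(u) %% 4 == 0, 2.2, 1) else 1
    rel <- rel + spec$teeth_amplitude * (f * w - 0.5)
  }
  E * rel
}

#' Render a synthetic leaf image with its ground truth
#'
#' Rasterises the polar leaf model of [leaf_spec()] onto a square canvas,
#' optionally adds a petiole and a mid-vein colour stripe, and returns the
#' image together with the ground-truth labels implied by the spec
#' (lobe/sinus counts, margin class, apex and base types). Rendering is fully
#' deterministic: the same spec always yields a bit-identical image.
#'
#' @param spec a [leaf_spec()].
#' @return A list with \code{image} (an \code{EBImage::Image}, grayscale or
#'   colour), \code{mask} (logical matrix, \code{[x, y]} indexing),
#'   \code{truth} (ground-truth list) and \code{spec}.
#' @export
generate_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  margin_px <- 30
  S <- as.integer(round(spec$scale + margin_px))
  cx <- (S + 1) / 2; cy <- (S + 1) / 2
  a <- if (spec$n_lobes > 0) spec$lobe_amplitude else 0
  t <- if (spec$teeth_count > 0) spec$teeth_amplitude * (1 + if (spec$doubly) 2 else 0) else 0
  pet_len_frac <- 0.22
  Rpx <- (spec$scale / 2) / (1 + a + t / 2 +
                             (if (spec$petiole) pet_len_frac else 0) + 0.02)

  xs <- matrix(rep(seq_len(S), S), S, S)
  ys <- matrix(rep(seq_len(S), each = S), S, S)
  dx <- xs - cx
  dy <- cy - ys                      # mathematical y (up); image rows grow down
  rot <- spec$rotation * pi / 180
  phi <- atan2(dy, dx) - rot
  rho <- sqrt(dx^2 + dy^2)
  mask <- rho <= Rpx * leaf_radius(phi, spec)
  lamina_area <- sum(mask)

  # apex and base tip positions in image coordinates
  tip_xy <- function(shape_angle) {
    r <- Rpx * leaf_radius(shape_angle, spec)
    th <- shape_angle + rot
    c(cx + r * cos(th), cy - r * sin(th))
  }
  apex_pt <- tip_xy(pi / 2)
  base_pt <- tip_xy(-pi / 2)

  pet_mask <- NULL
  if (spec$petiole) {
    len <- pet_len_frac * Rpx; w <- 5
    th <- -pi / 2 + rot
    p0 <- base_pt
    p1 <- c(p0[1] + len * cos(th), p0[2] - len * sin(th))
    pet_mask <- dist_to_segment(xs, ys, p0, p1) <= w / 2
    mask <- mask | pet_mask
  }

  if (spec$vein_stripe) {
    seg <- dist_to_segment(xs, ys, base_pt, apex_pt, return_s = TRUE)
    wd <- 6 - 4 * seg$s
    vein <- mask & seg$d <= wd / 2 & seg$s >= 0 & seg$s <= 1
    img <- array(1, dim = c(S, S, 3))
    col_leaf <- c(0.20, 0.55, 0.20)
    col_vein <- c(0.55, 0.45, 0.15)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[mask] <- col_leaf[k]
      ch[vein] <- col_vein[k]
      img[, , k] <- ch
    }
    image <- EBImage::Image(img, colormode = "Color")
  } else {
    ch <- matrix(1, S, S)
    ch[mask] <- 0.2
    image <- EBImage::Image(ch, colormode = "Grayscale")
  }

  diminutive <- spec$teeth_amplitude < 1 / 16
  margin_class <- if (spec$teeth_count == 0) "entire"
    else if (spec$doubly) "doubly_serrate"
    else switch(spec$teeth_waveform,
      saw = if (diminutive) "serrulate" else "serrate",
      triangular = if (diminutive) "denticulate" else "dentate",
      rounded = if (diminutive) "crenulate" else "crenate")
  truth <- list(
    lobes = spec$n_lobes, sinuses = spec$n_lobes,
    teeth_count = spec$teeth_count,
    margin_class = margin_class,
    diminutive = diminutive && spec$teeth_count > 0,
    tooth_type = if (spec$teeth_count == 0) "none" else
      switch(spec$teeth_waveform, saw = "type1", triangular = "type2", rounded = "type3"),
    apex_type = spec$apex_type, base_type = spec$base_type,
    apex_point = apex_pt, base_point = base_pt,
    lamina_area = lamina_area, petiole = spec$petiole,
    canvas = S, radius_px = Rpx
  )
  list(image = image, mask = mask, truth = truth, spec = spec)
}

# Distance from grid points to segment p0-p1; optionally also the normalised
# position s along the segment.
dist_to_segment <- function(xs, ys, p0, p1, return_s = FALSE) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  L2 <- vx^2 + vy^2
  s <- ((xs - p0[1]) * vx + (ys - p0[2]) * vy) / L2
  sc <- pmin(pmax(s, 0), 1)
  d <- sqrt((xs - (p0[1] + sc * vx))^2 + (ys - (p0[2] + sc * vy))^2)
  if (return_s) list(d = d, s = s) else d
}

#' Canonical morphology profiles for synthetic species
#'
#' Twelve species profiles spanning the eight margin classes, three apex
#' types, three base types, lobed and unlobed blades, and a range of
#' elongations; [generate_dataset()] cycles through them.
#'
#' @return A list of profiles, each with \code{lobes}, \code{margin},
#'   \code{apex}, \code{base}, \code{elong}.
#' @export
species_profiles <- function() {
  list(
    list(lobes = 0L, margin = "entire",        apex = "acute",     base = "cuneate", elong = 1.9),
    list(lobes = 0L, margin = "serrate",       apex = "acuminate", base = "rounded", elong = 1.45),
    list(lobes = 0L, margin = "serrulate",     apex = "acute",     base = "rounded", elong = 1.35),
    list(lobes = 0L, margin = "dentate",       apex = "rounded",   base = "rounded", elong = 1.3),
    list(lobes = 0L, margin = "denticulate",   apex = "acuminate", base = "rounded", elong = 1.2),
    list(lobes = 0L, margin = "crenate",       apex = "rounded",   base = "cordate", elong = 1.4),
    list(lobes = 0L, margin = "crenulate",     apex = "acute",     base = "rounded", elong = 1.4),
    list(lobes = 0L, margin = "doubly_serrate", apex = "acuminate", base = "rounded", elong = 1.4),
    list(lobes = 5L, margin = "entire",        apex = "acute",     base = "rounded", elong = 1.25),
    list(lobes = 7L, margin = "entire",        apex = "rounded",   base = "cordate", elong = 1.12),
    list(lobes = 3L, margin = "entire",        apex = "acute",     base = "cuneate", elong = 1.35),
    list(lobes = 5L, margin = "entire",        apex = "rounded",   base = "rounded", elong = 1.18)
  )
}

# Margin class -> tooth generator parameters. Amplitudes sit in the middle of
# the diminutive (<1/16) or regular (1/16..1/8) band so jitter cannot cross a
# class boundary.
margin_params <- function(margin_class) {
  switch(margin_class,
    entire        = list(count = 0L,  waveform = "saw",        amp = 0.07,  doubly = FALSE),
    serrate       = list(count = 40L, waveform = "saw",        amp = 0.085, doubly = FALSE),
    serrulate     = list(count = 64L, waveform = "saw",        amp = 0.022, doubly = FALSE),
    doubly_serrate = list(count = 60L, waveform = "saw",       amp = 0.028, doubly = TRUE),
    dentate       = list(count = 40L, waveform = "triangular", amp = 0.085, doubly = FALSE),
    denticulate   = list(count = 96L, waveform = "triangular", amp = 0.022, doubly = FALSE),
    crenate       = list(count = 36L, waveform = "rounded",    amp = 0.085, doubly = FALSE),
    crenulate     = list(count = 56L, waveform = "rounded",    amp = 0.022, doubly = FALSE),
    stop("unknown margin class: ", margin_class))
}

#' Build a leaf spec from a species profile
#'
#' Maps a [species_profiles()] entry to a concrete [leaf_spec()], applying
#' optional per-sample jitter multipliers (\code{lobe}, \code{teeth},
#' \code{elong}, \code{scale}) around the profile's nominal values.
#'
#' @param prof a profile from [species_profiles()].
#' @param rotation leaf rotation in degrees.
#' @param jitter named list of multipliers (absent entries default to 1).
#' @param scale nominal leaf length in pixels.
#' @param vein_stripe render the mid-vein colour stripe.
#' @param seed recorded in the spec.
#' @return A \code{leaf_spec}.
#' @export
spec_from_profile <- function(prof, rotation = 0, jitter = NULL, scale = 482,
                              vein_stripe = TRUE, seed = 1L) {
  mp <- margin_params(prof$margin)
  j <- function(name, def = 1) if (is.null(jitter[[name]])) def else jitter[[name]]
  leaf_spec(
    n_lobes = prof$lobes,
    lobe_amplitude = 0.18 * j("lobe"),
    teeth_count = mp$count,
    teeth_waveform = mp$waveform,
    teeth_amplitude = mp$amp * j("teeth"),
    doubly = mp$doubly,
    apex_type = prof$apex, base_type = prof$base,
    elongation = max(1.05, prof$elong * j("elong")),
    vein_stripe = vein_stripe,
    rotation = rotation, scale = scale * j("scale"), seed = seed)
}

#' Generate a labelled synthetic leaf dataset
#'
#' Builds \code{n_species} species, each defined by a base morphology profile
#' (lobe count, margin class, apex and base type, elongation), and renders
#' \code{samples_per_species} leaves per species with small random jitter on
#' amplitudes, elongation, scale and a uniformly random rotation. Records are
#' split into train and test sets at the given proportion.
#'
#' @param n_species number of species (at least 2, at most 12 distinct
#'   profiles; more recycles profiles at a different elongation).
#' @param samples_per_species leaves rendered per species.
#' @param seed single integer seed driving all jitter.
#' @param train_frac proportion of each species assigned to the train split.
#' @param vein_stripe render mid-vein colour stripes (needed for apex/base
#'   disambiguation).
#' @param scale leaf length in pixels.
#' @return A list with \code{records} (each holding \code{image}, \code{mask},
#'   \code{truth}, \code{species}, \code{split}) and \code{profiles}.
#' @export
generate_dataset <- function(n_species, samples_per_species, seed = 1L,
                             train_frac = 1280 / 1907, vein_stripe = TRUE,
                             scale = 482) {
  stopifnot(n_species >= 2, samples_per_species >= 1)
  profs <- species_profiles()
  records <- list()
  with_seed(seed, {
    for (sp in seq_len(n_species)) {
      prof <- profs[[(sp - 1L) %% length(profs) + 1L]]
      if (sp > length(profs)) prof$elong <- prof$elong * 1.25
      n_train <- max(1L, min(samples_per_species - 1L,
                             as.integer(round(train_frac * samples_per_species))))
      for (i in seq_len(samples_per_species)) {
        jit <- list(lobe = stats::runif(1, 0.92, 1.08),
                    teeth = stats::runif(1, 0.92, 1.08),
                    elong = stats::runif(1, 0.94, 1.06),
                    scale = stats::runif(1, 0.92, 1.0))
        rotation <- stats::runif(1, 0, 360)
        spec <- spec_from_profile(prof, rotation = rotation, jitter = jit,
                                  scale = scale, vein_stripe = vein_stripe,
                                  seed = seed)
        leaf <- generate_leaf(spec)
        leaf$species <- sprintf("sp%02d", sp)
        leaf$split <- if (i <= n_train) "train" else "test"
        records[[length(records) + 1L]] <- leaf
      }
    }
  })
  list(records = records, profiles = profs[seq_len(min(n_species, length(profs)))])
}
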